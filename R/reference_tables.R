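#' Reference TE-category contingency counts (human blood cell lines)
#'
#' Gene counts per TE-content category from a genome-wide survey of human
#' protein-coding genes (hg19), for the whole genome and for groups of
#' differentially expressed genes (lymphoblastoid "normal" vs chronic
#' myeloid leukemia "cancer" cell lines) selected by the direction of their
#' histone-enrichment change in the cancer condition. Down-regulated groups
#' are depleted in H3K4me1 / H3K4me3 / H3K79me2 or enriched in H3K27me3;
#' up-regulated groups are enriched in H3K4me1 / H3K4me2 / H3K4me3 /
#' H3K79me2.
#'
#' Besides the counts, the list carries the percentage and p-value
#' annotations as printed in the source table. Note two known
#' inconsistencies of those annotations, both detectable by arithmetic:
#' (i) in the `total_genome` and `down_enriched_H3K27me3` columns the
#' percentages printed for the All-TE-intermediate and All-TE-rich rows are
#' transposed relative to count/total; (ii) the printed chi-square p-values
#' cannot be derived from the printed counts (see the methods vignette).
#' Proportions recomputed by [build_contingency()] always equal
#' count / column total.
#'
#' @return A list: `counts` (12 x 9 integer matrix, rows in the standard
#'   category order), `percent_printed` (matching percentage annotations),
#'   `p_printed` (chi-square annotations per non-reference column; `NA`
#'   where only an upper bound `< 2.2e-16` was printed), `totals_printed`
#'   (printed column totals).
#' @export
te_category_reference <- function() {
  cols <- c(
    "total_genome",
    "down_depleted_H3K4me1", "down_depleted_H3K4me3", "down_depleted_H3K79me2",
    "down_enriched_H3K27me3",
    "up_enriched_H3K4me1", "up_enriched_H3K4me2", "up_enriched_H3K4me3",
    "up_enriched_H3K79me2"
  )
  counts <- matrix(c(
    # total, d-K4me1, d-K4me3, d-K79me2, e-K27me3, u-K4me1, u-K4me2, u-K4me3, u-K79me2
    2119, 156, 146, 161, 114, 298, 292, 310, 227, # SINE-rich
     972,  88,  82,  94,  80,  96, 107, 111,  78, # LINE-rich
     824,  91,  74,  87,  73,  96, 101,  97,  77, # DNA-rich
    1800, 255, 204, 284, 272, 247, 238, 267, 209, # LTR-rich
    1784, 118, 111,  98,  73, 229, 236, 250, 177, # SINE-intermediate
      20,   0,   1,   1,   2,   1,   1,   0,   1, # LINE-intermediate
      15,   1,   2,   1,   2,   3,   4,   2,   3, # DNA-intermediate
      63,   7,   5,   6,   1,   4,   5,   3,   3, # LTR-intermediate
    4300, 240, 221, 227, 170, 404, 407, 454, 314, # TE-free
     191,  14,   6,  20,  16,  41,  40,  44,  37, # All-TE-intermediate
     318,  27,  35,  42,  42,  25,  30,  32,  18, # All-TE-rich
    6665, 652, 533, 745, 669, 890, 884, 1013, 675 # Mix
  ), nrow = 12, byrow = TRUE, dimnames = list(TE_CATEGORIES, cols))
  percent_printed <- matrix(c(
    11.11, 9.46, 10.28, 9.12, 7.53, 12.77, 12.45, 12.00, 12.48,
     5.10, 5.34,  5.77, 5.32, 5.28,  4.11,  4.56,  4.30,  4.29,
     4.32, 5.52,  5.21, 4.93, 4.82,  4.11,  4.31,  3.76,  4.23,
     9.44, 15.46, 14.37, 16.08, 17.97, 11.58, 10.15, 10.34, 11.49,
     9.35, 7.16,  7.82, 5.55, 4.82,  9.81, 10.06,  9.68,  9.73,
     0.10, 0.00,  0.07, 0.06, 0.13,  0.04,  0.04,  0.00,  0.05,
     0.08, 0.06,  0.14, 0.06, 0.13,  0.13,  0.17,  0.08,  0.16,
     0.33, 0.42,  0.35, 0.34, 0.07,  0.17,  0.21,  0.12,  0.16,
    22.55, 14.55, 15.56, 12.85, 11.23, 17.31, 17.36, 17.58, 17.26,
     1.67, 0.85,  0.42, 1.13, 2.77,  1.76,  1.71,  1.70,  2.03,
     1.00, 1.64,  2.46, 2.38, 1.06,  1.07,  1.28,  1.24,  0.99,
    34.95, 39.54, 37.53, 42.19, 44.19, 38.13, 37.70, 39.22, 37.11
  ), nrow = 12, byrow = TRUE, dimnames = list(TE_CATEGORIES, cols))
  p_printed <- setNames(
    c(NA, 6.863e-14, NA, NA, NA, 2.208e-06, 3.434e-09, 5.405e-06),
    cols[-1]
  ) # NA: printed only as "< 2.2e-16"
  totals_printed <- setNames(
    c(19071, 1649, 1420, 1766, 1514, 2334, 2345, 2583, 1819), cols
  )
  list(counts = counts, percent_printed = percent_printed,
       p_printed = p_printed, totals_printed = totals_printed)
}
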