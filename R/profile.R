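#' Assign genes to 5% chromosome bins
#'
#' Each chromosome is split into 20 bins of 5% of its length; a gene is
#' assigned by its midpoint `(start + end) / 2`. Bins are left-open
#' right-closed, so a midpoint exactly at 10% of the chromosome falls in
#' bin 10 and genes in terminal regions fall in bins 5 and 100.
#'
#' @param genes Gene table.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @return Integer vector of bin labels (5, 10, ..., 100); `NA` with a
#'   warning for genes whose chromosome length is unknown.
#' @export
assign_bin <- function(genes, chrom_lengths) {
  len <- unname(chrom_lengths[genes$chrom])
  if (any(is.na(len))) {
    warning(sprintf("%d gene(s) on chromosomes without a known length were excluded",
                    sum(is.na(len))), call. = FALSE)
  }
  if (any(!is.na(len) & genes$end > len)) {
    tnt_validation_error("gene end exceeds chromosome length")
  }
  mid <- (genes$start + genes$end) / 2
  bin <- ceiling(20 * mid / len) * 5L
  bin[!is.na(mid) & mid == 0] <- 5L
  as.integer(bin)
}

#' Positional bin profiles of enrichment and TE content
#'
#' For each chromosome (or for the autosome / sex-chromosome groups) and
#' each 5% bin, reports the number of genes and the arithmetic per-gene
#' mean of every enrichment column and of overall TE density and coverage.
#' Empty bins are reported with `n_genes = 0` and missing (`NA`) means.
#'
#' @param genes Gene table.
#' @param enrichment Long enrichment table from [enrichment_matrix()], or
#'   `NULL` to profile TE metrics only.
#' @param metrics Metrics table from [te_metrics()], or `NULL`.
#' @param chrom_lengths Named vector of chromosome lengths.
#' @param grouping `"per-chromosome"` or `"autosomes-sex"`.
#' @param sex_chroms Chromosome names forming the sex group.
#' @return A long `data.frame`: `group`, `bin`, `n_genes`, `variable`
#'   (`"epsilon:<mark>:<condition>"`, `"density_all"` or `"coverage_all"`),
#'   `value`.
#' @export
bin_profile <- function(genes, enrichment = NULL, metrics = NULL, chrom_lengths,
                        grouping = c("per-chromosome", "autosomes-sex"),
                        sex_chroms = c("chrX", "chrY", "X", "Y")) {
  grouping <- match.arg(grouping)
  bins <- assign_bin(genes, chrom_lengths)
  keep <- !is.na(bins)
  genes <- genes[keep, , drop = FALSE]
  bins <- bins[keep]
  group <- if (grouping == "per-chromosome") genes$chrom else
    ifelse(genes$chrom %in% sex_chroms, "sex", "autosomes")

  values <- list()
  if (!is.null(enrichment)) {
    combos <- unique(enrichment[c("mark", "condition")])
    for (i in seq_len(nrow(combos))) {
      sel <- enrichment$mark == combos$mark[i] &
        enrichment$condition == combos$condition[i]
      v <- enrichment$epsilon[sel][match(genes$gene_id, enrichment$gene_id[sel])]
      values[[paste("epsilon", combos$mark[i], combos$condition[i], sep = ":")]] <- v
    }
  }
  if (!is.null(metrics)) {
    idx <- match(genes$gene_id, metrics$gene_id)
    values[["density_all"]] <- metrics$density_all[idx]
    values[["coverage_all"]] <- metrics$coverage_all[idx]
  }
  if (!length(values)) {
    tnt_validation_error("supply at least one of enrichment or metrics")
  }

  all_bins <- seq(5L, 100L, by = 5L)
  out <- list()
  for (g in sort(unique(group))) {
    in_g <- group == g
    for (b in all_bins) {
      in_b <- in_g & bins == b
      for (v in names(values)) {
        out[[length(out) + 1L]] <- data.frame(
          group = g, bin = b, n_genes = sum(in_b), variable = v,
          value = if (any(in_b)) mean(values[[v]][in_b]) else NA_real_,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
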