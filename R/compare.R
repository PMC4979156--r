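test_result <- function(test, statistic, p, n, n_tests = 1, family_alpha = 0.05) {
  alpha <- bonferroni_alpha(n_tests, family_alpha)
  data.frame(
    test = test, statistic = statistic, p = p, n = n,
    alpha_bonferroni = alpha,
    significant = !is.na(p) & p < alpha,
    stringsAsFactors = FALSE
  )
}

#' Bonferroni-corrected significance threshold
#'
#' Family-wise threshold `family_alpha / n_tests`; results with p below it
#' are called significant.
#'
#' @param n_tests Number of tests in the family (>= 1).
#' @param family_alpha Family-wise error rate, default 0.05.
#' @return The per-test threshold.
#' @examples
#' bonferroni_alpha(8) # 0.00625
#' @export
bonferroni_alpha <- function(n_tests, family_alpha = 0.05) {
  if (!is_count(n_tests) || n_tests < 1) {
    tnt_validation_error("n_tests must be a positive integer")
  }
  family_alpha / n_tests
}

#' Per-gene differential enrichment between two conditions
#'
#' For every gene and mark present in both conditions, computes
#' `delta = epsilon_condA - epsilon_condB` and flags the gene `"same"`
#' when `|delta| <= tau`, else `"different"`. With the default `tau = 0`,
#' "same" means numerically equal enrichment (including the both-zero
#' case). Marks present in only one condition are excluded with a warning.
#'
#' @param enrichment Long table from [enrichment_matrix()].
#' @param cond_a,cond_b Condition labels; `delta` is A minus B (e.g.
#'   normal minus cancer, so positive delta = depleted in B).
#' @param tau Tolerance on `|delta|` for the `"same"` call.
#' @return A `data.frame`: `gene_id`, `mark`, `epsilon_a`, `epsilon_b`,
#'   `delta`, `status`.
#' @export
differential_enrichment <- function(enrichment, cond_a, cond_b, tau = 0) {
  a <- enrichment[enrichment$condition == cond_a, c("gene_id", "mark", "epsilon")]
  b <- enrichment[enrichment$condition == cond_b, c("gene_id", "mark", "epsilon")]
  marks_a <- unique(a$mark)
  marks_b <- unique(b$mark)
  only <- union(setdiff(marks_a, marks_b), setdiff(marks_b, marks_a))
  if (length(only)) {
    warning("marks present in only one condition excluded: ",
            paste(only, collapse = ", "), call. = FALSE)
  }
  shared <- intersect(marks_a, marks_b)
  a <- a[a$mark %in% shared, ]
  b <- b[b$mark %in% shared, ]
  m <- merge(a, b, by = c("gene_id", "mark"), suffixes = c("_a", "_b"))
  m$delta <- m$epsilon_a - m$epsilon_b
  m$status <- ifelse(abs(m$delta) <= tau, "same", "different")
  m <- m[order(m$mark, m$gene_id), , drop = FALSE]
  rownames(m) <- NULL
  m
}

#' Paired Wilcoxon signed-rank test between conditions
#'
#' Tests, for one mark, whether per-gene enrichment differs between the
#' two conditions: signed-rank on the per-gene pairs, zero differences
#' dropped, normal approximation with continuity correction. When all
#' differences are zero the statistic is 0 and p = 1.
#'
#' @param enrichment Long table from [enrichment_matrix()].
#' @param mark Mark to test.
#' @param cond_a,cond_b Condition labels.
#' @param genes Optional gene-id subset.
#' @param n_tests,family_alpha Bonferroni family parameters for the
#'   significance flag.
#' @return A one-row test-result `data.frame` (`test`, `statistic`, `p`,
#'   `n`, `alpha_bonferroni`, `significant`).
#' @export
paired_condition_test <- function(enrichment, mark, cond_a, cond_b,
                                  genes = NULL, n_tests = 1, family_alpha = 0.05) {
  sub <- enrichment[enrichment$mark == mark, ]
  if (!is.null(genes)) sub <- sub[sub$gene_id %in% genes, ]
  a <- sub[sub$condition == cond_a, ]
  b <- sub[sub$condition == cond_b, ]
  idx <- match(a$gene_id, b$gene_id)
  ok <- !is.na(idx)
  x <- a$epsilon[ok]
  y <- b$epsilon[idx[ok]]
  if (length(x) < 2) {
    tnt_validation_error("need >= 2 genes with both conditions for mark %s", mark)
  }
  if (all(x == y)) {
    return(test_result("wilcoxon-paired", 0, 1, length(x), n_tests, family_alpha))
  }
  wt <- suppressWarnings(
    wilcox.test(x, y, paired = TRUE, exact = FALSE, correct = TRUE)
  )
  test_result("wilcoxon-paired", unname(wt$statistic), wt$p.value,
              length(x), n_tests, family_alpha)
}

#' Rank-based comparison of values across gene groups
#'
#' Unpaired Wilcoxon rank-sum for two groups, or Kruskal-Wallis for two or
#' more; ties are handled by midranks.
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param test `"wilcoxon-unpaired"` or `"kruskal-wallis"`.
#' @param n_tests,family_alpha Bonferroni family parameters.
#' @return A one-row test-result `data.frame`.
#' @export
group_comparison_test <- function(values_by_group,
                                  test = c("wilcoxon-unpaired", "kruskal-wallis"),
                                  n_tests = 1, family_alpha = 0.05) {
  test <- match.arg(test)
  if (length(values_by_group) < 2) {
    tnt_validation_error("need >= 2 groups")
  }
  sizes <- lengths(values_by_group)
  if (any(sizes == 0)) {
    tnt_validation_error("empty group(s): %s",
                         paste(names(values_by_group)[sizes == 0], collapse = ", "))
  }
  n <- sum(sizes)
  if (test == "wilcoxon-unpaired") {
    if (length(values_by_group) != 2) {
      tnt_validation_error("wilcoxon-unpaired requires exactly 2 groups")
    }
    ht <- suppressWarnings(
      wilcox.test(values_by_group[[1]], values_by_group[[2]], exact = FALSE)
    )
  } else {
    ht <- kruskal.test(values_by_group)
  }
  test_result(test, unname(ht$statistic), ht$p.value, n, n_tests, family_alpha)
}

#' Contingency table of TE categories across gene groups
#'
#' Counts the 12 TE-content categories within each named gene group (the
#' usual first group being all classified genes, the "total genome"
#' column) and derives within-column proportions.
#'
#' @param assignments Classification table with `gene_id` and `level12`
#'   (e.g. from [classify_genes()]).
#' @param groups Named list of gene-id vectors; every id must be
#'   classified.
#' @return A list of class `tenet_contingency`: `counts` (12 x groups
#'   integer matrix, rows in the standard category order), `proportions`
#'   (count / column total), `percent` (proportions x 100 rounded to 2
#'   decimals).
#' @export
build_contingency <- function(assignments, groups) {
  if (is.null(names(groups)) || any(names(groups) == "")) {
    tnt_validation_error("groups must be a named list")
  }
  counts <- matrix(0L, nrow = length(TE_CATEGORIES), ncol = length(groups),
                   dimnames = list(TE_CATEGORIES, names(groups)))
  for (j in seq_along(groups)) {
    ids <- unique(groups[[j]])
    idx <- match(ids, assignments$gene_id)
    if (any(is.na(idx))) {
      tnt_validation_error(
        "unclassified gene id(s) in group '%s': %s", names(groups)[j],
        paste(utils::head(ids[is.na(idx)], 5), collapse = ", ")
      )
    }
    tab <- table(factor(assignments$level12[idx], levels = TE_CATEGORIES))
    counts[, j] <- as.integer(tab)
  }
  totals <- colSums(counts)
  proportions <- sweep(counts, 2, totals, "/")
  structure(
    list(counts = counts, proportions = proportions,
         percent = round(100 * proportions, 2), totals = totals),
    class = "tenet_contingency"
  )
}

#' @export
print.tenet_contingency <- function(x, ...) {
  disp <- matrix(
    sprintf("%d (%.2f %%)", x$counts, x$percent),
    nrow = nrow(x$counts), dimnames = dimnames(x$counts)
  )
  print(as.data.frame(disp), ...)
  cat("Totals:", paste(sprintf("%s=%d", names(x$totals), x$totals), collapse = ", "), "\n")
  invisible(x)
}

#' Chi-square homogeneity test between two contingency columns
#'
#' Pearson chi-square on the categories x 2 table formed by a column and a
#' reference column (typically the total-genome column), with no
#' continuity correction and no pooling of sparse categories; categories
#' with zero combined count are dropped, so the degrees of freedom equal
#' the number of remaining categories minus one.
#'
#' @param contingency A `tenet_contingency` from [build_contingency()],
#'   or a counts matrix with category rows.
#' @param column Name (or index) of the column to test.
#' @param reference Name (or index) of the reference column.
#' @param n_tests,family_alpha Bonferroni family parameters.
#' @return A one-row test-result `data.frame` with an added `df` column.
#' @export
chi2_homogeneity <- function(contingency, column, reference,
                             n_tests = 1, family_alpha = 0.05) {
  counts <- if (inherits(contingency, "tenet_contingency")) contingency$counts
            else as.matrix(contingency)
  a <- counts[, column]
  b <- counts[, reference]
  if (sum(a) == 0 || sum(b) == 0) {
    tnt_validation_error("all-zero contingency column")
  }
  keep <- (a + b) > 0
  tab <- cbind(a[keep], b[keep])
  ht <- suppressWarnings(chisq.test(tab, correct = FALSE))
  out <- test_result("chi2-homogeneity", unname(ht$statistic), ht$p.value,
                     sum(a), n_tests, family_alpha)
  out$df <- unname(ht$parameter)
  out
}

#' Split DE results into up / down / unchanged gene sets
#'
#' Significance requires an adjusted p-value below `padj_cutoff`
#' (default 0.1); genes with missing `padj`, or significant genes with a
#' zero log2 fold change, are "unchanged".
#'
#' @param de DE table (`gene_id`, `log2fc`, `padj`).
#' @param padj_cutoff Adjusted p-value threshold.
#' @return A list of gene-id character vectors: `up`, `down`, `unchanged`.
#' @export
de_gene_sets <- function(de, padj_cutoff = 0.1) {
  sig <- !is.na(de$padj) & de$padj < padj_cutoff
  list(
    up = de$gene_id[sig & de$log2fc > 0],
    down = de$gene_id[sig & de$log2fc < 0],
    unchanged = de$gene_id[!(sig & de$log2fc != 0)]
  )
}

#' Genes enriched or depleted in the second condition
#'
#' With `delta = epsilon_condA - epsilon_condB` from
#' [differential_enrichment()] (A = normal, B = cancer under the default
#' convention), `"enriched-in-B"` selects genes with `delta < -tau` and
#' `"depleted-in-B"` genes with `delta > tau`; genes with `|delta| <= tau`
#' are in neither set.
#'
#' @param diff Table from [differential_enrichment()].
#' @param mark Mark to select.
#' @param direction `"enriched-in-B"` or `"depleted-in-B"`.
#' @param tau Tolerance, default 0.
#' @return Character vector of gene ids.
#' @export
enrichment_direction_sets <- function(diff, mark,
                                      direction = c("enriched-in-B", "depleted-in-B"),
                                      tau = 0) {
  direction <- match.arg(direction)
  sub <- diff[diff$mark == mark, ]
  if (direction == "enriched-in-B") sub$gene_id[sub$delta < -tau]
  else sub$gene_id[sub$delta > tau]
}
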