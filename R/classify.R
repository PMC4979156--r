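# Shared helper: PAM with k = 2 on standardized (density, coverage), with
# the cluster whose medoid has the larger coverage labeled "rich" (ties
# broken by density). Undefined densities (fully TE-covered regions) are
# replaced by the largest finite density before standardization: such genes
# are maximally TE-dense and must never fall on the sparse side.
rich_intermediate_split <- function(density, coverage) {
  stopifnot(length(density) == length(coverage))
  d <- density
  if (any(!is.finite(d))) {
    repl <- if (any(is.finite(d))) max(d[is.finite(d)]) else 0
    d[!is.finite(d)] <- repl
  }
  feats <- cbind(density = d, coverage = coverage)
  if (nrow(feats) < 2 || nrow(unique(feats)) < 2) {
    warning("fewer than 2 distinct genes to split; all labeled intermediate",
            call. = FALSE)
    return(rep("intermediate", nrow(feats)))
  }
  fit <- pam_cluster(feats, k = 2, standardize = TRUE)
  med_cov <- coverage[fit$medoids]
  med_den <- d[fit$medoids]
  rich_cluster <- order(med_cov, med_den, decreasing = TRUE)[1]
  ifelse(fit$clustering == rich_cluster, "rich", "intermediate")
}

#' Three-level TE-content classification (free / intermediate / rich)
#'
#' Genes with overall density and coverage both zero are TE-free. The
#' remaining genes are clustered with PAM (k = 2) on their standardized
#' overall (density, coverage); the cluster whose medoid has the larger
#' coverage is TE-rich, the other TE-intermediate. With fewer than two
#' non-free genes, all non-free genes are labeled TE-intermediate with a
#' warning.
#'
#' @param metrics Metrics table from [te_metrics()].
#' @return A `data.frame`: `gene_id`, `level3` (one of `"TE-free"`,
#'   `"TE-intermediate"`, `"TE-rich"`).
#' @export
split_free_intermediate_rich <- function(metrics) {
  free <- metrics$coverage_all == 0 &
    (metrics$density_all == 0 | !is.finite(metrics$density_all))
  level3 <- rep(NA_character_, nrow(metrics))
  level3[free] <- "TE-free"
  if (any(!free)) {
    lab <- rich_intermediate_split(metrics$density_all[!free],
                                   metrics$coverage_all[!free])
    level3[!free] <- ifelse(lab == "rich", "TE-rich", "TE-intermediate")
  }
  data.frame(gene_id = metrics$gene_id, level3 = level3,
             stringsAsFactors = FALSE)
}

#' Twelve-way type-specific TE category assignment
#'
#' TE-free genes stay TE-free. For each TE class, a per-class PAM (k = 2,
#' standardized per-class density and coverage) over the genes carrying
#' that class assigns each carrier a level, intermediate or rich. A strict
#' rule then avoids confounding between TE types: genes carrying exactly
#' one class become `"<class>-rich"` or `"<class>-intermediate"`; genes
#' carrying all four classes with a uniform level become `"All-TE-rich"` or
#' `"All-TE-intermediate"`; every other gene with at least one TE is
#' `"Mix"` (so e.g. a LINE-intermediate gene is free from other TE types).
#'
#' @param metrics Metrics table from [te_metrics()].
#' @param level3 Output of [split_free_intermediate_rich()] (or a character
#'   vector aligned with `metrics`).
#' @return A `data.frame`: `gene_id`, `level12` (one of the 12 category
#'   labels), plus one `level_<class>` column per TE class
#'   (`"rich"`/`"intermediate"`/`NA` for non-carriers).
#' @export
assign_type_categories <- function(metrics, level3) {
  if (is.data.frame(level3)) {
    level3 <- level3$level3[match(metrics$gene_id, level3$gene_id)]
  }
  n <- nrow(metrics)
  levels_by_class <- matrix(NA_character_, nrow = n, ncol = length(TE_CLASSES),
                            dimnames = list(NULL, TE_CLASSES))
  for (t in TE_CLASSES) {
    carrier <- metrics[[paste0("n_", t)]] > 0
    if (!any(carrier)) next
    if (sum(carrier) < 2) {
      warning(sprintf("class %s has < 2 carrier genes; carriers labeled intermediate", t),
              call. = FALSE)
      levels_by_class[carrier, t] <- "intermediate"
      next
    }
    levels_by_class[carrier, t] <- rich_intermediate_split(
      metrics[[paste0("density_", t)]][carrier],
      metrics[[paste0("coverage_", t)]][carrier]
    )
  }
  present <- !is.na(levels_by_class)
  n_classes <- rowSums(present)
  level12 <- character(n)
  for (i in seq_len(n)) {
    if (!is.na(level3[i]) && level3[i] == "TE-free") {
      level12[i] <- "TE-free"
    } else if (n_classes[i] == 0) {
      # no copies of any class yet not TE-free by level3: defensive fallback
      level12[i] <- "TE-free"
    } else if (n_classes[i] == 1) {
      t <- TE_CLASSES[which(present[i, ])]
      level12[i] <- paste0(t, "-", levels_by_class[i, t])
    } else if (n_classes[i] == 4 && all(levels_by_class[i, ] == "rich")) {
      level12[i] <- "All-TE-rich"
    } else if (n_classes[i] == 4 && all(levels_by_class[i, ] == "intermediate")) {
      level12[i] <- "All-TE-intermediate"
    } else {
      level12[i] <- "Mix"
    }
  }
  out <- data.frame(gene_id = metrics$gene_id, level12 = level12,
                    stringsAsFactors = FALSE)
  for (t in TE_CLASSES) out[[paste0("level_", t)]] <- levels_by_class[, t]
  out
}

#' Full TE-content classification of genes
#'
#' Runs [split_free_intermediate_rich()] and [assign_type_categories()]
#' and returns the combined per-gene assignment.
#'
#' @param metrics Metrics table from [te_metrics()].
#' @return A `data.frame`: `gene_id`, `level3`, `level12`, and per-class
#'   `level_<class>` columns.
#' @export
classify_genes <- function(metrics) {
  l3 <- split_free_intermediate_rich(metrics)
  l12 <- assign_type_categories(metrics, l3)
  cbind(l3, l12[setdiff(names(l12), "gene_id")])
}
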