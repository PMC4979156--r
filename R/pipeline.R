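#' Run the full analysis pipeline on files
#'
#' Executes metrics -> enrichment -> classification -> profile -> compare
#' in order, writing one TSV per stage plus a manifest, all from a single
#' configuration list. This is the programmatic front end of the package;
#' every stage is also available as an individual function.
#'
#' @param config A list with elements:
#'   \describe{
#'     \item{`genes`}{path to the gene annotation (GTF or TSV).}
#'     \item{`genes_format`}{`"gtf"` (default) or `"tsv"`.}
#'     \item{`tes`}{path to the TE file (RepeatMasker `.out` or TSV).}
#'     \item{`tes_format`}{`"tsv"` (default) or `"out"`.}
#'     \item{`peaks`}{named character vector of broadPeak paths, names
#'       `"<mark>:<condition>"`.}
#'     \item{`de`}{optional path to a DE TSV.}
#'     \item{`chrom_sizes`}{optional path to a chrom.sizes file (enables
#'       the profile stage).}
#'     \item{`out_dir`}{output directory.}
#'     \item{`flank`}{vicinity flank, default 2000.}
#'     \item{`mode`}{enrichment mode, default `"mean_peak_signal"`.}
#'     \item{`tau`}{differential-enrichment tolerance, default 0.}
#'     \item{`padj_cutoff`}{DE significance cutoff, default 0.1.}
#'     \item{`family_alpha`}{family-wise error rate, default 0.05.}
#'     \item{`cond_a`, `cond_b`}{condition labels for the comparison;
#'       defaults are the two conditions found in the peaks, first = A.}
#'   }
#' @return Invisibly, the manifest `data.frame` (`file`, `n_rows`), also
#'   written to `manifest.tsv` in `out_dir`.
#' @export
run_pipeline <- function(config) {
  defaults <- list(genes_format = "gtf", tes_format = "tsv", flank = 2000,
                   mode = "mean_peak_signal", tau = 0, padj_cutoff = 0.1,
                   family_alpha = 0.05)
  for (k in names(defaults)) if (is.null(config[[k]])) config[[k]] <- defaults[[k]]
  for (k in c("genes", "tes", "out_dir")) {
    if (is.null(config[[k]])) tnt_validation_error("config$%s is required", k)
  }
  paths <- c(config$genes, config$tes, unname(config$peaks),
             config$de, config$chrom_sizes)
  missing <- paths[!file.exists(paths)]
  if (length(missing)) {
    tnt_validation_error("missing input file(s): %s", paste(missing, collapse = ", "))
  }
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)

  genes <- read_gene_annotation(config$genes, config$genes_format)
  tes <- read_repeatmasker_out(config$tes, config$tes_format)
  check_chromosome_names(genes, tes)
  chrom_lengths <- if (!is.null(config$chrom_sizes))
    read_chrom_sizes(config$chrom_sizes) else NULL

  outputs <- list()
  emit <- function(df, name) {
    path <- file.path(config$out_dir, name)
    write_gene_table(df, path)
    outputs[[name]] <<- nrow(df)
  }

  metrics <- te_metrics(genes, tes, flank = config$flank,
                        chrom_lengths = chrom_lengths)
  emit(metrics, "metrics.tsv")

  enrichment <- NULL
  if (!is.null(config$peaks)) {
    key <- strsplit(names(config$peaks), ":", fixed = TRUE)
    peak_sets <- lapply(seq_along(config$peaks), function(i) {
      read_broadpeak(config$peaks[[i]], mark = key[[i]][1], condition = key[[i]][2])
    })
    enrichment <- enrichment_matrix(genes, peak_sets,
                                    enrichment_config(mode = config$mode))
    emit(enrichment, "enrichment.tsv")
  }

  classification <- classify_genes(metrics)
  emit(classification, "classification.tsv")

  if (!is.null(chrom_lengths)) {
    profile <- bin_profile(genes, enrichment, metrics, chrom_lengths,
                           grouping = "autosomes-sex")
    emit(profile, "profile.tsv")
  }

  if (!is.null(enrichment)) {
    conds <- unique(enrichment$condition)
    cond_a <- if (!is.null(config$cond_a)) config$cond_a else conds[1]
    cond_b <- if (!is.null(config$cond_b)) config$cond_b else conds[2]
    if (length(conds) >= 2) {
      diff <- differential_enrichment(enrichment, cond_a, cond_b, tau = config$tau)
      emit(diff, "differential.tsv")
      marks <- unique(diff$mark)
      tests <- do.call(rbind, lapply(marks, function(m) {
        cbind(mark = m,
              paired_condition_test(enrichment, m, cond_a, cond_b,
                                    n_tests = length(marks),
                                    family_alpha = config$family_alpha))
      }))
      emit(tests, "condition_tests.tsv")

      groups <- list(total_genome = classification$gene_id)
      if (!is.null(config$de)) {
        de <- read_de_table(config$de)
        sets <- de_gene_sets(de, config$padj_cutoff)
        for (m in marks) {
          for (dir in c("enriched-in-B", "depleted-in-B")) {
            ids <- enrichment_direction_sets(diff, m, dir, tau = config$tau)
            tag <- if (dir == "enriched-in-B") "enriched" else "depleted"
            groups[[sprintf("down_%s_%s", tag, m)]] <-
              intersect(sets$down, ids)
            groups[[sprintf("up_%s_%s", tag, m)]] <-
              intersect(sets$up, ids)
          }
        }
        groups <- groups[c(TRUE, vapply(groups[-1], length, integer(1)) > 0)]
      }
      cont <- build_contingency(classification, groups)
      cont_df <- data.frame(category = rownames(cont$counts), cont$counts,
                            check.names = FALSE)
      emit(cont_df, "contingency_counts.tsv")
      if (length(groups) > 1) {
        chi <- do.call(rbind, lapply(names(groups)[-1], function(g) {
          cbind(group = g,
                chi2_homogeneity(cont, g, "total_genome",
                                 n_tests = length(groups) - 1,
                                 family_alpha = config$family_alpha))
        }))
        emit(chi, "contingency_tests.tsv")
      }
    }
  }

  manifest <- data.frame(file = names(outputs),
                         n_rows = unlist(outputs, use.names = FALSE),
                         stringsAsFactors = FALSE)
  write_gene_table(manifest, file.path(config$out_dir, "manifest.tsv"))
  invisible(manifest)
}
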