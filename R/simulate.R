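#' Configuration for the synthetic-genome generator
#'
#' Builds and validates the parameter set of [simulate_genome()]. The
#' defaults define a desk-scale genome that mirrors the study system:
#' 200 non-overlapping protein-coding genes over three autosomes and one X
#' chromosome (1 Mb each), log-normal gene lengths (median 3 kb), TE-free /
#' TE-intermediate / TE-rich genes in the genome-wide proportions
#' 0.225 / 0.48 / 0.295, vicinity TE coverage planted in the disjoint
#' ranges [0.05, 0.15] (intermediate) and [0.45, 0.60] (rich), the ten
#' studied histone marks with mark-typical baseline fold enrichments, and
#' condition shifts concentrated on H3K9ac, H3K4me2 and H3K27me3 for
#' TE-carrying genes.
#'
#' @param seed RNG seed (all randomness derives from it).
#' @param n_chromosomes Number of chromosomes; the last is named `chrX` and
#'   treated as the sex chromosome, the others `chr1`, `chr2`, ...
#' @param chrom_length Length of every chromosome, bp.
#' @param n_genes Number of genes.
#' @param gene_len_meanlog,gene_len_sdlog Log-normal gene-length parameters.
#' @param flank Vicinity flank, bp.
#' @param level3_fractions Named fractions (`free`, `intermediate`, `rich`);
#'   must sum to 1.
#' @param coverage_ranges List with `intermediate` and `rich` ranges of the
#'   planted total vicinity coverage.
#' @param per_class_coverage Optional list with `intermediate` and `rich`
#'   ranges applied to each planted class individually (instead of
#'   dividing a total-coverage draw among classes); used to plant cleanly
#'   separated per-class levels for 12-way recovery studies.
#' @param composition_fractions Named fractions (`single`, `all`, `mix`)
#'   of non-free genes carrying one class, all four classes, or a 2-3
#'   class mixture.
#' @param class_weights Sampling weights of the four TE classes.
#' @param te_lengths Typical copy length per class, bp.
#' @param marks Histone marks to emit.
#' @param baseline_signal Named baseline fold enrichment per mark.
#' @param signal_sd Gaussian noise sd added to every peak signal.
#' @param condition_shift `data.frame(mark, level3, shift)`: additive
#'   signal shift applied in the second condition to genes of that
#'   three-level category.
#' @param conditions Two condition labels (second receives the shifts).
#' @param peak_cover_range Range of the fraction of the gene body covered
#'   by its peak.
#' @param background_per_mb Intergenic background TE copies per Mb.
#' @param de_fraction_up,de_fraction_down Baseline fractions of up- /
#'   down-regulated genes.
#' @param de_coupling Probability that a gene whose `de_mark` signal is
#'   shifted gets the DE label implied by the shift sign (positive shift
#'   in the second condition couples to down-regulation for a repressive
#'   mark).
#' @param de_mark Mark whose planted shift drives the DE coupling.
#' @return A validated list of class `tenet_sim_config`.
#' @export
sim_config <- function(seed = 1,
                       n_chromosomes = 4,
                       chrom_length = 1e6,
                       n_genes = 200,
                       gene_len_meanlog = log(3000),
                       gene_len_sdlog = 0.6,
                       flank = 2000,
                       level3_fractions = c(free = 0.225, intermediate = 0.48, rich = 0.295),
                       coverage_ranges = list(intermediate = c(0.05, 0.15),
                                              rich = c(0.45, 0.60)),
                       per_class_coverage = NULL,
                       composition_fractions = c(single = 0.515, all = 0.035, mix = 0.45),
                       class_weights = c(DNA = 0.15, LTR = 0.15, LINE = 0.25, SINE = 0.45),
                       te_lengths = c(DNA = 800, LTR = 1500, LINE = 1000, SINE = 300),
                       marks = HISTONE_MARKS,
                       baseline_signal = c(
                         H3K4me1 = 5.6, H3K4me2 = 9.7, H3K4me3 = 6.8,
                         H3K9ac = 8.6, H3K9me3 = 2.2, H3K27ac = 8.0,
                         H3K27me3 = 1.8, H3K36me3 = 2.9, H3K79me2 = 4.0,
                         H4K20me1 = 1.3
                       ),
                       signal_sd = 0.4,
                       condition_shift = data.frame(
                         mark = c("H3K9ac", "H3K4me2", "H3K27me3", "H3K9ac", "H3K27me3"),
                         level3 = c("rich", "rich", "rich", "intermediate", "intermediate"),
                         shift = c(-7.5, 3.6, 2.3, -3.0, 2.0),
                         stringsAsFactors = FALSE
                       ),
                       conditions = c("normal", "cancer"),
                       peak_cover_range = c(0.4, 0.9),
                       background_per_mb = 50,
                       de_fraction_up = 0.2,
                       de_fraction_down = 0.2,
                       de_coupling = 0.5,
                       de_mark = "H3K27me3") {
  cfg <- as.list(environment())
  if (abs(sum(level3_fractions) - 1) > 1e-8 ||
      any(level3_fractions < 0)) {
    tnt_validation_error("level3_fractions must be nonnegative and sum to 1")
  }
  if (abs(sum(composition_fractions) - 1) > 1e-8 ||
      any(composition_fractions < 0)) {
    tnt_validation_error("composition_fractions must be nonnegative and sum to 1")
  }
  ok_range <- function(r) length(r) == 2 && r[1] > 0 && r[1] <= r[2] && r[2] < 1
  if (!ok_range(coverage_ranges$intermediate) || !ok_range(coverage_ranges$rich)) {
    tnt_validation_error("coverage ranges must satisfy 0 < lo <= hi < 1")
  }
  if (max(coverage_ranges$rich) > 0.9) {
    tnt_validation_error("rich coverage range above 0.9 is unsatisfiable (copies must fit)")
  }
  if (!is.null(per_class_coverage)) {
    if (!ok_range(per_class_coverage$intermediate) || !ok_range(per_class_coverage$rich)) {
      tnt_validation_error("per_class_coverage ranges must satisfy 0 < lo <= hi < 1")
    }
    if (4 * max(per_class_coverage$rich) > 0.9) {
      tnt_validation_error(
        "per-class rich coverage up to %.2f is unsatisfiable with four classes",
        max(per_class_coverage$rich)
      )
    }
  }
  if (length(conditions) != 2) tnt_validation_error("exactly 2 conditions required")
  if (de_fraction_up + de_fraction_down > 1) {
    tnt_validation_error("de fractions must sum to at most 1")
  }
  if (de_coupling < 0 || de_coupling > 1) {
    tnt_validation_error("de_coupling must be in [0, 1]")
  }
  missing_base <- setdiff(marks, names(baseline_signal))
  if (length(missing_base)) {
    tnt_validation_error("no baseline signal for mark(s): %s",
                         paste(missing_base, collapse = ", "))
  }
  structure(cfg, class = "tenet_sim_config")
}

# Split `total` bp into copies of roughly `unit` bp (at least one copy).
split_copies <- function(total, unit) {
  n <- max(1L, round(total / unit))
  base <- total %/% n
  rem <- total %% n
  base + (seq_len(n) <= rem)
}

#' Generate a synthetic genome with planted ground truth
#'
#' Emits non-overlapping genes, TE copies placed so that each gene's
#' vicinity has exactly its planted TE coverage (plus intergenic background
#' copies), one broadPeak per gene x mark x condition whose signal is the
#' mark baseline plus the planted condition shift plus Gaussian noise, a
#' DE table coupled to the planted shifts, and the ground-truth tables.
#' Planted TE-free genes have zero overlapping copies; vicinities of
#' distinct genes never overlap, so recomputing metrics reproduces the
#' planted coverage exactly. Output is fully deterministic given
#' `config$seed`.
#'
#' @param config A [sim_config()].
#' @param out_dir Optional directory; when given, all tables are written
#'   there (`genes.gtf`, `te.tsv`, `chrom.sizes`,
#'   `<mark>_<condition>.broadPeak`, `de.tsv`, `truth_categories.tsv`,
#'   `truth_shifts.tsv`) in the package's external formats.
#' @return A list: `genes`, `tes`, `peaks`, `de`, `chrom_lengths`,
#'   `truth` (list `categories`, `shifts`), `config`.
#' @export
simulate_genome <- function(config = sim_config(), out_dir = NULL) {
  if (!inherits(config, "tenet_sim_config")) {
    tnt_validation_error("config must come from sim_config()")
  }
  set.seed(config$seed, kind = "Mersenne-Twister", normal.kind = "Inversion",
           sample.kind = "Rejection")
  chroms <- c(paste0("chr", seq_len(config$n_chromosomes - 1)), "chrX")
  chrom_lengths <- setNames(rep(as.integer(config$chrom_length), length(chroms)), chroms)
  n <- config$n_genes
  flank <- as.integer(config$flank)

  ## -- genes: round-robin over chromosomes, sequential placement ----------
  gene_len <- pmax(200L, as.integer(round(
    rlnorm(n, config$gene_len_meanlog, config$gene_len_sdlog)
  )))
  chrom <- chroms[((seq_len(n) - 1L) %% length(chroms)) + 1L]
  start <- integer(n)
  min_gap <- 2L * flank + 200L
  for (cc in chroms) {
    idx <- which(chrom == cc)
    pos <- flank # keep the first vicinity unclipped
    for (i in idx) {
      pos <- pos + as.integer(round(runif(1, min_gap, min_gap + 6000)))
      start[i] <- pos
      pos <- pos + gene_len[i]
    }
    if (pos + flank > chrom_lengths[cc]) {
      tnt_validation_error(
        "genes do not fit on %s (need %d bp, have %d); reduce n_genes or gene length",
        cc, pos + flank, chrom_lengths[cc]
      )
    }
  }
  genes <- data.frame(
    gene_id = sprintf("G%04d", seq_len(n)), chrom = chrom,
    start = start, end = start + gene_len,
    strand = sample(c("+", "-"), n, replace = TRUE),
    stringsAsFactors = FALSE
  )

  ## -- planted categories --------------------------------------------------
  level3 <- sample(names(config$level3_fractions), n, replace = TRUE,
                   prob = config$level3_fractions)
  composition <- ifelse(level3 == "free", "none",
    sample(names(config$composition_fractions), n, replace = TRUE,
           prob = config$composition_fractions))
  classes <- vector("list", n)
  class_cov <- vector("list", n) # named per-class target coverage
  for (i in seq_len(n)) {
    if (level3[i] == "free") { classes[[i]] <- character(0); class_cov[[i]] <- numeric(0); next }
    cls <- switch(composition[i],
      single = sample(TE_CLASSES, 1, prob = config$class_weights[TE_CLASSES]),
      all = TE_CLASSES,
      mix = sample(TE_CLASSES, sample(2:3, 1), prob = config$class_weights[TE_CLASSES])
    )
    if (!is.null(config$per_class_coverage)) {
      r <- config$per_class_coverage[[level3[i]]]
      cov_t <- runif(length(cls), r[1], r[2])
    } else {
      r <- config$coverage_ranges[[level3[i]]]
      total <- runif(1, r[1], r[2])
      w <- runif(length(cls), 0.5, 1)
      cov_t <- total * w / sum(w)
    }
    classes[[i]] <- cls
    class_cov[[i]] <- setNames(cov_t, cls)
  }
  level12 <- vapply(seq_len(n), function(i) {
    switch(composition[i],
      none = "TE-free",
      single = paste0(classes[[i]], "-",
                      if (level3[i] == "rich") "rich" else "intermediate"),
      all = if (level3[i] == "rich") "All-TE-rich" else "All-TE-intermediate",
      mix = "Mix"
    )
  }, character(1))

  ## -- TE copies inside vicinities (exact planted coverage) ---------------
  te_rows <- list()
  fam <- c(DNA = "hAT-syn", LTR = "ERV-syn", LINE = "L1-syn", SINE = "Alu-syn")
  for (i in seq_len(n)) {
    if (!length(classes[[i]])) next
    lo <- max(0L, genes$start[i] - flank)
    hi <- min(chrom_lengths[genes$chrom[i]], genes$end[i] + flank)
    L <- hi - lo
    lens <- integer(0)
    lab <- character(0)
    for (t in classes[[i]]) {
      pieces <- split_copies(as.integer(round(class_cov[[i]][t] * L)),
                             config$te_lengths[t])
      lens <- c(lens, pieces)
      lab <- c(lab, rep(t, length(pieces)))
    }
    ord <- sample(seq_along(lens))
    pos <- place_pieces_ordered(lens[ord], lo, hi)
    te_rows[[length(te_rows) + 1L]] <- data.frame(
      chrom = genes$chrom[i], start = pos[, "start"], end = pos[, "end"],
      strand = sample(c("+", "-"), length(lens), replace = TRUE),
      family = fam[lab[ord]], te_class = lab[ord],
      stringsAsFactors = FALSE
    )
  }

  ## -- intergenic background copies (never touch a vicinity) --------------
  for (cc in chroms) {
    g <- genes[genes$chrom == cc, ]
    vic <- cbind(pmax(0L, g$start - flank), pmin(chrom_lengths[cc], g$end + flank))
    vic <- vic[order(vic[, 1]), , drop = FALSE]
    gaps <- cbind(c(0L, vic[, 2]), c(vic[, 1], chrom_lengths[cc]))
    gaps <- gaps[gaps[, 2] - gaps[, 1] > 2000, , drop = FALSE]
    for (r in seq_len(nrow(gaps))) {
      glen <- gaps[r, 2] - gaps[r, 1]
      n_bg <- as.integer(round(glen / 1e6 * config$background_per_mb))
      if (n_bg == 0) next
      cls <- sample(TE_CLASSES, n_bg, replace = TRUE,
                    prob = config$class_weights[TE_CLASSES])
      lens <- pmin(config$te_lengths[cls], glen - 2L)
      starts <- gaps[r, 1] + 1L +
        vapply(lens, function(l) sample.int(glen - l - 1L, 1), integer(1))
      te_rows[[length(te_rows) + 1L]] <- data.frame(
        chrom = cc, start = as.integer(starts), end = as.integer(starts + lens),
        strand = sample(c("+", "-"), n_bg, replace = TRUE),
        family = fam[cls], te_class = cls, stringsAsFactors = FALSE
      )
    }
  }
  tes <- do.call(rbind, te_rows)
  tes <- tes[order(tes$chrom, tes$start, tes$end), , drop = FALSE]
  rownames(tes) <- NULL

  ## -- peaks ---------------------------------------------------------------
  shift_for <- function(mark, lvl) {
    cs <- config$condition_shift
    hit <- cs$mark == mark & cs$level3 == lvl
    if (any(hit)) cs$shift[hit][1] else 0
  }
  shift_mat <- outer(seq_len(n), seq_along(config$marks),
                     Vectorize(function(i, j) shift_for(config$marks[j], level3[i])))
  pk <- expand.grid(gi = seq_len(n), mark = config$marks,
                    condition = config$conditions, stringsAsFactors = FALSE)
  frac <- runif(nrow(pk), config$peak_cover_range[1], config$peak_cover_range[2])
  plen <- pmax(1L, as.integer(round(gene_len[pk$gi] * frac)))
  off <- as.integer(floor(runif(nrow(pk)) * (gene_len[pk$gi] - plen + 1L)))
  is_b <- pk$condition == config$conditions[2]
  mu <- config$baseline_signal[pk$mark] +
    shift_mat[cbind(pk$gi, match(pk$mark, config$marks))] * is_b
  signal <- round(pmax(mu + rnorm(nrow(pk), 0, config$signal_sd), 0.01), 3)
  peaks <- data.frame(
    chrom = genes$chrom[pk$gi],
    start = genes$start[pk$gi] + off,
    end = genes$start[pk$gi] + off + plen,
    mark = pk$mark, condition = pk$condition, signal = unname(signal),
    stringsAsFactors = FALSE
  )

  ## -- differential expression coupled to the planted shifts ---------------
  u <- runif(n)
  de_label <- ifelse(u < config$de_fraction_up, "up",
               ifelse(u < config$de_fraction_up + config$de_fraction_down,
                      "down", "unchanged"))
  de_shift <- vapply(level3, function(l) shift_for(config$de_mark, l), numeric(1))
  couple <- runif(n) < config$de_coupling & de_shift != 0
  de_label[couple & de_shift > 0] <- "down"
  de_label[couple & de_shift < 0] <- "up"
  padj <- round(runif(n, 0.12, 0.95), 4)
  padj[de_label != "unchanged"] <- round(runif(sum(de_label != "unchanged"),
                                               1e-4, 0.095), 4)
  padj[de_label == "unchanged" & runif(n) < 0.02] <- NA
  lfc <- round(rnorm(n, 0, 0.15), 3)
  lfc[de_label == "up"] <- round(runif(sum(de_label == "up"), 0.5, 4), 3)
  lfc[de_label == "down"] <- -round(runif(sum(de_label == "down"), 0.5, 4), 3)
  de <- data.frame(gene_id = genes$gene_id, log2fc = lfc, padj = padj,
                   stringsAsFactors = FALSE)

  ## -- ground truth ---------------------------------------------------------
  truth_categories <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    level3 = c(free = "TE-free", intermediate = "TE-intermediate",
               rich = "TE-rich")[level3],
    level12 = level12,
    classes = vapply(classes, paste, character(1), collapse = ","),
    coverage_total = vapply(class_cov, sum, numeric(1)),
    de_label = de_label,
    stringsAsFactors = FALSE
  )
  nonzero <- which(shift_mat != 0, arr.ind = TRUE)
  truth_shifts <- data.frame(
    gene_id = genes$gene_id[nonzero[, 1]],
    mark = config$marks[nonzero[, 2]],
    shift = shift_mat[nonzero],
    stringsAsFactors = FALSE
  )
  truth_shifts <- truth_shifts[order(truth_shifts$gene_id, truth_shifts$mark), ]
  rownames(truth_shifts) <- NULL

  out <- list(genes = genes, tes = tes, peaks = peaks, de = de,
              chrom_lengths = chrom_lengths,
              truth = list(categories = truth_categories, shifts = truth_shifts),
              config = config)
  if (!is.null(out_dir)) write_simulation(out, out_dir)
  out
}

# Place disjoint pieces (already in their final order) inside [lo, hi),
# separated by a random composition of the free space.
place_pieces_ordered <- function(lens, lo, hi) {
  free <- (hi - lo) - sum(lens)
  stopifnot(free >= 0)
  cuts <- sort(sample.int(free + 1L, length(lens), replace = TRUE) - 1L)
  starts <- as.integer(lo + cuts + c(0L, cumsum(lens[-length(lens)])))
  cbind(start = starts, end = starts + as.integer(lens))
}

write_simulation <- function(sim, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  g <- sim$genes
  gtf <- sprintf('%s\ttenet_sim\tgene\t%d\t%d\t.\t%s\t.\tgene_id "%s";',
                 g$chrom, g$start + 1L, g$end, g$strand, g$gene_id)
  writeLines(gtf, file.path(out_dir, "genes.gtf"))
  write_gene_table(sim$tes, file.path(out_dir, "te.tsv"))
  writeLines(sprintf("%s\t%d", names(sim$chrom_lengths), sim$chrom_lengths),
             file.path(out_dir, "chrom.sizes"))
  for (m in unique(sim$peaks$mark)) {
    for (cond in unique(sim$peaks$condition)) {
      p <- sim$peaks[sim$peaks$mark == m & sim$peaks$condition == cond, ]
      writeLines(sprintf("%s\t%d\t%d\t.\t0\t.\t%.3f\t-1\t-1",
                         p$chrom, p$start, p$end, p$signal),
                 file.path(out_dir, sprintf("%s_%s.broadPeak", m, cond)))
    }
  }
  write_gene_table(sim$de, file.path(out_dir, "de.tsv"))
  write_gene_table(sim$truth$categories, file.path(out_dir, "truth_categories.tsv"))
  write_gene_table(sim$truth$shifts, file.path(out_dir, "truth_shifts.tsv"))
  invisible(out_dir)
}
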