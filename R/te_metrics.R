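# Convert 0-based half-open (chrom, start, end) to GRanges (1-based closed).
as_granges0 <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end)
  )
}

#' Gene vicinity interval
#'
#' The gene body extended by `flank` bp on both sides (default 2000, which
#' reaches promoter regions upstream), clamped to chromosome bounds.
#'
#' @param gene One-row gene `data.frame` (columns `start`, `end`) or a list
#'   with `start`/`end`.
#' @param flank Flank size in bp (>= 0).
#' @param chrom_length Chromosome length in bp, or `NA` when unknown (then
#'   the upper bound is `end + flank`).
#' @return Integer vector `c(start, end)`, 0-based half-open.
#' @export
gene_vicinity <- function(gene, flank = 2000, chrom_length = NA) {
  if (!is.numeric(flank) || length(flank) != 1L || flank < 0) {
    tnt_validation_error("flank must be a single nonnegative number")
  }
  lo <- max(0L, as.integer(gene$start) - as.integer(flank))
  hi <- as.integer(gene$end) + as.integer(flank)
  if (!is.na(chrom_length)) hi <- min(as.integer(chrom_length), hi)
  c(start = lo, end = hi)
}

# Per-gene copy count and union-merged covered bp for one set of TE copies,
# vicinities given as a GRanges. Returns list(n, lte) of vectors.
overlap_stats <- function(vic_gr, te_df) {
  n <- integer(length(vic_gr))
  lte <- integer(length(vic_gr))
  if (nrow(te_df) == 0) return(list(n = n, lte = lte))
  te_gr <- as_granges0(te_df)
  hits <- GenomicRanges::findOverlaps(vic_gr, te_gr, minoverlap = 1L)
  if (!length(hits)) return(list(n = n, lte = lte))
  q <- queryHits(hits)
  s <- subjectHits(hits)
  cnt <- table(q)
  n[as.integer(names(cnt))] <- as.integer(cnt)
  clipped <- IRanges::pintersect(
    GenomicRanges::ranges(vic_gr)[q], GenomicRanges::ranges(te_gr)[s]
  )
  # union-merge clipped copies within each gene
  byg <- split(clipped, q)
  cov <- vapply(byg, function(r) sum(IRanges::width(IRanges::reduce(r))), integer(1))
  lte[as.integer(names(byg))] <- cov
  list(n = n, lte = lte)
}

#' Per-gene TE density and coverage
#'
#' For every gene, computes over its vicinity (gene body plus `flank` bp on
#' each side) the TE copy count `N`, the union-merged TE-covered length
#' `L_TE` (copies clipped to the vicinity so coverage never exceeds 1), the
#' density `D = N / (L_g - L_TE)` in copies per non-TE bp, and the coverage
#' `C = L_TE / L_g` -- overall (`all`) and per TE class (`DNA`, `LTR`,
#' `LINE`, `SINE`). A copy counts if it overlaps the vicinity by at least
#' 1 bp; a copy overlapping two genes' vicinities counts for both. When a
#' vicinity is entirely TE-covered the density is undefined and reported as
#' `NA` (the gene remains classifiable by coverage).
#'
#' @param genes Gene table (`gene_id`, `chrom`, `start`, `end`).
#' @param tes TE table (`chrom`, `start`, `end`, `te_class`).
#' @param flank Flank size in bp, default 2000.
#' @param chrom_lengths Optional named vector of chromosome lengths used to
#'   clamp vicinities.
#' @return A `data.frame` with one row per gene: `gene_id`, `region_start`,
#'   `region_end`, `L_g`, then for each scope `s` in
#'   `all, DNA, LTR, LINE, SINE`: `n_<s>`, `lte_<s>`, `density_<s>`,
#'   `coverage_<s>`.
#' @export
te_metrics <- function(genes, tes, flank = 2000, chrom_lengths = NULL) {
  if (nrow(genes) == 0) {
    tnt_validation_error("no genes supplied")
  }
  cl <- if (is.null(chrom_lengths)) rep(NA_integer_, nrow(genes)) else
    unname(chrom_lengths[genes$chrom])
  region_start <- pmax(0L, genes$start - as.integer(flank))
  region_end <- genes$end + as.integer(flank)
  region_end <- ifelse(is.na(cl), region_end, pmin(as.integer(cl), region_end))
  out <- data.frame(
    gene_id = genes$gene_id, chrom = genes$chrom,
    region_start = region_start, region_end = region_end,
    L_g = region_end - region_start,
    stringsAsFactors = FALSE
  )
  vic_gr <- GenomicRanges::GRanges(
    seqnames = genes$chrom,
    ranges = IRanges::IRanges(start = region_start + 1L, end = region_end)
  )
  scopes <- c(list(all = tes), lapply(
    setNames(TE_CLASSES, TE_CLASSES),
    function(k) tes[tes$te_class == k, , drop = FALSE]
  ))
  for (s in names(scopes)) {
    st <- overlap_stats(vic_gr, scopes[[s]])
    dens <- ifelse(st$lte < out$L_g, st$n / (out$L_g - st$lte), NA_real_)
    out[[paste0("n_", s)]] <- st$n
    out[[paste0("lte_", s)]] <- st$lte
    out[[paste0("density_", s)]] <- dens
    out[[paste0("coverage_", s)]] <- st$lte / out$L_g
  }
  out
}

#' TE metrics for a single gene
#'
#' Convenience wrapper around [te_metrics()] for one gene; the supplied
#' copies must lie on the gene's chromosome (the caller filters).
#'
#' @inheritParams te_metrics
#' @param gene One-row gene `data.frame`.
#' @param copies TE table.
#' @return One-row metrics `data.frame` (see [te_metrics()]).
#' @export
te_metrics_for_gene <- function(gene, copies, flank = 2000, chrom_lengths = NULL) {
  te_metrics(gene, copies, flank = flank, chrom_lengths = chrom_lengths)
}

#' Spearman correlation between TE density and coverage
#'
#' @param metrics Metrics table from [te_metrics()].
#' @return A list with `rho`, `p`, and `n` (genes with defined density and
#'   coverage). When the correlation is undefined (all-tied input) `rho`
#'   and `p` are `NA`.
#' @export
density_coverage_correlation <- function(metrics) {
  ok <- is.finite(metrics$density_all) & is.finite(metrics$coverage_all)
  d <- metrics$density_all[ok]
  c_ <- metrics$coverage_all[ok]
  if (length(d) < 3) {
    tnt_validation_error("need >= 3 genes with defined density and coverage")
  }
  if (length(unique(d)) == 1 || length(unique(c_)) == 1) {
    return(list(rho = NA_real_, p = NA_real_, n = length(d)))
  }
  ct <- suppressWarnings(cor.test(d, c_, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p = ct$p.value, n = length(d))
}
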