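#' Configuration for per-gene histone enrichment
#'
#' The per-gene summary `epsilon` of broadPeak fold-enrichment values admits
#' three interpretations, selected by `mode`:
#' \describe{
#'   \item{`mean_peak_signal`}{arithmetic mean of the signal of the peaks
#'     overlapping the gene body (default). Yields values on the scale of
#'     the broadPeak signalValue column.}
#'   \item{`literal_E1`}{sum of peak signals divided by `n * l` where `n`
#'     is the number of overlapping peaks and `l` the gene length; a
#'     size-normalized variant whose magnitude is ~1e-4 for typical genes.}
#'   \item{`base_weighted`}{sum of signal times overlap length, divided by
#'     the gene length: a per-base average treating non-peak bases as 0.}
#' }
#' Genes with no overlapping peak get `empty_value` in every mode.
#'
#' @param mode One of `"mean_peak_signal"`, `"literal_E1"`, `"base_weighted"`.
#' @param empty_value Value assigned when no peak overlaps the gene.
#' @return A list of class `tenet_enrichment_config`.
#' @export
enrichment_config <- function(mode = c("mean_peak_signal", "literal_E1", "base_weighted"),
                              empty_value = 0) {
  structure(
    list(mode = match.arg(mode), empty_value = empty_value),
    class = "tenet_enrichment_config"
  )
}

epsilon_from_hits <- function(signal, overlap_bp, l, mode, empty_value) {
  n <- length(signal)
  if (n == 0) return(empty_value)
  switch(mode,
    mean_peak_signal = sum(signal) / n,
    literal_E1 = sum(signal) / (n * l),
    base_weighted = sum(signal * overlap_bp) / l
  )
}

#' Mean histone enrichment of one gene
#'
#' Summarizes the fold-enrichment values of the peaks overlapping the gene
#' body (flanks are not added; >= 1 bp overlap counts). The peaks must be
#' pre-filtered to a single mark, condition and the gene's chromosome.
#'
#' @param gene One-row gene `data.frame` (`start`, `end`).
#' @param peaks Peak table (`start`, `end`, `signal`).
#' @param config An [enrichment_config()].
#' @return A list with `epsilon` and `n_values` (number of contributing
#'   peaks).
#' @export
mean_histone_enrichment <- function(gene, peaks, config = enrichment_config()) {
  l <- gene$end - gene$start
  if (length(l) != 1L || l <= 0) {
    tnt_validation_error("gene length must be positive")
  }
  ov_start <- pmax(peaks$start, gene$start)
  ov_end <- pmin(peaks$end, gene$end)
  hit <- ov_end > ov_start
  eps <- epsilon_from_hits(peaks$signal[hit], (ov_end - ov_start)[hit], l,
                           config$mode, config$empty_value)
  list(epsilon = eps, n_values = sum(hit))
}

#' Per-gene enrichment for every (mark, condition) combination
#'
#' @param genes Gene table.
#' @param peaks Either one peak table with `mark` and `condition` columns,
#'   or a list of such tables (keys are ignored; each element must carry a
#'   single (mark, condition) pair, and pairs must not repeat).
#' @param config An [enrichment_config()].
#' @return A long `data.frame`: `gene_id`, `mark`, `condition`, `epsilon`,
#'   `n_values`, with one row per gene x mark x condition; combinations
#'   with no peaks get `empty_value` and `n_values = 0`.
#' @export
enrichment_matrix <- function(genes, peaks, config = enrichment_config()) {
  if (is.data.frame(peaks)) {
    peak_df <- peaks
  } else {
    keys <- vapply(peaks, function(p) {
      paste(unique(p$mark), unique(p$condition), sep = ":")
    }, character(1))
    if (anyDuplicated(keys)) {
      tnt_validation_error(
        "duplicate (mark, condition) peak sets: %s",
        paste(unique(keys[duplicated(keys)]), collapse = ", ")
      )
    }
    peak_df <- do.call(rbind, peaks)
  }
  l <- genes$end - genes$start
  if (any(l <= 0)) tnt_validation_error("gene length must be positive")
  combos <- unique(peak_df[c("mark", "condition")])
  if (anyDuplicated(combos)) combos <- unique(combos)
  gene_gr <- as_granges0(genes)
  res <- vector("list", nrow(combos))
  for (i in seq_len(nrow(combos))) {
    sel <- peak_df$mark == combos$mark[i] & peak_df$condition == combos$condition[i]
    pk <- peak_df[sel, , drop = FALSE]
    eps <- rep(config$empty_value, nrow(genes))
    nv <- integer(nrow(genes))
    if (nrow(pk)) {
      pk_gr <- as_granges0(pk)
      hits <- GenomicRanges::findOverlaps(gene_gr, pk_gr, minoverlap = 1L)
      if (length(hits)) {
        q <- queryHits(hits)
        s <- subjectHits(hits)
        gi <- sort(unique(q))
        sig_sum <- rowsum(pk$signal[s], q)[, 1]
        n_hit <- rowsum(rep(1L, length(q)), q)[, 1]
        nv[gi] <- n_hit
        eps[gi] <- switch(config$mode,
          mean_peak_signal = sig_sum / n_hit,
          literal_E1 = sig_sum / (n_hit * l[gi]),
          base_weighted = {
            ov <- IRanges::width(IRanges::pintersect(
              GenomicRanges::ranges(gene_gr)[q], GenomicRanges::ranges(pk_gr)[s]
            ))
            rowsum(pk$signal[s] * ov, q)[, 1] / l[gi]
          }
        )
      }
    }
    res[[i]] <- data.frame(
      gene_id = genes$gene_id, mark = combos$mark[i],
      condition = combos$condition[i], epsilon = eps, n_values = nv,
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
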