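# Small constructors and independent oracles shared across tests.

make_genes <- function(starts, ends, chrom = "chr1", ids = NULL) {
  n <- length(starts)
  data.frame(
    gene_id = if (is.null(ids)) sprintf("G%03d", seq_len(n)) else ids,
    chrom = rep_len(chrom, n), start = as.integer(starts),
    end = as.integer(ends), strand = rep_len("+", n),
    stringsAsFactors = FALSE
  )
}

make_tes <- function(starts, ends, te_class = "SINE", chrom = "chr1") {
  n <- length(starts)
  data.frame(
    chrom = rep_len(chrom, n), start = as.integer(starts),
    end = as.integer(ends), strand = rep_len("+", n),
    family = rep_len("fam", n), te_class = rep_len(te_class, n),
    stringsAsFactors = FALSE
  )
}

make_peaks <- function(starts, ends, signal, mark = "H3K4me3",
                       condition = "normal", chrom = "chr1") {
  n <- length(starts)
  data.frame(
    chrom = rep_len(chrom, n), start = as.integer(starts),
    end = as.integer(ends), mark = rep_len(mark, n),
    condition = rep_len(condition, n), signal = as.numeric(signal),
    stringsAsFactors = FALSE
  )
}

# Plain (unadjusted) Rand index between two labelings.
rand_index <- function(a, b) {
  e1071::classAgreement(table(a, b))$rand
}

# Exhaustive k = 2 PAM oracle: minimum total cost over all medoid pairs,
# Euclidean distance on (optionally standardized) features.
brute_pam_cost <- function(x, standardize = TRUE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  if (standardize) {
    x <- scale(x)
    x[is.nan(x)] <- 0
  }
  d <- as.matrix(dist(x))
  pairs <- utils::combn(nrow(x), 2)
  min(apply(pairs, 2, function(m) sum(pmin(d[, m[1]], d[, m[2]]))))
}

# Per-base brute-force oracle for TE metrics of a single gene: marks
# covered bases in the vicinity one copy at a time.
brute_gene_metrics <- function(gene, tes, flank = 2000, chrom_length = NA) {
  lo <- max(0L, gene$start - flank)
  hi <- gene$end + flank
  if (!is.na(chrom_length)) hi <- min(chrom_length, hi)
  L <- hi - lo
  covered <- logical(L)
  n <- 0L
  for (i in seq_len(nrow(tes))) {
    s <- max(tes$start[i], lo)
    e <- min(tes$end[i], hi)
    if (e > s) {
      n <- n + 1L
      covered[(s - lo + 1L):(e - lo)] <- TRUE
    }
  }
  lte <- sum(covered)
  list(L_g = L, n = n, lte = lte,
       coverage = lte / L,
       density = if (lte < L) n / (L - lte) else NA_real_)
}
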