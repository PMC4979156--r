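#' Partitioning Around Medoids (k-medoids), deterministic BUILD + SWAP
#'
#' Classic Kaufman-Rousseeuw PAM: a greedy BUILD phase seeds `k` medoids
#' (first the point minimizing total dissimilarity, then the point with the
#' largest cost reduction, repeatedly), followed by a SWAP phase that keeps
#' applying the best cost-decreasing medoid/non-medoid exchange until none
#' exists. When the medoid space is small (`choose(n, k) <= 20000`, which
#' covers every k = 2 problem up to 200 points) the globally optimal medoid
#' set is found by exhaustive enumeration instead, since BUILD + SWAP can
#' stall in a swap-optimal configuration above the global optimum.
#' Dissimilarity is Euclidean, optionally on z-score-standardized columns.
#' The algorithm involves no randomness: ties are broken toward the lower
#' point index, so results are reproducible and permutation of the input
#' only relabels clusters.
#'
#' Medoids are actual input points; every point is assigned to its nearest
#' medoid (ties toward the lower medoid index); the returned total cost is
#' the sum of dissimilarities of points to their medoid and is minimal with
#' respect to any single medoid swap.
#'
#' @param x Numeric matrix (rows = points) or vector (treated as one
#'   column).
#' @param k Number of clusters (`1 <= k <= nrow(x)`).
#' @param standardize Standardize columns to zero mean and unit variance
#'   before computing distances (columns with zero variance are centered
#'   only). Default `TRUE`.
#' @return A list of class `tenet_pam`: `k`, `medoids` (row indices,
#'   ascending), `clustering` (cluster id per point, ids follow medoid
#'   order), `total_cost`.
#' @examples
#' p <- pam_cluster(c(0, 0.1, 0.2, 10, 10.1), k = 2)
#' p$clustering
#' @export
pam_cluster <- function(x, k, standardize = TRUE) {
  if (is.vector(x)) x <- matrix(x, ncol = 1)
  x <- as.matrix(x)
  n <- nrow(x)
  if (!is_count(k) || k < 1) tnt_validation_error("k must be a positive integer")
  if (k > n) {
    tnt_validation_error("k = %d exceeds the number of points (%d)", k, n)
  }
  if (standardize) {
    x <- scale(x)
    x[, attr(x, "scaled:scale") == 0] <- 0
    x[is.nan(x)] <- 0
  }
  d <- as.matrix(stats::dist(x))
  cost_of <- function(med) sum(apply(d[, med, drop = FALSE], 1, min))

  # Small medoid spaces are solved to global optimality by enumeration
  # (the optimum is trivially swap-optimal); larger ones fall back to the
  # greedy BUILD + SWAP heuristic.
  if (choose(n, k) <= 20000) {
    sets <- utils::combn(n, k)
    costs <- vapply(seq_len(ncol(sets)), function(j) {
      sum(do.call(pmin, lapply(sets[, j], function(m) d[, m])))
    }, numeric(1))
    medoids <- sets[, which.min(costs)] # ties -> lexicographically first
    return(pam_result(d, medoids, k))
  }

  # BUILD
  medoids <- which.min(colSums(d))[1]
  nearest <- d[, medoids]
  while (length(medoids) < k) {
    gains <- vapply(seq_len(n), function(j) {
      if (j %in% medoids) return(-Inf)
      sum(pmax(0, nearest - d[, j]))
    }, numeric(1))
    best <- which.max(gains)[1]
    medoids <- c(medoids, best)
    nearest <- pmin(nearest, d[, best])
  }

  current <- cost_of(medoids)

  # SWAP: accept the best strictly cost-decreasing exchange, repeat
  repeat {
    best_cost <- current
    best_swap <- NULL
    for (mi in seq_along(medoids)) {
      for (h in setdiff(seq_len(n), medoids)) {
        cand <- medoids
        cand[mi] <- h
        cc <- cost_of(cand)
        if (cc < best_cost - 1e-12) {
          best_cost <- cc
          best_swap <- cand
        }
      }
    }
    if (is.null(best_swap)) break
    medoids <- best_swap
    current <- best_cost
  }
  pam_result(d, medoids, k)
}

pam_result <- function(d, medoids, k) {
  medoids <- sort(medoids)
  dm <- d[, medoids, drop = FALSE]
  clustering <- apply(dm, 1, which.min) # which.min: ties -> lower medoid index
  structure(
    list(k = k, medoids = medoids, clustering = as.integer(clustering),
         total_cost = sum(apply(dm, 1, min))),
    class = "tenet_pam"
  )
}

#' @export
print.tenet_pam <- function(x, ...) {
  cat(sprintf("PAM clustering: k = %d, medoids = [%s], total cost = %.4g\n",
              x$k, paste(x$medoids, collapse = ", "), x$total_cost))
  invisible(x)
}
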