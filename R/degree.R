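## Composite weighted degree over a proportional-threshold sweep, with
## within-/between-network decomposition.

#' Default edge-density sweep
#'
#' Sparsity thresholds of 2-10% edge density in 1% increments, the range used
#' to make composite degree robust to any single threshold choice.
#'
#' @return numeric vector `seq(0.02, 0.10, by = 0.01)`.
#' @export
densitySweep <- function() seq(0.02, 0.10, by = 0.01)

checkSweep <- function(sweep) {
  .assert(length(sweep) > 0, "sweep must be nonempty")
  .assert(all(sweep > 0 & sweep <= 1), "densities must be in (0, 1]")
  .assert(all(diff(sweep) > 0), "densities must be strictly increasing")
}

## ranks of off-diagonal edges: weight descending, ties by ascending (i, j)
edgeOrder <- function(w) {
  n <- nrow(w)
  ut <- which(upper.tri(w))
  i <- ((ut - 1L) %% n) + 1L
  j <- ((ut - 1L) %/% n) + 1L
  ord <- order(-w[ut], i, j)
  list(ut = ut[ord], n = n)
}

#' Proportional (edge-density) threshold
#'
#' Retains the `m = max(1, floor(density * n(n-1)/2))` strongest off-diagonal
#' edges (ties broken deterministically by ascending row then column index),
#' keeping their weights; all other edges become 0.
#'
#' @param C a [ConnectivityMatrix-class] or symmetric matrix.
#' @param density fraction of the `n(n-1)/2` possible edges to retain, in
#'   (0, 1].
#' @return a [ConnectivityMatrix-class] at the requested density.
#' @export
proportionalThreshold <- function(C, density) {
  w <- if (is(C, "ConnectivityMatrix")) connWeights(C) else as.matrix(C)
  .assert(length(density) == 1L && density > 0 && density <= 1,
          "density must be in (0, 1]")
  if (all(w[upper.tri(w)] == 0))
    warning("all-zero connectivity matrix; threshold returns an empty graph")
  eo <- edgeOrder(w)
  nEdges <- length(eo$ut)
  m <- max(1L, floor(density * nEdges))
  keep <- eo$ut[seq_len(min(m, nEdges))]
  out <- matrix(0, eo$n, eo$n, dimnames = dimnames(w))
  out[keep] <- w[keep]
  out <- out + t(out)
  ConnectivityMatrix(out)
}

#' Weighted degree
#'
#' `k_i = sum_j a_ij`: the sum of a node's edge weights in the (thresholded)
#' connectivity matrix.
#'
#' @param C a [ConnectivityMatrix-class] or symmetric matrix.
#' @return numeric vector of per-parcel degree.
#' @export
weightedDegree <- function(C) {
  w <- if (is(C, "ConnectivityMatrix")) connWeights(C) else as.matrix(C)
  rowSums(w)
}

#' Composite weighted degree over a density sweep
#'
#' Thresholds the matrix at each density in the sweep and sums the resulting
#' weighted degrees, so an edge contributes its weight once per density at
#' which it survives.
#'
#' @param C a [ConnectivityMatrix-class] or symmetric matrix.
#' @param sweep strictly increasing densities in (0, 1]; default
#'   [densitySweep()].
#' @return numeric vector of per-parcel composite degree.
#' @export
compositeDegree <- function(C, sweep = densitySweep()) {
  checkSweep(sweep)
  w <- if (is(C, "ConnectivityMatrix")) connWeights(C) else as.matrix(C)
  k <- numeric(nrow(w))
  for (d in sweep)
    k <- k + weightedDegree(proportionalThreshold(w, d))
  names(k) <- rownames(w)
  k
}

#' Within- and between-network degree decomposition
#'
#' The full matrix is thresholded at each density of the sweep; each surviving
#' edge is then classed by whether its endpoints share a network label.
#' `within + between` equals the composite total degree exactly.
#'
#' @param C a [ConnectivityMatrix-class] or symmetric matrix.
#' @param parcellation a [Parcellation-class] matching `C`.
#' @param sweep density sweep (default [densitySweep()]).
#' @return list with numeric vectors `within`, `between`, `total`.
#' @export
partitionDegree <- function(C, parcellation, sweep = densitySweep()) {
  checkSweep(sweep)
  w <- if (is(C, "ConnectivityMatrix")) connWeights(C) else as.matrix(C)
  .assert(nrow(w) == nParcels(parcellation),
          "parcellation does not match the connectivity matrix")
  net <- networks(parcellation)
  same <- outer(net, net, "==")
  within <- numeric(nrow(w)); between <- numeric(nrow(w))
  for (d in sweep) {
    wt <- connWeights(proportionalThreshold(w, d))
    within <- within + rowSums(wt * same)
    between <- between + rowSums(wt * !same)
  }
  names(within) <- names(between) <- rownames(w)
  list(within = within, between = between, total = within + between)
}
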