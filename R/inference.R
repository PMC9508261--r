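## Permutation-based group and brain-behavior inference with BH-FDR control,
## effect sizes, and classical two-sample t tests.

## accept a DegreeExperiment (parcels x subjects) or a subjects x parcels
## matrix; return subjects x parcels plus parcel metadata
.degreeMatrix <- function(degrees) {
  if (is(degrees, "DegreeExperiment")) {
    X <- t(assay(degrees, "total"))
    ids <- seq_len(ncol(X))
    net <- rowData(degrees)$network
  } else {
    X <- as.matrix(degrees)
    ids <- seq_len(ncol(X))
    net <- rep(NA_character_, ncol(X))
  }
  .assert(!anyNA(X), "degree matrix must not contain NA")
  list(X = X, parcel_id = ids, network = net)
}

#' Cohen's d (pooled standard deviation)
#'
#' `(mean(a) - mean(b)) / s_p` with the pooled SD using an `n_a + n_b - 2`
#' denominator.
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @return the standardized mean difference.
#' @export
cohensD <- function(a, b) {
  .assert(length(a) >= 2L && length(b) >= 2L, "each group needs >= 2 values")
  sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
    (length(a) + length(b) - 2)
  .assert(sp2 > 0, "pooled SD is zero; Cohen's d is undefined")
  (mean(a) - mean(b)) / sqrt(sp2)
}

#' Benjamini-Hochberg false discovery rate control
#'
#' Step-up adjusted q values via `stats::p.adjust(method = "BH")`; rejection at
#' `q <= alpha`.
#'
#' @param p numeric p values in [0,1].
#' @param alpha FDR level.
#' @return list with `q` and logical `reject`.
#' @export
bhFDR <- function(p, alpha = 0.05) {
  if (length(p) == 0L) return(list(q = numeric(0), reject = logical(0)))
  .assert(all(p >= 0 & p <= 1), "p values must lie in [0,1]")
  q <- p.adjust(p, method = "BH")
  list(q = q, reject = q <= alpha)
}

## shared permutation schedule: one label/behavior shuffle per row, reused
## across all parcels so the null preserves cross-parcel dependence
permutationSchedule <- function(n, nPerm, seed) {
  withSeed(seed, t(replicate(nPerm, sample.int(n))))
}

#' Permutation test for group differences in degree
#'
#' Per parcel the statistic is the difference of group means of composite
#' degree (first factor level minus second). The null is built from `nPerm`
#' random reassignments of the group labels, shared across parcels. The
#' two-tailed p is the plain proportion of permuted |differences| at least as
#' large as the observed |difference| (p = 0 is possible; set
#' `addOne = TRUE` for the (b+1)/(m+1) variant). q values are BH-adjusted
#' across parcels and Cohen's d is attached.
#'
#' @param degrees a [DegreeExperiment-class] or subjects x parcels matrix.
#' @param labels group label per subject (two levels).
#' @param nPerm number of permutations (>= 100; default 5000).
#' @param seed integer seed for the permutation schedule.
#' @param alpha FDR level for the significance flag (default 0.05).
#' @param alternative `"two.sided"` (default, absolute differences) or
#'   `"greater"` (one-sided on the signed difference).
#' @param addOne use the (b+1)/(m+1) small-sample correction.
#' @return an [AssociationResult-class] of type `"group"`.
#' @export
groupPermutationTest <- function(degrees, labels, nPerm = 5000L, seed = 1L,
                                 alpha = 0.05,
                                 alternative = c("two.sided", "greater"),
                                 addOne = FALSE) {
  alternative <- match.arg(alternative)
  dm <- .degreeMatrix(degrees)
  X <- dm$X
  f <- factor(labels)
  .assert(nlevels(f) == 2L, "exactly two groups are required")
  .assert(all(table(f) >= 2L), "each group needs >= 2 subjects")
  .assert(nPerm >= 100L, "nPerm must be >= 100")
  .assert(length(f) == nrow(X), "one label per subject is required")
  gA <- f == levels(f)[1L]
  w <- ifelse(gA, 1 / sum(gA), -1 / sum(!gA))
  obs <- colMeans(X[gA, , drop = FALSE]) - colMeans(X[!gA, , drop = FALSE])
  sched <- permutationSchedule(nrow(X), nPerm, seed)
  W <- matrix(w[t(sched)], nrow = nPerm, byrow = TRUE)
  nullDiff <- W %*% X
  if (alternative == "two.sided") {
    b <- colSums(abs(nullDiff) >= matrix(abs(obs), nPerm, ncol(X), byrow = TRUE))
  } else {
    b <- colSums(nullDiff >= matrix(obs, nPerm, ncol(X), byrow = TRUE))
  }
  p <- if (addOne) (b + 1) / (nPerm + 1) else b / nPerm
  se <- apply(nullDiff, 2, sd)
  z <- ifelse(se > 0, obs / se, 0)
  fdr <- bhFDR(p, alpha)
  d <- vapply(seq_len(ncol(X)), function(j)
    cohensD(X[gA, j], X[!gA, j]), numeric(1))
  tb <- data.frame(parcel_id = dm$parcel_id, network = dm$network,
                   statistic = obs, d = d, se = se, z = z, p = p,
                   q = fdr$q, significant = fdr$reject)
  new("AssociationResult", table = tb, type = "group",
      nPerm = as.integer(nPerm), seed = as.integer(seed), alpha = alpha)
}

#' Permutation-calibrated degree-behavior correlation test
#'
#' Per parcel, Pearson r between composite degree and the behavioral outcome.
#' `nPerm` behavior reshuffles estimate the standard error of r at each node;
#' z = r / SE gives a two-tailed normal p, BH-adjusted across parcels. A
#' parcel is flagged significant when q falls below `familyAlpha` (default
#' 0.025, the Bonferroni-corrected threshold for the two behavioral outcomes:
#' accuracy and reaction time).
#'
#' @param degrees a [DegreeExperiment-class] or subjects x parcels matrix.
#' @param behavior numeric outcome per subject (no missing values).
#' @param nPerm permutations for the SE estimate (default 5000).
#' @param seed integer seed.
#' @param familyAlpha familywise threshold applied to q.
#' @return an [AssociationResult-class] of type `"correlation"`.
#' @export
correlationPermutationTest <- function(degrees, behavior, nPerm = 5000L,
                                       seed = 1L, familyAlpha = 0.025) {
  dm <- .degreeMatrix(degrees)
  X <- dm$X
  n <- nrow(X)
  .assert(n >= 5L, "need at least 5 subjects")
  .assert(length(behavior) == n, "one behavior value per subject is required")
  .assert(!anyNA(behavior), "behavior must not contain missing values")
  .assert(sd(behavior) > 0, "behavior has zero variance")
  .assert(nPerm >= 100L, "nPerm must be >= 100")
  sds <- apply(X, 2, sd)
  flat <- sds == 0
  if (any(flat))
    warning(sprintf("%d constant degree column(s); their r set to 0", sum(flat)))
  Xs <- scale(X)
  Xs[, flat] <- 0
  bs <- as.vector(scale(behavior))
  r <- as.vector(crossprod(bs, Xs)) / (n - 1)
  sched <- permutationSchedule(n, nPerm, seed)
  B <- matrix(bs[t(sched)], nrow = nPerm, byrow = TRUE)
  nullR <- (B %*% Xs) / (n - 1)
  se <- apply(nullR, 2, sd)
  z <- ifelse(se > 0, r / se, 0)
  p <- 2 * pnorm(-abs(z))
  fdr <- bhFDR(p, familyAlpha)
  tb <- data.frame(parcel_id = dm$parcel_id, network = dm$network,
                   statistic = r, se = se, z = z, p = p, q = fdr$q,
                   significant = fdr$q < familyAlpha)
  new("AssociationResult", table = tb, type = "correlation",
      nPerm = as.integer(nPerm), seed = as.integer(seed), alpha = familyAlpha)
}

#' Two-sample t test from summary statistics or raw samples
#'
#' The pooled-variance (classical) two-sample t test by default; Welch via
#' `variant = "welch"`. Usable directly on published group summaries
#' (mean, SD, n per group) as well as raw vectors through [tTestTwoSample()].
#'
#' @param meanA,sdA,nA,meanB,sdB,nB group summaries.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return list with `t`, `df`, `p` (two-tailed), `variant`.
#' @export
tTestSummary <- function(meanA, sdA, nA, meanB, sdB, nB,
                         variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  .assert(nA >= 2 && nB >= 2, "each group needs n >= 2")
  .assert(sdA > 0 && sdB > 0, "group SDs must be positive")
  if (variant == "pooled") {
    sp2 <- ((nA - 1) * sdA^2 + (nB - 1) * sdB^2) / (nA + nB - 2)
    tstat <- (meanA - meanB) / sqrt(sp2 * (1 / nA + 1 / nB))
    df <- nA + nB - 2
  } else {
    vA <- sdA^2 / nA; vB <- sdB^2 / nB
    tstat <- (meanA - meanB) / sqrt(vA + vB)
    df <- (vA + vB)^2 / (vA^2 / (nA - 1) + vB^2 / (nB - 1))
  }
  list(t = tstat, df = df, p = 2 * pt(-abs(tstat), df), variant = variant)
}

#' @rdname tTestSummary
#' @param a,b raw samples (delegates to [stats::t.test()]).
#' @export
tTestTwoSample <- function(a, b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  ht <- t.test(a, b, var.equal = variant == "pooled")
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, variant = variant)
}
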