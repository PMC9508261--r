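## Degree-based connectome predictive modeling (CPM): feature selection by
## training-set correlation, a combined summary score, LOOCV prediction and
## permutation significance.

## vectorized per-parcel Pearson r and parametric two-tailed p
.corWithP <- function(X, y) {
  n <- nrow(X)
  Xc <- X - rep(colMeans(X), each = n)
  sx <- sqrt(colSums(Xc^2))
  yc <- y - mean(y)
  sy <- sqrt(sum(yc^2))
  ok <- sx > 0 & sy > 0
  r <- numeric(ncol(X))
  if (any(ok))
    r[ok] <- as.vector(crossprod(yc, Xc[, ok, drop = FALSE])) / (sx[ok] * sy)
  r <- pmin(pmax(r, -1), 1)
  tstat <- r * sqrt((n - 2) / pmax(1 - r^2, 1e-12))
  p <- 2 * pt(-abs(tstat), n - 2)
  p[!ok] <- 1
  list(r = r, p = p, constant = sx == 0)
}

#' CPM feature selection
#'
#' Correlates every parcel's degree with behavior over the training subjects;
#' the positive set collects parcels with `r > 0` and parametric two-tailed
#' `p < pSelect`, the negative set those with `r < 0` and `p < pSelect`.
#' Constant features are excluded with a warning.
#'
#' @param trainDegrees training subjects x parcels degree matrix.
#' @param trainBehavior behavior of the training subjects.
#' @param pSelect selection threshold on the parametric p (default 0.01).
#' @return list with integer vectors `positive`, `negative` and the per-parcel
#'   `r` and `p`.
#' @export
cpmSelect <- function(trainDegrees, trainBehavior, pSelect = 0.01) {
  X <- as.matrix(trainDegrees)
  .assert(nrow(X) >= 5L, "need at least 5 training subjects")
  .assert(length(trainBehavior) == nrow(X), "behavior length must match subjects")
  cp <- .corWithP(X, trainBehavior)
  if (any(cp$constant))
    warning(sprintf("%d constant feature(s) excluded from selection",
                    sum(cp$constant)))
  sel <- cp$p < pSelect & !cp$constant
  list(positive = which(sel & cp$r > 0),
       negative = which(sel & cp$r < 0),
       r = cp$r, p = cp$p)
}

#' CPM combined summary score
#'
#' For each subject, the sum of degree over the positive feature set minus the
#' sum over the negative set.
#'
#' @param degrees subjects x parcels degree matrix.
#' @param positive,negative disjoint integer parcel-index sets.
#' @return numeric score per subject.
#' @export
cpmSummaryScore <- function(degrees, positive, negative) {
  X <- as.matrix(degrees)
  .assert(length(intersect(positive, negative)) == 0L,
          "positive and negative sets must be disjoint")
  pos <- if (length(positive)) rowSums(X[, positive, drop = FALSE]) else numeric(nrow(X))
  neg <- if (length(negative)) rowSums(X[, negative, drop = FALSE]) else numeric(nrow(X))
  as.numeric(pos - neg)
}

## one full LOOCV pass; returns predicted values and per-fold feature sets.
## Per-fold training correlations are computed by leave-one-out downdating of
## the full-sample sums (O(nP) per pass instead of O(n^2 P)), which matters
## because the significance test reruns the whole pass inside every
## permutation. Data are centered first so the downdates are numerically
## stable.
.loocvPass <- function(X, y, pSelect) {
  n <- nrow(X)
  Xc <- X - rep(colMeans(X), each = n)
  yc <- y - mean(y)
  Sxx <- colSums(Xc^2)
  Sxy <- as.vector(crossprod(Xc, yc))
  Syy <- sum(yc^2)
  m <- n - 1
  predicted <- numeric(n)
  folds <- vector("list", n)
  vfloor <- 1e-12 * max(Sxx, 1e-300)
  ## all folds at once: row i holds the training moments with subject i out
  vxM <- (rep(Sxx, each = n) - Xc^2) - Xc^2 / m   # training sums are -Xc[i,]
  cvM <- (rep(Sxy, each = n) - Xc * yc) - (Xc * yc) / m
  vyV <- (Syy - yc^2) - yc^2 / m
  okM <- vxM > vfloor & vyV > 0
  rM <- cvM / sqrt(vxM * vyV)
  rM[!okM] <- 0
  ## p < pSelect on the training t statistic is |r| > rCrit (df = m - 2)
  tCrit <- qt(1 - pSelect / 2, m - 2)
  rCrit <- tCrit / sqrt(m - 2 + tCrit^2)
  selM <- okM & abs(rM) > rCrit
  ySum <- sum(y)
  for (i in seq_len(n)) {
    positive <- which(selM[i, ] & rM[i, ] > 0)
    negative <- which(selM[i, ] & rM[i, ] < 0)
    folds[[i]] <- list(positive = positive, negative = negative)
    meanTr <- (ySum - y[i]) / m
    if (length(positive) + length(negative) == 0L) {
      predicted[i] <- meanTr      # empty-feature fold: fall back to the mean
      folds[[i]]$empty <- TRUE
      next
    }
    scoreAll <- numeric(n)
    if (length(positive))
      scoreAll <- scoreAll + rowSums(X[, positive, drop = FALSE])
    if (length(negative))
      scoreAll <- scoreAll - rowSums(X[, negative, drop = FALSE])
    strain <- scoreAll[-i]
    vs <- var(strain)
    if (vs == 0) {
      predicted[i] <- meanTr      # degenerate training regression
      folds[[i]]$degenerate <- TRUE
      next
    }
    ytr <- y[-i]
    slope <- cov(strain, ytr) / vs
    predicted[i] <- meanTr + slope * (scoreAll[i] - mean(strain))
  }
  list(predicted = predicted, folds = folds)
}

.predictionR <- function(predicted, observed) {
  if (sd(predicted) == 0 || sd(observed) == 0) return(0)
  cor(predicted, observed)
}

#' Leave-one-out cross-validated degree-based prediction
#'
#' For each fold, feature selection ([cpmSelect()]), the combined summary
#' score ([cpmSummaryScore()]) and a one-variable least-squares line (behavior
#' on score) are built on the N-1 training subjects only; the held-out
#' subject's behavior is predicted from its own score. Predictive power is the
#' Pearson correlation between predicted and observed behavior across all N
#' folds; per-parcel prevalence is the fraction of folds selecting the parcel
#' into either set. With `nPerm > 0` a permutation p is attached via
#' [cpmSignificance()].
#'
#' @param degrees a [DegreeExperiment-class] or subjects x parcels matrix.
#' @param behavior numeric outcome per subject.
#' @param pSelect selection threshold (default 0.01).
#' @param nPerm permutations for significance (0 = skip; default 1000 in
#'   [cpmSignificance()]).
#' @param seed integer seed (permutation schedule only; LOOCV itself is
#'   deterministic).
#' @return a [PredictionResult-class].
#' @export
cpmLOOCV <- function(degrees, behavior, pSelect = 0.01, nPerm = 0L, seed = 1L) {
  dm <- .degreeMatrix(degrees)
  X <- dm$X
  n <- nrow(X)
  .assert(n >= 10L, "LOOCV needs at least 10 subjects")
  .assert(length(behavior) == n, "one behavior value per subject is required")
  .assert(!anyNA(behavior), "behavior must not contain missing values")
  pass <- .loocvPass(X, behavior, pSelect)
  score <- {
    sel <- suppressWarnings(cpmSelect(X, behavior, pSelect))
    cpmSummaryScore(X, sel$positive, sel$negative)
  }
  selCount <- integer(ncol(X))
  for (f in pass$folds) {
    idx <- c(f$positive, f$negative)
    selCount[idx] <- selCount[idx] + 1L
  }
  r <- .predictionR(pass$predicted, behavior)
  p <- NA_real_
  if (nPerm > 0L)
    p <- cpmSignificance(X, behavior, observedR = r, pSelect = pSelect,
                         nPerm = nPerm, seed = seed)
  new("PredictionResult", observed = as.numeric(behavior),
      predicted = pass$predicted, score = score, r = r, p = p,
      prevalence = selCount / n, folds = pass$folds,
      pSelect = pSelect, nPerm = as.integer(nPerm), seed = as.integer(seed))
}

#' Permutation significance of the LOOCV prediction
#'
#' Behavior is reshuffled `nPerm` times and the full LOOCV (selection, scoring
#' and regression per fold) is rerun on each shuffle; p is the plain
#' proportion of null prediction correlations at least as large as the
#' observed one.
#'
#' @param degrees subjects x parcels degree matrix (or
#'   [DegreeExperiment-class]).
#' @param behavior numeric outcome per subject.
#' @param observedR the observed prediction correlation (computed via
#'   [cpmLOOCV()] if omitted).
#' @param pSelect selection threshold.
#' @param nPerm number of permutations (>= 100; default 1000).
#' @param seed integer seed.
#' @return the permutation p value.
#' @export
cpmSignificance <- function(degrees, behavior, observedR = NULL,
                            pSelect = 0.01, nPerm = 1000L, seed = 1L) {
  dm <- .degreeMatrix(degrees)
  X <- dm$X
  .assert(nPerm >= 100L, "nPerm must be >= 100")
  if (is.null(observedR))
    observedR <- .predictionR(.loocvPass(X, behavior, pSelect)$predicted, behavior)
  sched <- permutationSchedule(nrow(X), nPerm, seed)
  nullR <- vapply(seq_len(nPerm), function(b) {
    yb <- behavior[sched[b, ]]
    .predictionR(.loocvPass(X, yb, pSelect)$predicted, yb)
  }, numeric(1))
  mean(nullR >= observedR)
}
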