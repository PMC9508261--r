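## Motion QC, confound regression, band-pass filtering and Fisher-z
## connectivity.

#' Framewise displacement from six rigid-body parameters
#'
#' FD at volume t is the sum of the absolute backward differences of the six
#' realignment parameters, with the three rotations converted to arc length on
#' a 50 mm sphere (the standard head-radius convention): `FD_t =
#' sum(|d trans|) + 50 * sum(|d rot|)`. FD of the first volume is 0.
#'
#' @param motion T x 6 matrix: columns 1-3 rotations (radians), 4-6
#'   translations (mm).
#' @param radius rotation-to-arc conversion radius in mm.
#' @return numeric vector of length T (mm).
#' @export
framewiseDisplacement <- function(motion, radius = 50) {
  motion <- as.matrix(motion)
  .assert(ncol(motion) == 6L, "motion trace must have 6 columns (3 rotations, 3 translations)")
  .assert(nrow(motion) >= 2L, "need at least 2 volumes")
  d <- abs(diff(motion))
  fd <- c(0, rowSums(d[, 4:6, drop = FALSE]) + radius * rowSums(d[, 1:3, drop = FALSE]))
  fd
}

#' Motion quality control: exclusion and scrubbing
#'
#' A subject is excluded when mean FD over the run exceeds `meanThreshold`
#' (0.25 mm); individual volumes with FD above `scrubThreshold` (0.5 mm) are
#' scrubbed, i.e. dropped from the connectivity computation only.
#'
#' @param fd numeric FD series (mm), e.g. from [framewiseDisplacement()].
#' @param meanThreshold subject-exclusion threshold on mean FD (mm).
#' @param scrubThreshold per-volume scrub threshold (mm).
#' @return list: `include` (logical), `meanFD`, `keepMask` (logical per
#'   volume, FALSE = scrubbed), `scrubbedFraction`.
#' @export
motionQC <- function(fd, meanThreshold = 0.25, scrubThreshold = 0.5) {
  .assert(all(fd >= 0), "FD must be nonnegative")
  keep <- fd <= scrubThreshold
  list(include = mean(fd) <= meanThreshold,
       meanFD = mean(fd),
       keepMask = keep,
       scrubbedFraction = mean(!keep))
}

## Butterworth band-pass applied forward and backward (zero phase)
bandpassFilter <- function(x, tr, low, high, order = 2L) {
  nyquist <- 1 / (2 * tr)
  .assert(low >= 0 && low < high, "need 0 <= low < high")
  .assert(high < nyquist,
          sprintf("high cutoff %.4g Hz must be below Nyquist %.4g Hz", high, nyquist))
  bf <- signal::butter(order, c(low, high) / nyquist, type = "pass")
  apply(as.matrix(x), 2, function(col) signal::filtfilt(bf, col))
}

#' Regress confounds and band-pass filter parcel time series
#'
#' Each parcel's series is replaced by its residual from an ordinary
#' least-squares fit on an intercept plus the confound columns (motion
#' parameters, global signal, tissue regressors, ...), then band-pass filtered
#' with a zero-phase (forward-backward) Butterworth filter retaining the
#' default 0.01-0.08 Hz band. Collinear confound columns are dropped with a
#' warning.
#'
#' @param ts T x n matrix of parcel signals.
#' @param tr repetition time in seconds.
#' @param confounds optional T x q matrix of nuisance regressors.
#' @param bandLow,bandHigh passband edges in Hz; `bandHigh` must be below the
#'   Nyquist frequency `1/(2 tr)`.
#' @param order Butterworth order (applied twice, so the effective
#'   attenuation is doubled).
#' @return T x n matrix of cleaned signals (approximately zero mean).
#' @export
cleanTimeSeries <- function(ts, tr, confounds = NULL,
                            bandLow = 0.01, bandHigh = 0.08, order = 2L) {
  ts <- as.matrix(ts)
  .assert(nrow(ts) >= 10L, "need at least 10 volumes")
  .assert(!anyNA(ts), "time series must not contain NA")
  X <- matrix(1, nrow(ts), 1L)
  if (!is.null(confounds)) {
    confounds <- as.matrix(confounds)
    .assert(nrow(confounds) == nrow(ts),
            "confound table must have one row per volume")
    X <- cbind(X, confounds)
    q <- qr(X)
    if (q$rank < ncol(X)) {
      drop <- q$pivot[(q$rank + 1L):ncol(X)]
      warning(sprintf("dropping %d collinear confound column(s)", length(drop)))
      X <- X[, -drop, drop = FALSE]
    }
  }
  resid <- ts - X %*% qr.solve(qr(X), ts)
  out <- bandpassFilter(resid, tr = tr, low = bandLow, high = bandHigh,
                        order = order)
  out <- out - rep(colMeans(out), each = nrow(out))  # re-center filter edges
  dimnames(out) <- dimnames(ts)
  out
}

#' Fisher-z connectivity matrix from parcel time series
#'
#' Pairwise Pearson correlation over the kept volumes, Fisher z-transformed
#' (`atanh`, with r clipped to +/-(1 - 1e-7) so degenerate inputs stay
#' finite), negative entries set to zero and the diagonal zeroed. Parcels with
#' zero variance get all their edges set to zero with a warning.
#'
#' @param ts T x n matrix of (cleaned) parcel signals.
#' @param keepMask optional logical vector: volumes entering the correlation
#'   (FALSE = scrubbed). At least 10 volumes must remain.
#' @return a [ConnectivityMatrix-class].
#' @export
connectivityMatrix <- function(ts, keepMask = NULL) {
  ts <- as.matrix(ts)
  if (!is.null(keepMask)) {
    .assert(length(keepMask) == nrow(ts), "keepMask length must equal T")
    ts <- ts[keepMask, , drop = FALSE]
  }
  .assert(nrow(ts) >= 10L, "fewer than 10 volumes remain after scrubbing")
  sds <- apply(ts, 2, sd)
  flat <- sds == 0 | !is.finite(sds)
  if (any(flat)) {
    warning(sprintf("%d zero-variance parcel(s); their edges set to 0", sum(flat)))
    ts[, flat] <- seq_len(nrow(ts))  # placeholder so cor() is finite; zeroed below
  }
  r <- cor(ts)
  r[flat, ] <- 0
  r[, flat] <- 0
  r <- pmin(pmax(r, -(1 - 1e-7)), 1 - 1e-7)
  z <- atanh(r)
  z[z < 0] <- 0
  diag(z) <- 0
  z <- (z + t(z)) / 2
  ConnectivityMatrix(z)
}
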