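## Behavioral outcomes: per-load accuracy/RT assembly and the group
## comparison table.

#' Combine per-load outcomes into overall accuracy and reaction time
#'
#' Combined accuracy is the unweighted mean over the available loads; combined
#' reaction time is the trial-count-weighted mean when per-load trial counts
#' are supplied (probes averaged over all trials and loads), otherwise the
#' plain mean over loads.
#'
#' @param perf data.frame (one row per subject) with columns `acc_<load>` and
#'   `rt_<load>` for loads among 1/3/5/7.
#' @param loads loads expected to be present (default `c(1, 3, 5, 7)`); a
#'   declared subset is allowed.
#' @param trialCounts optional named numeric per-load trial counts (e.g.
#'   `c("1" = 28, ...)`), used to weight the RT average.
#' @return data.frame with `acc_combined` and `rt_combined` appended.
#' @export
combineOutcomes <- function(perf, loads = c(1L, 3L, 5L, 7L),
                            trialCounts = NULL) {
  .assert(length(loads) >= 1L, "at least one load must be declared")
  .assert(all(loads %in% c(1L, 3L, 5L, 7L)), "loads must be among 1/3/5/7")
  accCols <- paste0("acc_", loads)
  rtCols <- paste0("rt_", loads)
  .assert(all(c(accCols, rtCols) %in% names(perf)),
          "missing per-load accuracy/RT columns for the declared loads")
  acc <- as.matrix(perf[, accCols, drop = FALSE])
  .assert(all(acc >= 0 & acc <= 100, na.rm = TRUE), "accuracy must lie in [0,100]")
  rt <- as.matrix(perf[, rtCols, drop = FALSE])
  .assert(all(rt > 0, na.rm = TRUE), "reaction times must be positive")
  wts <- if (is.null(trialCounts)) rep(1, length(loads)) else {
    .assert(all(as.character(loads) %in% names(trialCounts)),
            "trialCounts must cover the declared loads")
    as.numeric(trialCounts[as.character(loads)])
  }
  perf$acc_combined <- as.vector(acc %*% rep(1 / length(loads), length(loads)))
  perf$rt_combined <- as.vector(rt %*% (wts / sum(wts)))
  perf
}

#' Group comparison of behavioral outcomes
#'
#' Two-sample t tests (pooled by default; see [tTestTwoSample()]) comparing
#' the groups per load and for the combined outcome, mirroring the standard
#' demographics/performance table. Subjects missing the outcome are excluded
#' listwise per comparison with a message reporting the count.
#'
#' @param records data.frame with `group` (two levels) plus per-load columns
#'   `acc_<load>` / `rt_<load>` and combined columns (added via
#'   [combineOutcomes()] if absent).
#' @param outcome `"accuracy"` or `"rt"`.
#' @param loads loads to compare (default `c(1, 3, 5, 7)`).
#' @param variant t-test variant, `"pooled"` or `"welch"`.
#' @return data.frame: one row per load plus `"combined"`, with group means,
#'   SDs, ns, t, df and two-tailed p (uncorrected across loads).
#' @export
groupCompare <- function(records, outcome = c("accuracy", "rt"),
                         loads = c(1L, 3L, 5L, 7L),
                         variant = c("pooled", "welch")) {
  outcome <- match.arg(outcome)
  variant <- match.arg(variant)
  f <- factor(records$group)
  .assert(nlevels(f) == 2L, "exactly two groups are required")
  prefix <- if (outcome == "accuracy") "acc_" else "rt_"
  cols <- c(paste0(prefix, loads), paste0(prefix, "combined"))
  if (!paste0(prefix, "combined") %in% names(records))
    records <- combineOutcomes(records, loads = loads)
  lv <- levels(f)
  rows <- lapply(cols, function(cl) {
    v <- records[[cl]]
    ok <- !is.na(v)
    if (any(!ok))
      message(sprintf("%s: %d subject(s) excluded listwise (missing values)",
                      cl, sum(!ok)))
    a <- v[ok & f == lv[1L]]
    b <- v[ok & f == lv[2L]]
    ht <- tTestTwoSample(a, b, variant = variant)
    data.frame(outcome = outcome, load = sub(prefix, "", cl),
               mean_a = mean(a), sd_a = sd(a), n_a = length(a),
               mean_b = mean(b), sd_b = sd(b), n_b = length(b),
               t = ht$t, df = ht$df, p = ht$p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  attr(out, "groups") <- lv
  out
}
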