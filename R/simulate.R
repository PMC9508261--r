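## Synthetic cohort generator: block-covariance parcel time series with
## designated hubs, motion traces with spikes, and degree-coupled behavior.

#' Cohort generative model
#'
#' Encodes the statistical structure the degree pipeline assumes: parcel time
#' series drawn from a zero-mean multivariate normal whose correlation matrix
#' is block-structured by network (`rhoWithin` inside a network, `rhoBetween`
#' across networks), with designated hub parcels whose rows/columns are raised
#' to `rhoHub` (plus a per-group additive offset `groupDelta` for patients,
#' creating a group difference in hub degree); head-motion traces are bounded
#' random walks with Bernoulli displacement spikes; behavior (working-memory
#' accuracy and reaction time) is linearly coupled to mean composite degree
#' over `couplingNodes` plus group offsets and Gaussian noise.
#'
#' Defaults describe the emulated study: 333 parcels in 12 networks plus an
#' unassigned class, 29 patients and 29 controls, 120 volumes at TR = 3 s,
#' and Table-1-like behavioral means (controls 91.5% accuracy / 879.5 ms RT;
#' patients 7 points less accurate and 70 ms slower).
#'
#' @slot nParcels,networkSizes parcel count and named per-network sizes.
#' @slot rhoWithin,rhoBetween,rhoHub correlation levels; `0 <= rhoBetween <=
#'   rhoWithin < 1`, `rhoHub < 1`.
#' @slot hubNodes,couplingNodes parcel id sets (hubs; behavior-coupled nodes).
#' @slot groupDelta additive offset applied to hub correlations in patients.
#' @slot beta accuracy points per unit of mean composite degree at the
#'   coupling nodes; `sigmaY` is the accuracy noise SD (percentage points).
#' @slot groupSizes named integer `c(control=, patient=)`.
#' @slot nVolumes,tr time-series length and repetition time (seconds).
#' @slot spikeRate per-volume probability of a motion spike (FD > 0.5 mm).
#' @slot behavior list of behavioral constants (intercepts, group offsets,
#'   per-load offsets, RT coupling and noise).
#' @export
setClass("CohortModel",
         representation(nParcels = "integer", networkSizes = "integer",
                        rhoWithin = "numeric", rhoBetween = "numeric",
                        rhoHub = "numeric", hubNodes = "integer",
                        groupDelta = "numeric", couplingNodes = "integer",
                        beta = "numeric", sigmaY = "numeric",
                        groupSizes = "integer", nVolumes = "integer",
                        tr = "numeric", spikeRate = "numeric",
                        behavior = "list"))

setValidity("CohortModel", function(object) {
  if (sum(object@networkSizes) != object@nParcels)
    return("networkSizes must sum to nParcels")
  if (object@rhoWithin < 0 || object@rhoWithin >= 1)
    return("rhoWithin must be in [0,1)")
  if (object@rhoBetween < 0 || object@rhoBetween > object@rhoWithin)
    return("rhoBetween must be in [0, rhoWithin]")
  if (object@rhoHub < 0 || object@rhoHub >= 1)
    return("rhoHub must be in [0,1)")
  if (object@rhoHub + max(0, object@groupDelta) >= 1 ||
      object@rhoHub + min(0, object@groupDelta) < -1)
    return("rhoHub + groupDelta leaves the valid correlation range")
  if (any(object@hubNodes < 1L | object@hubNodes > object@nParcels))
    return("hubNodes out of range")
  if (any(object@couplingNodes < 1L | object@couplingNodes > object@nParcels))
    return("couplingNodes out of range")
  if (length(object@couplingNodes) == 0L && object@beta != 0)
    return("beta != 0 requires a nonempty coupling set")
  if (any(object@groupSizes < 2L)) return("group sizes must be >= 2")
  if (object@nVolumes < 10L) return("nVolumes must be >= 10")
  if (object@tr <= 0) return("tr must be positive")
  if (object@spikeRate < 0 || object@spikeRate > 1)
    return("spikeRate must be a probability")
  TRUE
})

## network sizes mirroring the 333-parcel scheme (12 networks + unassigned)
defaultNetworkSizes <- function() {
  c(DMN = 41L, SM = 38L, SML = 8L, VN = 39L, FPN = 24L, AN = 24L,
    CP = 5L, RSP = 8L, CON = 40L, VAN = 23L, SN = 4L, DAN = 32L, UA = 47L)
}

#' @param nParcels,networkSizes,rhoWithin,rhoBetween,rhoHub,hubNodes see slots.
#' @param groupDelta,couplingNodes,beta,sigmaY,groupSizes,nVolumes,tr,spikeRate
#'   see slots.
#' @param behavior list overriding any of the behavioral constants
#'   `accIntercept`, `accGroupOffset`, `accLoadOffsets`, `loadNoise`,
#'   `rtIntercept`, `rtGroupOffset`, `betaRT`, `sigmaRT`, `rtLoadOffsets`.
#' @return a validated [CohortModel-class].
#' @rdname CohortModel-class
#' @export
cohortModel <- function(nParcels = 333L,
                        networkSizes = defaultNetworkSizes(),
                        rhoWithin = 0.30, rhoBetween = 0.05, rhoHub = 0.25,
                        hubNodes = 1:10, groupDelta = -0.06,
                        couplingNodes = 1:5, beta = 0.1, sigmaY = 8,
                        groupSizes = c(control = 29L, patient = 29L),
                        nVolumes = 120L, tr = 3, spikeRate = 0.01,
                        behavior = list()) {
  beh <- list(accIntercept = 91.5, accGroupOffset = -7.0,
              accLoadOffsets = c(`1` = 6, `3` = 2, `5` = -2, `7` = -6),
              loadNoise = 1.5,
              rtIntercept = 879.5, rtGroupOffset = 70.1,
              betaRT = 0, sigmaRT = 130,
              rtLoadOffsets = c(`1` = -150, `3` = -50, `5` = 50, `7` = 150))
  beh[names(behavior)] <- behavior
  new("CohortModel",
      nParcels = as.integer(nParcels),
      networkSizes = structure(as.integer(networkSizes), names = names(networkSizes)),
      rhoWithin = rhoWithin, rhoBetween = rhoBetween, rhoHub = rhoHub,
      hubNodes = as.integer(hubNodes), groupDelta = groupDelta,
      couplingNodes = as.integer(couplingNodes), beta = beta, sigmaY = sigmaY,
      groupSizes = structure(as.integer(groupSizes), names = names(groupSizes)),
      nVolumes = as.integer(nVolumes), tr = tr, spikeRate = spikeRate,
      behavior = beh)
}

setMethod("show", "CohortModel", function(object) {
  cat(sprintf(paste0("CohortModel: %d parcels / %d networks; groups %s; ",
                     "T = %d @ TR %gs\n"),
              object@nParcels, length(object@networkSizes),
              paste(sprintf("%s=%d", names(object@groupSizes), object@groupSizes),
                    collapse = ", "),
              object@nVolumes, object@tr))
  cat(sprintf("  rho within/between/hub: %.2f / %.2f / %.2f; group delta %.2f on %d hubs\n",
              object@rhoWithin, object@rhoBetween, object@rhoHub,
              object@groupDelta, length(object@hubNodes)))
})

#' Build a parcellation with given network block sizes
#'
#' Parcels are assigned to networks contiguously (parcels 1..s1 to the first
#' network, and so on), matching the block structure of the generative
#' covariance. Centroids are drawn uniformly in a cortical bounding box.
#'
#' @param nParcels total number of parcels.
#' @param networkSizes named integer vector of block sizes summing to
#'   `nParcels`.
#' @param seed integer seed (centroids only; the assignment is deterministic).
#' @return a [Parcellation-class].
#' @export
makeParcellation <- function(nParcels = 333L,
                             networkSizes = defaultNetworkSizes(),
                             seed = 1L) {
  .assert(sum(networkSizes) == nParcels,
          sprintf("networkSizes sums to %d but nParcels is %d",
                  sum(networkSizes), nParcels))
  .assert(!is.null(names(networkSizes)) && all(nzchar(names(networkSizes))),
          "networkSizes must be named")
  network <- rep(names(networkSizes), times = networkSizes)
  centroid <- withSeed(seed, cbind(runif(nParcels, -70, 70),
                                   runif(nParcels, -105, 70),
                                   runif(nParcels, -45, 80)))
  Parcellation(network = network, centroid = centroid)
}

## group-specific generating correlation matrix, PSD-repaired
modelCovariance <- function(model, group = c("control", "patient")) {
  group <- match.arg(group)
  n <- model@nParcels
  sizes <- model@networkSizes
  block <- rep(seq_along(sizes), times = sizes)
  S <- matrix(model@rhoBetween, n, n)
  same <- outer(block, block, "==")
  S[same] <- model@rhoWithin
  hub <- model@rhoHub + if (group == "patient") model@groupDelta else 0
  if (length(model@hubNodes)) {
    idx <- model@hubNodes
    S[idx, ] <- pmax(S[idx, , drop = FALSE], hub)
    S[, idx] <- pmax(S[, idx, drop = FALSE], hub)
  }
  diag(S) <- 1
  repairPSD(S)
}

#' Repair a symmetric matrix to positive semidefiniteness
#'
#' Clips eigenvalues below `floor` up to `floor` and re-symmetrizes. Needed
#' because block correlation matrices with hub boosts can be indefinite.
#'
#' @param S symmetric matrix.
#' @param floor smallest retained eigenvalue.
#' @return the repaired matrix.
#' @export
repairPSD <- function(S, floor = 1e-8) {
  e <- eigen((S + t(S)) / 2, symmetric = TRUE)
  if (min(e$values) >= floor) return((S + t(S)) / 2)
  .assert(max(e$values) > 0, "covariance is not repairable (no positive spectrum)")
  v <- pmax(e$values, floor)
  R <- e$vectors %*% (v * t(e$vectors))
  (R + t(R)) / 2
}

## sample T x n rows from N(0, S) using the eigen factor of the repaired S
sampleMVN <- function(nRows, S) {
  e <- eigen(S, symmetric = TRUE)
  v <- pmax(e$values, 0)
  Z <- matrix(rnorm(nRows * ncol(S)), nRows, ncol(S))
  Z %*% t(e$vectors %*% diag(sqrt(v), ncol(S)))
}

#' Simulate one subject's parcel time series and motion trace
#'
#' @param model a [CohortModel-class].
#' @param group `"control"` or `"patient"`.
#' @param seed integer seed; identical `(model, group, seed)` gives identical
#'   output.
#' @return list with `ts` (T x nParcels matrix, columns named by parcel
#'   label) and `motion` (T x 6 matrix: 3 rotations in radians then 3
#'   translations in mm).
#' @export
simulateSubject <- function(model, group = c("control", "patient"), seed = 1L) {
  group <- match.arg(group)
  validObject(model)
  S <- modelCovariance(model, group)
  withSeed(seed, {
    ts <- sampleMVN(model@nVolumes, S)
    colnames(ts) <- sprintf("P%03d", seq_len(model@nParcels))
    motion <- simulateMotion(model@nVolumes, spikeRate = model@spikeRate)
    list(ts = ts, motion = motion)
  })
}

#' Simulate a six-parameter rigid-body motion trace
#'
#' Rotations (radians) follow a smooth bounded random walk; translations (mm)
#' follow a bounded random walk with Bernoulli spike volumes whose jump
#' exceeds the 0.5 mm framewise-displacement scrub threshold. Step sizes are
#' calibrated so typical mean FD is ~0.1 mm, matching ordinary resting-state
#' cohorts.
#'
#' @param nVolumes number of time points.
#' @param spikeRate per-volume spike probability (volumes 2..T).
#' @param stepTrans,stepRot random-walk step SDs (mm, radians).
#' @return T x 6 matrix, columns `rot_x, rot_y, rot_z, trans_x, trans_y,
#'   trans_z`.
#' @export
simulateMotion <- function(nVolumes, spikeRate = 0.01,
                           stepTrans = 0.018, stepRot = 4.5e-4) {
  rot <- apply(matrix(rnorm(nVolumes * 3, sd = stepRot), nVolumes, 3), 2, cumsum)
  rot <- pmin(pmax(rot, -0.02), 0.02)
  trans <- apply(matrix(rnorm(nVolumes * 3, sd = stepTrans), nVolumes, 3), 2, cumsum)
  trans <- pmin(pmax(trans, -1), 1)
  if (spikeRate > 0 && nVolumes > 1) {
    spikes <- which(rbinom(nVolumes - 1L, 1L, spikeRate) == 1L) + 1L
    for (t in spikes) {
      axis <- sample.int(3L, 1L)
      trans[t, axis] <- trans[t, axis] + sample(c(-1, 1), 1L) * runif(1, 0.6, 1.2)
    }
  }
  m <- cbind(rot, trans)
  colnames(m) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  m
}

#' Attach behavior linearly coupled to degree
#'
#' Combined working-memory accuracy is `accIntercept + accGroupOffset[group] +
#' beta * mean(composite degree over couplingNodes) + N(0, sigmaY)`; per-load
#' accuracies are the combined value plus fixed load offsets and small noise,
#' clipped to [0, 100]. Reaction time follows the same construction with the
#' RT constants (and optional `betaRT` coupling), positive-clipped. The
#' coupled degree is centered at its cohort mean, so the intercept is the
#' expected outcome of a subject with cohort-average coupled degree whatever
#' the parcel count or density sweep.
#'
#' @param degrees parcels x subjects matrix of composite degree (or a
#'   [DegreeExperiment-class]).
#' @param group character vector of group labels per subject
#'   (`"control"`/`"patient"`); taken from `colData` if `degrees` is a
#'   `DegreeExperiment`.
#' @param model a [CohortModel-class].
#' @param seed integer seed.
#' @return data.frame with subject_id, group, per-load and combined accuracy
#'   (percent) and reaction time (ms).
#' @export
attachBehavior <- function(degrees, model, group = NULL, seed = 1L) {
  if (is(degrees, "DegreeExperiment")) {
    if (is.null(group)) group <- colData(degrees)$group
    degrees <- assay(degrees, "total")
  }
  degrees <- as.matrix(degrees)
  nSub <- ncol(degrees)
  .assert(!is.null(group) && length(group) == nSub,
          "one group label per subject is required")
  .assert(length(model@couplingNodes) > 0L || model@beta == 0,
          "beta != 0 requires a nonempty coupling set")
  .assert(all(model@couplingNodes <= nrow(degrees)),
          "couplingNodes exceed the number of parcels")
  beh <- model@behavior
  kbar <- if (length(model@couplingNodes))
    colMeans(degrees[model@couplingNodes, , drop = FALSE]) else rep(0, nSub)
  kbar <- kbar - mean(kbar)
  offA <- ifelse(group == "patient", beh$accGroupOffset, 0)
  offR <- ifelse(group == "patient", beh$rtGroupOffset, 0)
  withSeed(seed, {
    acc <- beh$accIntercept + offA + model@beta * kbar +
      rnorm(nSub, sd = model@sigmaY)
    rt <- beh$rtIntercept + offR + beh$betaRT * kbar +
      rnorm(nSub, sd = beh$sigmaRT)
    loads <- c(1L, 3L, 5L, 7L)
    accLoad <- sapply(seq_along(loads), function(i)
      pmin(pmax(acc + beh$accLoadOffsets[i] +
                  rnorm(nSub, sd = beh$loadNoise), 0), 100))
    rtLoad <- sapply(seq_along(loads), function(i)
      pmax(rt + beh$rtLoadOffsets[i] + rnorm(nSub, sd = beh$loadNoise * 10), 150))
    colnames(accLoad) <- paste0("acc_", loads)
    colnames(rtLoad) <- paste0("rt_", loads)
    data.frame(subject_id = colnames(degrees) %||% paste0("S", seq_len(nSub)),
               group = as.character(group),
               accLoad, rtLoad,
               acc_combined = pmin(pmax(acc, 0), 100),
               rt_combined = pmax(rt, 150),
               stringsAsFactors = FALSE)
  })
}

#' Simulate a full cohort
#'
#' Draws every subject's time series and motion trace, computes each subject's
#' connectivity matrix and composite weighted degree (generator-side, on the
#' raw series with no scrubbing), and attaches degree-coupled behavior. All
#' randomness derives from `seed` via [childSeed()].
#'
#' @param model a [CohortModel-class].
#' @param seed integer top-level seed.
#' @param sweep density sweep used for the generator-side coupling degrees.
#' @return list with `model`, `parcellation`, `subjects` (list of
#'   `list(ts, motion, group, subject_id)`), `behavior` (data.frame), and
#'   `degrees` (parcels x subjects generator-side composite degree matrix).
#' @export
simulateCohort <- function(model = cohortModel(), seed = 1L,
                           sweep = densitySweep()) {
  validObject(model)
  parc <- makeParcellation(model@nParcels, model@networkSizes,
                           seed = childSeed(seed, 0L))
  groups <- rep(names(model@groupSizes), times = model@groupSizes)
  nSub <- length(groups)
  ids <- sprintf("sub-%03d", seq_len(nSub))
  subjects <- vector("list", nSub)
  degrees <- matrix(NA_real_, model@nParcels, nSub,
                    dimnames = list(sprintf("P%03d", seq_len(model@nParcels)), ids))
  for (i in seq_len(nSub)) {
    s <- simulateSubject(model, groups[i], seed = childSeed(seed, i))
    subjects[[i]] <- c(s, list(group = groups[i], subject_id = ids[i]))
    C <- connectivityMatrix(s$ts)
    degrees[, i] <- compositeDegree(C, sweep = sweep)
  }
  behavior <- attachBehavior(degrees, model, group = groups,
                             seed = childSeed(seed, nSub + 1L))
  behavior$subject_id <- ids
  list(model = model, parcellation = parc, subjects = subjects,
       behavior = behavior, degrees = degrees)
}
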