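#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
#' @importFrom SummarizedExperiment SummarizedExperiment assay assays rowData
#'   colData assayNames
NULL

## ---------------------------------------------------------------------------
## Parcellation
## ---------------------------------------------------------------------------

#' Parcellation: parcel-to-network assignment
#'
#' Maps every cortical parcel (graph node) to exactly one network community.
#' Mirrors the 333-parcel / 12-network scheme used for resting-state hub
#' analysis, but any number of parcels and any subset of the vocabulary (plus
#' unknown labels, which are permitted with a warning on read) is valid.
#'
#' @slot table data.frame with columns `parcel_id` (integer, contiguous from
#'   1), `parcel_label` (unique character), `network` (character), and
#'   optionally `x`, `y`, `z` centroid coordinates in mm.
#' @export
setClass("Parcellation", representation(table = "data.frame"))

setValidity("Parcellation", function(object) {
  tb <- object@table
  req <- c("parcel_id", "parcel_label", "network")
  if (!all(req %in% names(tb)))
    return(paste("missing columns:", paste(setdiff(req, names(tb)), collapse = ", ")))
  n <- nrow(tb)
  if (n < 2L) return("a parcellation needs at least 2 parcels")
  if (anyDuplicated(tb$parcel_id))
    return(sprintf("duplicated parcel_id: %s",
                   paste(unique(tb$parcel_id[duplicated(tb$parcel_id)]), collapse = ", ")))
  if (!identical(as.integer(tb$parcel_id), seq_len(n)))
    return("parcel_id must be contiguous integers 1..n in order")
  if (anyNA(tb$network) || any(!nzchar(tb$network)))
    return("every parcel needs exactly one non-empty network label")
  TRUE
})

#' Construct a Parcellation
#'
#' @param parcel_id integer vector 1..n (defaults to `seq_along(network)`).
#' @param parcel_label character labels; default `"P<jj>"`.
#' @param network character network label per parcel.
#' @param centroid optional n x 3 matrix of mm coordinates.
#' @return a [Parcellation-class] object.
#' @export
Parcellation <- function(network, parcel_id = seq_along(network),
                         parcel_label = sprintf("P%03d", parcel_id),
                         centroid = NULL) {
  tb <- data.frame(parcel_id = as.integer(parcel_id),
                   parcel_label = as.character(parcel_label),
                   network = as.character(network),
                   stringsAsFactors = FALSE)
  if (!is.null(centroid)) {
    centroid <- as.matrix(centroid)
    .assert(nrow(centroid) == nrow(tb) && ncol(centroid) == 3L,
            "centroid must be an n x 3 matrix")
    tb$x <- centroid[, 1]; tb$y <- centroid[, 2]; tb$z <- centroid[, 3]
  }
  new("Parcellation", table = tb)
}

#' @describeIn Parcellation number of parcels
#' @param object,x a `Parcellation`.
#' @export
setGeneric("nParcels", function(object) standardGeneric("nParcels"))

#' @rdname Parcellation-class
#' @export
setMethod("nParcels", "Parcellation", function(object) nrow(object@table))

#' @describeIn Parcellation per-parcel network labels
#' @export
setGeneric("networks", function(object) standardGeneric("networks"))

#' @rdname Parcellation-class
#' @export
setMethod("networks", "Parcellation", function(object) object@table$network)

#' @rdname Parcellation-class
#' @export
setMethod("as.data.frame", "Parcellation", function(x) x@table)

setMethod("show", "Parcellation", function(object) {
  tb <- object@table
  cat(sprintf("Parcellation: %d parcels, %d networks (%s)\n",
              nrow(tb), length(unique(tb$network)),
              paste(utils::head(sort(unique(tb$network)), 6), collapse = ", ")))
})

## ---------------------------------------------------------------------------
## ConnectivityMatrix
## ---------------------------------------------------------------------------

#' Nonnegative Fisher-z functional connectivity matrix
#'
#' Symmetric n x n matrix of edge weights a_ij: Pearson correlations between
#' parcel time courses, Fisher z-transformed, with negative correlations
#' removed (set to zero) and a zero diagonal.
#'
#' @slot weights numeric n x n matrix.
#' @export
setClass("ConnectivityMatrix", representation(weights = "matrix"))

setValidity("ConnectivityMatrix", function(object) {
  w <- object@weights
  if (!is.numeric(w)) return("weights must be numeric")
  if (nrow(w) != ncol(w)) return("weights must be square")
  if (nrow(w) < 2L) return("need at least 2 parcels")
  if (anyNA(w)) return("weights must not contain NA")
  if (any(w < 0)) return("weights must be nonnegative")
  if (any(abs(w - t(w)) > 1e-8)) return("weights must be symmetric")
  if (any(diag(w) != 0)) return("diagonal must be zero")
  TRUE
})

#' @param weights symmetric nonnegative matrix with zero diagonal.
#' @return a [ConnectivityMatrix-class].
#' @rdname ConnectivityMatrix-class
#' @export
ConnectivityMatrix <- function(weights) {
  weights <- as.matrix(weights)
  new("ConnectivityMatrix", weights = weights)
}

#' @describeIn ConnectivityMatrix edge-weight matrix accessor
#' @param object,x a `ConnectivityMatrix`.
#' @export
setGeneric("connWeights", function(object) standardGeneric("connWeights"))

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("connWeights", "ConnectivityMatrix", function(object) object@weights)

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("nParcels", "ConnectivityMatrix", function(object) nrow(object@weights))

#' @rdname ConnectivityMatrix-class
#' @export
setMethod("dim", "ConnectivityMatrix", function(x) dim(x@weights))

setMethod("show", "ConnectivityMatrix", function(object) {
  w <- object@weights
  off <- w[upper.tri(w)]
  cat(sprintf("ConnectivityMatrix: %d parcels, density %.3f, max weight %.3f\n",
              nrow(w), mean(off > 0), if (length(off)) max(off) else 0))
})

## ---------------------------------------------------------------------------
## DegreeExperiment
## ---------------------------------------------------------------------------

#' Cohort-level degree container
#'
#' A [SummarizedExperiment][SummarizedExperiment::SummarizedExperiment-class]
#' holding composite weighted degree for a cohort: parcels are rows, subjects
#' are columns. Assays are `"total"` and, when a parcellation was supplied,
#' `"within"` and `"between"` (which sum to `"total"` exactly). `rowData`
#' carries the parcellation, `colData` the subject metadata (group, behavior,
#' motion QC), and `metadata()` the density sweep.
#'
#' @export
setClass("DegreeExperiment", contains = "SummarizedExperiment")

setValidity("DegreeExperiment", function(object) {
  an <- assayNames(object)
  if (!"total" %in% an) return("assay 'total' is required")
  if (!"network" %in% names(rowData(object)))
    return("rowData must contain a 'network' column")
  if (all(c("within", "between") %in% an)) {
    d <- assay(object, "within") + assay(object, "between") - assay(object, "total")
    if (max(abs(d)) > 1e-8)
      return("within + between must equal total")
  }
  TRUE
})

#' Construct a DegreeExperiment
#'
#' @param total parcels x subjects matrix of composite total degree.
#' @param within,between optional matching matrices of the network-resolved
#'   decomposition (must sum to `total`).
#' @param parcellation a [Parcellation-class] with `nrow(total)` parcels.
#' @param colData data.frame of subject metadata (one row per column).
#' @param sweep the density sweep used (stored in metadata).
#' @return a [DegreeExperiment-class].
#' @rdname DegreeExperiment-class
#' @export
DegreeExperiment <- function(total, parcellation, within = NULL, between = NULL,
                             colData = NULL, sweep = NULL) {
  total <- as.matrix(total)
  .assert(nrow(total) == nParcels(parcellation),
          "degree matrix rows must match the parcellation")
  assays <- list(total = total)
  if (!is.null(within) || !is.null(between)) {
    .assert(!is.null(within) && !is.null(between),
            "supply both 'within' and 'between' or neither")
    assays$within <- as.matrix(within)
    assays$between <- as.matrix(between)
  }
  if (is.null(colData)) {
    colData <- DataFrame(subject_id = colnames(total) %||% paste0("S", seq_len(ncol(total))))
  } else {
    colData <- DataFrame(colData)
  }
  rd <- DataFrame(as.data.frame(parcellation))
  se <- SummarizedExperiment(assays = assays, rowData = rd, colData = colData)
  if (!is.null(sweep)) metadata(se)$sweep <- sweep
  new("DegreeExperiment", se)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

setMethod("show", "DegreeExperiment", function(object) {
  cat(sprintf("DegreeExperiment: %d parcels x %d subjects; assays: %s\n",
              nrow(object), ncol(object), paste(assayNames(object), collapse = ", ")))
  if (!is.null(metadata(object)$sweep))
    cat("  density sweep:", paste(metadata(object)$sweep, collapse = ", "), "\n")
})

## ---------------------------------------------------------------------------
## Result classes
## ---------------------------------------------------------------------------

#' Per-parcel association test results
#'
#' One row per parcel: the observed statistic (group mean difference of degree,
#' or Pearson r with behavior), the permutation-null summary, z, two-tailed p,
#' Benjamini-Hochberg q, Cohen's d (group tests) and the significance flag at
#' the applicable family threshold.
#'
#' @slot table data.frame of per-parcel results.
#' @slot type `"group"` or `"correlation"`.
#' @slot nPerm number of permutations used.
#' @slot seed seed of the permutation schedule.
#' @slot alpha the family threshold applied to q.
#' @export
setClass("AssociationResult",
         representation(table = "data.frame", type = "character",
                        nPerm = "integer", seed = "integer", alpha = "numeric"))

setValidity("AssociationResult", function(object) {
  tb <- object@table
  if (!all(c("parcel_id", "statistic", "p", "q") %in% names(tb)))
    return("table must contain parcel_id, statistic, p, q")
  if (any(tb$p < 0 | tb$p > 1, na.rm = TRUE)) return("p outside [0,1]")
  if (any(tb$q < 0 | tb$q > 1, na.rm = TRUE)) return("q outside [0,1]")
  if (!object@type %in% c("group", "correlation")) return("unknown type")
  TRUE
})

#' @describeIn AssociationResult per-parcel results table
#' @param object an `AssociationResult` or `PredictionResult`.
#' @export
setGeneric("resultTable", function(object) standardGeneric("resultTable"))

#' @rdname AssociationResult-class
#' @export
setMethod("resultTable", "AssociationResult", function(object) object@table)

#' @describeIn AssociationResult parcel ids flagged significant
#' @export
setGeneric("significantParcels", function(object) standardGeneric("significantParcels"))

#' @rdname AssociationResult-class
#' @export
setMethod("significantParcels", "AssociationResult", function(object)
  object@table$parcel_id[object@table$significant])

setMethod("show", "AssociationResult", function(object) {
  tb <- object@table
  cat(sprintf("AssociationResult (%s): %d parcels, %d permutations, alpha = %g\n",
              object@type, nrow(tb), object@nPerm, object@alpha))
  cat(sprintf("  significant at family threshold: %d\n", sum(tb$significant)))
})

#' Degree-based prediction (CPM) results
#'
#' @slot observed,predicted,score per-subject vectors across LOOCV folds.
#' @slot r Pearson correlation of predicted vs observed behavior.
#' @slot p permutation p value (NA until [cpmSignificance()] is run or
#'   `nPerm > 0` in [cpmLOOCV()]).
#' @slot prevalence per-parcel selection frequency across folds, in [0,1].
#' @slot folds list with per-fold `positive` / `negative` feature sets.
#' @slot pSelect selection threshold used.
#' @slot nPerm,seed permutation settings.
#' @export
setClass("PredictionResult",
         representation(observed = "numeric", predicted = "numeric",
                        score = "numeric", r = "numeric", p = "numeric",
                        prevalence = "numeric", folds = "list",
                        pSelect = "numeric", nPerm = "integer", seed = "integer"))

setValidity("PredictionResult", function(object) {
  n <- length(object@observed)
  if (length(object@predicted) != n || length(object@score) != n)
    return("observed/predicted/score lengths differ")
  if (length(object@folds) != n) return("one fold per subject is required")
  if (any(object@prevalence < 0 | object@prevalence > 1))
    return("prevalence outside [0,1]")
  TRUE
})

#' @rdname PredictionResult-class
#' @export
setMethod("resultTable", "PredictionResult", function(object)
  data.frame(subject = seq_along(object@observed),
             observed = object@observed,
             predicted = object@predicted,
             score = object@score))

#' @describeIn PredictionResult per-parcel selection prevalence across folds
#' @param object a `PredictionResult`.
#' @export
setGeneric("prevalence", function(object) standardGeneric("prevalence"))

#' @rdname PredictionResult-class
#' @export
setMethod("prevalence", "PredictionResult", function(object) object@prevalence)

setMethod("show", "PredictionResult", function(object) {
  cat(sprintf("PredictionResult: N = %d folds, prediction r = %.3f, permutation p = %s\n",
              length(object@observed), object@r,
              ifelse(is.na(object@p), "not computed", format(object@p))))
  cat(sprintf("  p_select = %g; mean features/fold = %.1f\n", object@pSelect,
              mean(vapply(object@folds, function(f)
                length(f$positive) + length(f$negative), numeric(1)))))
})
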