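## Readers and writers: TSV for tabular data, whitespace text for motion,
## JSON for config/manifests. All tabular formats are plain text.

#' Read a parcellation table
#'
#' Expects a TSV with columns `parcel_id`, `parcel_label`, `network` and
#' optionally `x`, `y`, `z`. Network labels outside the standard vocabulary
#' ([networkVocabulary()]) are permitted but reported.
#'
#' @param path file path.
#' @return a [Parcellation-class].
#' @export
readParcellation <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  req <- c("parcel_id", "parcel_label", "network")
  missing <- setdiff(req, names(tb))
  .assert(length(missing) == 0L,
          sprintf("parcellation file lacks column(s): %s",
                  paste(missing, collapse = ", ")))
  dup <- unique(tb$parcel_id[duplicated(tb$parcel_id)])
  .assert(length(dup) == 0L,
          sprintf("duplicated parcel_id: %s", paste(dup, collapse = ", ")))
  unknown <- setdiff(unique(tb$network), networkVocabulary())
  if (length(unknown))
    message("parcellation uses network labels outside the standard vocabulary: ",
            paste(unknown, collapse = ", "))
  cent <- if (all(c("x", "y", "z") %in% names(tb)))
    as.matrix(tb[, c("x", "y", "z")]) else NULL
  Parcellation(network = tb$network, parcel_id = tb$parcel_id,
               parcel_label = tb$parcel_label, centroid = cent)
}

#' @rdname readParcellation
#' @param parcellation a [Parcellation-class] to write.
#' @export
writeParcellation <- function(parcellation, path) {
  utils::write.table(as.data.frame(parcellation), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write parcel time series
#'
#' T rows x n parcels, tab-separated, header row of parcel labels.
#'
#' @param path file path.
#' @return numeric T x n matrix.
#' @export
readTimeSeries <- function(path) {
  tb <- utils::read.table(path, header = TRUE, sep = "\t", check.names = FALSE)
  as.matrix(tb)
}

#' @rdname readTimeSeries
#' @param ts T x n matrix with column names.
#' @export
writeTimeSeries <- function(ts, path) {
  utils::write.table(ts, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write six-parameter motion traces
#'
#' Whitespace-delimited text, one row per volume, six columns: three rotations
#' in radians, then three translations in mm.
#'
#' @param path file path.
#' @return T x 6 matrix.
#' @export
readMotion <- function(path) {
  m <- as.matrix(utils::read.table(path, header = FALSE))
  .assert(ncol(m) == 6L, sprintf("motion file %s has %d columns; expected 6",
                                 path, ncol(m)))
  colnames(m) <- c("rot_x", "rot_y", "rot_z", "trans_x", "trans_y", "trans_z")
  m
}

#' @rdname readMotion
#' @param motion T x 6 matrix.
#' @export
writeMotion <- function(motion, path) {
  utils::write.table(motion, path, sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write the behavior table
#'
#' TSV with `subject_id`, `group`, per-load `acc_*`/`rt_*` and combined
#' columns.
#'
#' @param path file path.
#' @return data.frame.
#' @export
readBehavior <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' @rdname readBehavior
#' @param behavior data.frame to write.
#' @export
writeBehavior <- function(behavior, path) {
  utils::write.table(behavior, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a connectivity matrix as square TSV
#'
#' @param path file path.
#' @return a [ConnectivityMatrix-class].
#' @export
readConnectivity <- function(path) {
  m <- as.matrix(utils::read.table(path, header = TRUE, sep = "\t",
                                   check.names = FALSE))
  rownames(m) <- colnames(m)
  ConnectivityMatrix(m)
}

#' @rdname readConnectivity
#' @param C a [ConnectivityMatrix-class].
#' @export
writeConnectivity <- function(C, path) {
  utils::write.table(connWeights(C), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

## serializable snapshot of a CohortModel
modelToList <- function(model) {
  list(nParcels = model@nParcels,
       networkSizes = as.list(structure(as.integer(model@networkSizes),
                                        names = names(model@networkSizes))),
       rhoWithin = model@rhoWithin, rhoBetween = model@rhoBetween,
       rhoHub = model@rhoHub, hubNodes = model@hubNodes,
       groupDelta = model@groupDelta, couplingNodes = model@couplingNodes,
       beta = model@beta, sigmaY = model@sigmaY,
       groupSizes = as.list(structure(as.integer(model@groupSizes),
                                      names = names(model@groupSizes))),
       nVolumes = model@nVolumes, tr = model@tr, spikeRate = model@spikeRate,
       behavior = model@behavior)
}

#' Write a simulated cohort to disk
#'
#' Layout: `parcellation.tsv`, `behavior.tsv`, `ts/<id>_ts.tsv`,
#' `motion/<id>_motion.txt`, and `manifest.json` (subject list, generator
#' config, seed) — the input layout [runPipeline()] consumes.
#'
#' @param cohort output of [simulateCohort()].
#' @param dir output directory (created if needed).
#' @param seed the seed the cohort was generated with (recorded in the
#'   manifest).
#' @return `dir`, invisibly.
#' @export
writeCohort <- function(cohort, dir, seed = NA_integer_) {
  dir.create(file.path(dir, "ts"), recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "motion"), showWarnings = FALSE)
  writeParcellation(cohort$parcellation, file.path(dir, "parcellation.tsv"))
  writeBehavior(cohort$behavior, file.path(dir, "behavior.tsv"))
  subjects <- lapply(cohort$subjects, function(s) {
    tsPath <- file.path("ts", paste0(s$subject_id, "_ts.tsv"))
    moPath <- file.path("motion", paste0(s$subject_id, "_motion.txt"))
    writeTimeSeries(s$ts, file.path(dir, tsPath))
    writeMotion(s$motion, file.path(dir, moPath))
    list(subject_id = s$subject_id, group = s$group, ts = tsPath, motion = moPath)
  })
  manifest <- list(subjects = subjects, seed = seed,
                   tr = cohort$model@tr, config = modelToList(cohort$model))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
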