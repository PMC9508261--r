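#' @import methods
#' @importFrom stats cor cor.test cov pnorm pt qt qnorm rnorm runif rbinom sd
#'   var p.adjust t.test
#' @importFrom tools md5sum
NULL

#' Derive a child seed from a top-level seed
#'
#' All stochastic stages take one explicit integer seed. Where a stage needs
#' several independent streams (one per subject, one per permutation schedule),
#' child seeds are derived deterministically so that the whole cohort is a pure
#' function of the top-level seed.
#'
#' @param seed integer top-level seed.
#' @param index nonnegative integer stream index.
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @export
childSeed <- function(seed, index) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.numeric(index))
  as.integer((as.double(seed) + 104729 * as.double(index)) %% 2147483646)
}

## run `expr` under a local RNG state so callers' streams are untouched
withSeed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

.assert <- function(ok, ...) {
  if (!isTRUE(ok)) stop(..., call. = FALSE)
}

## canonical network vocabulary of the 12-community cortical parcellation,
## plus the unassigned class
#' Network community vocabulary
#'
#' The 12 network labels of the cortical parcellation scheme the package
#' emulates, plus `"UA"` (unassigned) for communities too small to form a
#' network.
#' @return character vector of 13 labels.
#' @export
networkVocabulary <- function() {
  c("DMN", "VN", "FPN", "DAN", "VAN", "SN", "CON",
    "SM", "SML", "AN", "CP", "RSP", "UA")
}
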