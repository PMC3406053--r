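#' @include AllGenerics.R
NULL

## Canonical 20-residue ordering: alphabetical by three-letter code.
.AA3 <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS",
          "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP",
          "TYR", "VAL")
.AA1 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H",
          "I", "L", "K", "M", "F", "P", "S", "T", "W",
          "Y", "V")

.SS_CATEGORIES <- c("helix", "strand", "turn", "coil")

.DIM_NAMES <- c("AA1", "AA2", "SA", "D", "SS1", "SS2", "CL", "SD")

#' BinScheme: the 8-dimension binning of pair observations
#'
#' Describes how each of the eight pair descriptors is discretized:
#' the two residue types (20 bins each, alphabetical by three-letter
#' code), relative solvent accessibility in percent (12 bins: SA<=0,
#' width-10 bins up to 100, SA>100), functional-atom distance in
#' Angstrom (14 bins: D<=1.75 then width-0.5 bins up to 8.25), the two
#' secondary-structure categories (helix/strand/turn/coil), chain
#' length (12 bins: CL<=0, width-100 bins up to 1000, CL>1000) and
#' sequence distance (6 bins: 0, 1, 2, 3, 4, >4). All numeric bins are
#' left-open right-closed, \code{(lower, upper]}.
#'
#' Internal edge vectors store the finite boundaries only; the two
#' extreme bins of each numeric dimension absorb out-of-range values.
#'
#' @slot aaOrder character(20), residue ordering for the AA1/AA2 axes.
#' @slot saEdges numeric, internal solvent-accessibility edges
#'   (default \code{0, 10, ..., 100}).
#' @slot distEdges numeric, internal distance edges (default
#'   \code{1.75, 2.25, ..., 7.75}).
#' @slot ssCategories character(4), secondary-structure categories.
#' @slot clEdges numeric, internal chain-length edges (default
#'   \code{0, 100, ..., 1000}).
#' @slot sdMax integer, largest individually binned sequence distance
#'   (default 4; separations above it share the final bin).
#' @seealso [defaultBinScheme()], [assignBin()], [tensorSize()]
#' @export
setClass("BinScheme",
  representation(
    aaOrder      = "character",
    saEdges      = "numeric",
    distEdges    = "numeric",
    ssCategories = "character",
    clEdges      = "numeric",
    sdMax        = "integer"
  )
)

setValidity("BinScheme", function(object) {
  msg <- character()
  if (length(object@aaOrder) != 20L ||
      !setequal(object@aaOrder, .AA3))
    msg <- c(msg, "aaOrder must be a permutation of the 20 standard residues")
  for (s in c("saEdges", "distEdges", "clEdges")) {
    e <- slot(object, s)
    if (length(e) < 1L || anyNA(e) || any(!is.finite(e)) ||
        is.unsorted(e, strictly = TRUE))
      msg <- c(msg, paste(s, "must be finite and strictly increasing"))
  }
  if (length(object@ssCategories) != 4L ||
      anyDuplicated(object@ssCategories))
    msg <- c(msg, "ssCategories must be 4 distinct labels")
  if (length(object@sdMax) != 1L || is.na(object@sdMax) || object@sdMax < 1L)
    msg <- c(msg, "sdMax must be a positive integer")
  if (length(msg)) msg else TRUE
})

#' ValidatedChain: one protein chain after merge and validation
#'
#' Holds the per-residue table of a chain whose residues all carry a
#' residue type, C-alpha and functional-atom coordinates, a
#' secondary-structure category and a solvent-accessibility value.
#' Rows are ordered by \code{seqIndex}, the 1-based ordinal position
#' among the validated residues (the sequence-distance input), with the
#' author residue number retained for provenance.
#'
#' @slot structureId character, 4-character structure identifier.
#' @slot chainId character, single chain identifier.
#' @slot residues data.frame with columns \code{aa} (three-letter
#'   code), \code{seqIndex}, \code{authNum}, \code{insCode},
#'   \code{caX,caY,caZ}, \code{f1X,f1Y,f1Z}, \code{f2X,f2Y,f2Z}
#'   (NA for single-functional-atom types), \code{ss}, \code{sa}.
#' @seealso [mergeAndValidate()], [findPairs()], [shuffleLabels()]
#' @export
setClass("ValidatedChain",
  representation(
    structureId = "character",
    chainId     = "character",
    residues    = "data.frame"
  )
)

.CHAIN_COLS <- c("aa", "seqIndex", "authNum", "insCode",
                 "caX", "caY", "caZ",
                 "f1X", "f1Y", "f1Z", "f2X", "f2Y", "f2Z",
                 "ss", "sa")

setValidity("ValidatedChain", function(object) {
  msg <- character()
  r <- object@residues
  if (!all(.CHAIN_COLS %in% names(r)))
    msg <- c(msg, paste("residues must have columns:",
                        paste(.CHAIN_COLS, collapse = ", ")))
  else {
    if (nrow(r)) {
      if (!all(r$aa %in% .AA3))
        msg <- c(msg, "unknown residue types present")
      if (!all(r$ss %in% .SS_CATEGORIES))
        msg <- c(msg, "ss must be one of helix/strand/turn/coil")
      if (anyNA(r$sa) || any(!is.finite(r$sa)))
        msg <- c(msg, "sa must be finite")
      if (is.unsorted(r$seqIndex, strictly = TRUE))
        msg <- c(msg, "seqIndex must be strictly increasing")
      if (anyNA(r[, c("caX", "caY", "caZ", "f1X", "f1Y", "f1Z")]))
        msg <- c(msg, "C-alpha and first functional atom must be present")
    }
  }
  if (length(object@chainId) != 1L || !nzchar(object@chainId))
    msg <- c(msg, "chainId must be a single non-empty string")
  if (length(msg)) msg else TRUE
})

#' PairTensor: sparse 8-dimensional pair-count tensor
#'
#' Stores only the non-zero cells of the pair-count tensor as a
#' data.frame of integer bin indices plus a count column. Counts are
#' integers for observed tensors and may be fractional for averaged
#' reference tensors. Insertion modes: \code{"symmetric"} (each
#' observation incremented at both (AA1,AA2,..,SS1,SS2,..) and the
#' swapped cell, total = 2 x observations) and \code{"canonical"} (one
#' increment with AA1 <= AA2, total = observations).
#'
#' @slot cells data.frame with columns \code{AA1, AA2, SA, D, SS1,
#'   SS2, CL, SD} (integer bin indices) and \code{count}.
#' @slot scheme the \linkS4class{BinScheme} the indices refer to.
#' @slot dims character, names of the dimensions the cells are indexed
#'   by (all 8 for full tensors, fewer after projection).
#' @slot mode \code{"symmetric"} or \code{"canonical"}.
#' @slot nObs number of pair observations accumulated.
#' @slot meta list of free-form provenance (corpus description, seeds).
#' @seealso [accumulatePairs()], [projectTensor()], [rankFrequency()]
#' @export
setClass("PairTensor",
  representation(
    cells  = "data.frame",
    scheme = "BinScheme",
    dims   = "character",
    mode   = "character",
    nObs   = "numeric",
    meta   = "list"
  )
)

setValidity("PairTensor", function(object) {
  msg <- character()
  d <- object@dims
  if (!length(d) || !all(d %in% .DIM_NAMES))
    msg <- c(msg, "dims must be a non-empty subset of the 8 dimension names")
  cl <- object@cells
  if (!all(c(d, "count") %in% names(cl)))
    msg <- c(msg, "cells must carry one column per dimension plus 'count'")
  else if (nrow(cl)) {
    if (any(cl$count <= 0) || anyNA(cl$count))
      msg <- c(msg, "stored counts must be positive (no zero cells)")
    bc <- binCounts(object@scheme)
    for (dd in d) {
      v <- cl[[dd]]
      if (anyNA(v) || any(v < 1L) || any(v > bc[[dd]]))
        msg <- c(msg, paste("index out of range in dimension", dd))
    }
    if (anyDuplicated(cl[, d, drop = FALSE]))
      msg <- c(msg, "duplicate cell indices")
  }
  if (!object@mode %in% c("symmetric", "canonical"))
    msg <- c(msg, "mode must be 'symmetric' or 'canonical'")
  if (length(msg)) msg else TRUE
})

#' ReferenceTensor: averaged composition-shuffled null tensor
#'
#' The cell-wise mean of \code{nReps} tensors, each built by re-running
#' the full pair pipeline on chains whose residue-type labels were
#' uniformly permuted within the chain (composition preserved,
#' geometry, accessibility and secondary structure left positional).
#'
#' @slot tensor the averaged \linkS4class{PairTensor} (fractional counts).
#' @slot nReps integer, repetitions averaged.
#' @slot seed integer, master seed the repetition streams were derived
#'   from.
#' @seealso [buildReference()], [ratioMap()]
#' @export
setClass("ReferenceTensor",
  representation(
    tensor = "PairTensor",
    nReps  = "integer",
    seed   = "integer"
  )
)

setValidity("ReferenceTensor", function(object) {
  if (object@nReps < 1L) "nReps must be >= 1" else TRUE
})

#' PowerLawFit: log2-log2 linear fit of a rank-frequency table
#'
#' Ordinary least squares of log2(omega) on log2(rank), one point per
#' distinct rank. \code{slope} estimates -lambda of the power law
#' omega(R) = c R^-lambda. Goodness is reported both as the absolute
#' Pearson correlation of the log-log points (larger is better, the
#' conventional figure of merit for these fits) and as the residual
#' RMSE in log2 units.
#'
#' @slot slope fitted slope (-lambda).
#' @slot intercept fitted intercept, log2 units.
#' @slot slopeCI numeric(2), 95 percent t-interval on the slope.
#' @slot pearsonR absolute Pearson correlation of the fitted points.
#' @slot rmse root-mean-square residual, log2 units.
#' @slot nPoints number of distinct ranks entering the fit.
#' @seealso [fitPowerLaw()], [subspaceScan()]
#' @export
setClass("PowerLawFit",
  representation(
    slope     = "numeric",
    intercept = "numeric",
    slopeCI   = "numeric",
    pearsonR  = "numeric",
    rmse      = "numeric",
    nPoints   = "integer"
  )
)

setValidity("PowerLawFit", function(object) {
  msg <- character()
  if (length(object@slopeCI) != 2L)
    msg <- c(msg, "slopeCI must have length 2")
  else if (!is.na(object@slope) &&
           (object@slope < object@slopeCI[1] - 1e-12 ||
            object@slope > object@slopeCI[2] + 1e-12))
    msg <- c(msg, "slopeCI must contain the slope")
  if (!is.na(object@pearsonR) &&
      (object@pearsonR < 0 || object@pearsonR > 1 + 1e-12))
    msg <- c(msg, "pearsonR must lie in [0, 1]")
  if (object@nPoints < 3L)
    msg <- c(msg, "a reported fit needs at least 3 points")
  if (length(msg)) msg else TRUE
})

## ---- show methods -------------------------------------------------

setMethod("show", "BinScheme", function(object) {
  bc <- binCounts(object)
  cat("BinScheme:", paste(names(bc), bc, sep = "=", collapse = " "), "\n")
  cat("  cells:", format(tensorSize(object), big.mark = ","), "\n")
})

setMethod("show", "ValidatedChain", function(object) {
  cat(sprintf("ValidatedChain %s chain %s: %d residues\n",
              object@structureId, object@chainId, nrow(object@residues)))
})

setMethod("show", "PairTensor", function(object) {
  cat(sprintf("PairTensor [%s] over (%s): %d non-zero cells, total %.6g (%g observations)\n",
              object@mode, paste(object@dims, collapse = ","),
              nrow(object@cells), tensorTotal(object), object@nObs))
})

setMethod("show", "ReferenceTensor", function(object) {
  cat(sprintf("ReferenceTensor: mean of %d shuffled repetitions (seed %d)\n",
              object@nReps, object@seed))
  show(object@tensor)
})

setMethod("show", "PowerLawFit", function(object) {
  cat(sprintf(
    "PowerLawFit: slope %.3f (95%% CI %.3f .. %.3f), intercept %.2f, |r| %.3f, RMSE %.3f, n=%d\n",
    object@slope, object@slopeCI[1], object@slopeCI[2],
    object@intercept, object@pearsonR, object@rmse, object@nPoints))
})

## ---- simple accessors ---------------------------------------------

#' @describeIn ValidatedChain-class number of validated residues.
#' @param x a \code{ValidatedChain}.
#' @export
setMethod("chainLength", "ValidatedChain",
          function(x) nrow(x@residues))

#' @describeIn ValidatedChain-class the per-residue table.
#' @export
setMethod("residues", "ValidatedChain", function(x) x@residues)

#' @describeIn PairTensor-class sum of all stored counts.
#' @param x a \code{PairTensor}.
#' @export
setMethod("tensorTotal", "PairTensor", function(x) sum(x@cells$count))

#' @describeIn PairTensor-class number of non-zero cells.
#' @export
setMethod("nonzeroCells", "PairTensor", function(x) nrow(x@cells))

#' @describeIn ReferenceTensor-class total of the averaged tensor.
#' @param x a \code{ReferenceTensor}.
#' @export
setMethod("tensorTotal", "ReferenceTensor",
          function(x) tensorTotal(x@tensor))

#' @describeIn ReferenceTensor-class non-zero cells of the averaged
#'   tensor.
#' @export
setMethod("nonzeroCells", "ReferenceTensor",
          function(x) nonzeroCells(x@tensor))

#' Dimension names of the 8-D pair tensor
#'
#' @return \code{c("AA1","AA2","SA","D","SS1","SS2","CL","SD")}.
#' @export
#' @examples
#' tensorDimNames()
tensorDimNames <- function() .DIM_NAMES

#' Standard residue orderings
#'
#' Three-letter and one-letter codes of the 20 standard amino acids in
#' the canonical axis order (alphabetical by three-letter code).
#' @return Character vector of length 20.
#' @export
#' @examples
#' aminoAcids3()[1:4]
aminoAcids3 <- function() .AA3

#' @rdname aminoAcids3
#' @export
aminoAcids1 <- function() .AA1

#' Secondary-structure categories
#' @return \code{c("helix","strand","turn","coil")}.
#' @export
ssCategories <- function() .SS_CATEGORIES
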