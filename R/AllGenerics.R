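#' @import methods
NULL

#' Number of bins along each tensor dimension
#'
#' @param x a \linkS4class{BinScheme}.
#' @return Named integer vector of length 8
#'   (\code{AA1, AA2, SA, D, SS1, SS2, CL, SD}).
#' @export
setGeneric("binCounts", function(x) standardGeneric("binCounts"))

#' Total number of cells addressable by a bin scheme
#'
#' @param x a \linkS4class{BinScheme}.
#' @param dims optional character vector of dimension names; the size of
#'   the sub-space spanned by those dimensions is returned.
#' @return A single number, the product of per-dimension bin counts.
#' @export
setGeneric("tensorSize", function(x, dims = NULL) standardGeneric("tensorSize"))

#' Total count stored in a tensor
#' @param x a \linkS4class{PairTensor} or \linkS4class{ReferenceTensor}.
#' @return Numeric scalar, the sum over all non-zero cells.
#' @export
setGeneric("tensorTotal", function(x) standardGeneric("tensorTotal"))

#' Number of non-zero cells in a tensor
#' @param x a \linkS4class{PairTensor} or \linkS4class{ReferenceTensor}.
#' @return Integer scalar.
#' @export
setGeneric("nonzeroCells", function(x) standardGeneric("nonzeroCells"))

#' Marginalize a tensor onto a subset of its dimensions
#'
#' Counts are summed over the dropped dimensions; the projected total
#' always equals the original total.
#'
#' @param x a \linkS4class{PairTensor}.
#' @param keep character vector of dimension names to keep, a subset of
#'   \code{c("AA1","AA2","SA","D","SS1","SS2","CL","SD")}.
#' @return A \linkS4class{PairTensor} whose cells are indexed by the kept
#'   dimensions only.
#' @export
setGeneric("projectTensor", function(x, keep) standardGeneric("projectTensor"))

#' Rank-frequency table of cell populations
#'
#' Tabulates, for every population size R occurring in the tensor, the
#' number of cells omega(R) holding exactly that population. Zero cells
#' are never counted.
#'
#' @param x a \linkS4class{PairTensor}.
#' @return A data.frame with columns \code{rank} and \code{omega},
#'   ordered by rank.
#' @export
setGeneric("rankFrequency", function(x) standardGeneric("rankFrequency"))

#' Number of validated residues in a chain
#' @param x a \linkS4class{ValidatedChain}.
#' @return Integer scalar.
#' @export
setGeneric("chainLength", function(x) standardGeneric("chainLength"))

#' Per-residue table of a validated chain
#' @param x a \linkS4class{ValidatedChain}.
#' @return The underlying residue data.frame (one row per validated
#'   residue).
#' @export
setGeneric("residues", function(x) standardGeneric("residues"))
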