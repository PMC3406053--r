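#' @include AllClasses.R
NULL

#' The default 8-dimension bin scheme
#'
#' 20 x 20 residue-type bins, 12 solvent-accessibility bins (SA<=0,
#' width-10 up to 100, SA>100), 14 distance bins (D<=1.75, width-0.5 up
#' to 8.25 Angstrom), 4 x 4 secondary-structure bins, 12 chain-length
#' bins (CL<=0, width-100 up to 1000, CL>1000) and 6 sequence-distance
#' bins (0, 1, 2, 3, 4, >4): 77,414,400 cells in total.
#'
#' @return A \linkS4class{BinScheme}.
#' @export
#' @examples
#' scheme <- defaultBinScheme()
#' tensorSize(scheme)                  # 77,414,400
#' tensorSize(scheme, c("AA1", "AA2")) # 400
defaultBinScheme <- function() {
  new("BinScheme",
      aaOrder      = .AA3,
      saEdges      = seq(0, 100, by = 10),
      distEdges    = seq(1.75, 7.75, by = 0.5),
      ssCategories = .SS_CATEGORIES,
      clEdges      = seq(0, 1000, by = 100),
      sdMax        = 4L)
}

#' @describeIn binCounts bins per dimension of a \code{BinScheme}.
#' @export
setMethod("binCounts", "BinScheme", function(x) {
  c(AA1 = length(x@aaOrder),
    AA2 = length(x@aaOrder),
    SA  = length(x@saEdges) + 1L,
    D   = length(x@distEdges) + 1L,
    SS1 = length(x@ssCategories),
    SS2 = length(x@ssCategories),
    CL  = length(x@clEdges) + 1L,
    SD  = x@sdMax + 2L)
})

#' @describeIn tensorSize product of bin counts, optionally restricted
#'   to a dimension subset.
#' @export
setMethod("tensorSize", "BinScheme", function(x, dims = NULL) {
  bc <- binCounts(x)
  if (!is.null(dims)) {
    if (!all(dims %in% names(bc)))
      stop("unknown dimension(s): ",
           paste(setdiff(dims, names(bc)), collapse = ", "))
    bc <- bc[dims]
  }
  prod(bc)
})

#' Assign values to bins of a numeric tensor dimension
#'
#' Bins are left-open right-closed, \code{(lower, upper]}; the two
#' extreme bins absorb values beyond the stated ranges. Vectorized.
#'
#' @param value numeric vector of values to bin; must be finite.
#' @param dimension one of \code{"sa"}, \code{"dist"}, \code{"cl"},
#'   \code{"sd"}. Sequence distances are binned individually at
#'   0..\code{sdMax} with a single shared bin above.
#' @param scheme a \linkS4class{BinScheme}.
#' @return Integer vector of 1-based bin indices.
#' @export
#' @examples
#' scheme <- defaultBinScheme()
#' assignBin(5, "sa", scheme)    # 2: the (0,10] shell
#' assignBin(4.0, "dist", scheme) # 6: the (3.75,4.25] shell
#' assignBin(7, "sd", scheme)    # 6: the >4 bin
assignBin <- function(value, dimension = c("sa", "dist", "cl", "sd"),
                      scheme = defaultBinScheme()) {
  dimension <- match.arg(dimension)
  if (anyNA(value) || any(!is.finite(value)))
    stop("assignBin: values must be finite (dimension '", dimension, "')")
  if (dimension == "sd") {
    v <- as.integer(value)
    return(pmin(v, scheme@sdMax + 1L) + 1L)
  }
  edges <- switch(dimension,
                  sa   = scheme@saEdges,
                  dist = scheme@distEdges,
                  cl   = scheme@clEdges)
  findInterval(value, edges, left.open = TRUE) + 1L
}

#' Human-readable labels for the bins of one dimension
#'
#' @param dimension one of \code{"aa"}, \code{"sa"}, \code{"dist"},
#'   \code{"ss"}, \code{"cl"}, \code{"sd"}.
#' @param scheme a \linkS4class{BinScheme}.
#' @return Character vector, one label per bin.
#' @export
#' @examples
#' binLabels("sa")[1:3]
binLabels <- function(dimension = c("aa", "sa", "dist", "ss", "cl", "sd"),
                      scheme = defaultBinScheme()) {
  dimension <- match.arg(dimension)
  edgeLabels <- function(edges) {
    n <- length(edges)
    c(sprintf("<=%g", edges[1]),
      sprintf("(%g,%g]", edges[-n], edges[-1]),
      sprintf(">%g", edges[n]))
  }
  switch(dimension,
         aa   = scheme@aaOrder,
         sa   = edgeLabels(scheme@saEdges),
         dist = edgeLabels(scheme@distEdges),
         ss   = scheme@ssCategories,
         cl   = edgeLabels(scheme@clEdges),
         sd   = c(as.character(0:scheme@sdMax),
                  sprintf(">%d", scheme@sdMax)))
}

#' The functional-atom table
#'
#' The side-chain atom(s) representing each residue type's chemically
#' active tip, between which inter-residue distances are measured:
#' Ala CB; Arg NH1,NH2; Asn ND2,OD1; Asp OD1,OD2; Cys SG; Gln NE2,OE1;
#' Glu OE1,OE2; Gly CA; His ND1; Ile CG1,CG2; Leu CG; Lys NZ; Met SD;
#' Phe CZ; Pro CG; Ser OG; Thr OG1; Trp CE2; Tyr OH; Val CG1,CG2.
#'
#' @return Named list mapping three-letter residue codes to character
#'   vectors of 1 or 2 PDB atom names.
#' @export
#' @examples
#' functionalAtomTable()$ARG  # "NH1" "NH2"
functionalAtomTable <- function() {
  list(ALA = "CB",
       ARG = c("NH1", "NH2"),
       ASN = c("ND2", "OD1"),
       ASP = c("OD1", "OD2"),
       CYS = "SG",
       GLN = c("NE2", "OE1"),
       GLU = c("OE1", "OE2"),
       GLY = "CA",
       HIS = "ND1",
       ILE = c("CG1", "CG2"),
       LEU = "CG",
       LYS = "NZ",
       MET = "SD",
       PHE = "CZ",
       PRO = "CG",
       SER = "OG",
       THR = "OG1",
       TRP = "CE2",
       TYR = "OH",
       VAL = c("CG1", "CG2"))
}
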