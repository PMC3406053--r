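#' @include AllClasses.R binScheme.R utils.R
NULL

#' Functional-atom distance between two residues
#'
#' The minimum Euclidean distance over all combinations of the two
#' residues' functional atoms (1 or 2 per residue).
#'
#' @param r1,r2 single-row residue records (rows of
#'   \code{residues(chain)}).
#' @return Distance in Angstrom.
#' @export
pairDistance <- function(r1, r2) {
  A <- rbind(c(r1$f1X, r1$f1Y, r1$f1Z), c(r1$f2X, r1$f2Y, r1$f2Z))
  B <- rbind(c(r2$f1X, r2$f1Y, r2$f1Z), c(r2$f2X, r2$f2Y, r2$f2Z))
  A <- A[stats::complete.cases(A), , drop = FALSE]
  B <- B[stats::complete.cases(B), , drop = FALSE]
  min(.crossDist(A, B))
}

#' Detect amino-acid pairs in a validated chain
#'
#' Two residues of the same chain form a pair when they fall in the
#' same solvent-accessibility bin and the minimum distance between
#' their functional atoms is below 8.25 Angstrom. Every unordered
#' residue pair (i < j by sequence position) is tested; self-pairs are
#' excluded. Each detected pair is reported with its 8 bin
#' coordinates: the two residue types (AA1 = the earlier residue),
#' the shared SA bin, the distance bin, the two secondary-structure
#' categories, the chain-length bin and the sequence-distance bin,
#' plus the exact distance and a provenance string
#' (structure id + zero-padded residue number + chain id, twice,
#' e.g. \code{"1ABC0102A1030A"}).
#'
#' @param chain a \linkS4class{ValidatedChain}.
#' @param scheme a \linkS4class{BinScheme}.
#' @param maxDist distance cut-off in Angstrom (strict \code{<});
#'   defaults to the upper edge of the last distance bin.
#' @return data.frame with integer columns \code{AA1, AA2, SA, D, SS1,
#'   SS2, CL, SD}, numeric \code{euclid} and character
#'   \code{provenance}; zero rows when no pair qualifies.
#' @export
findPairs <- function(chain, scheme = defaultBinScheme(),
                      maxDist = max(scheme@distEdges) + 0.5) {
  r <- residues(chain)
  n <- nrow(r)
  empty <- data.frame(AA1 = integer(), AA2 = integer(), SA = integer(),
                      D = integer(), SS1 = integer(), SS2 = integer(),
                      CL = integer(), SD = integer(),
                      euclid = numeric(), provenance = character(),
                      stringsAsFactors = FALSE)
  if (n < 2L) return(empty)
  F1 <- as.matrix(r[, c("f1X", "f1Y", "f1Z")])
  F2 <- as.matrix(r[, c("f2X", "f2Y", "f2Z")])
  d11 <- .crossDist(F1, F1)
  d12 <- .crossDist(F1, F2)   # d12[i, j] = |F1_i - F2_j|
  d22 <- .crossDist(F2, F2)
  dmin <- pmin(d11, d12, t(d12), d22, na.rm = TRUE)
  saBin <- assignBin(r$sa, "sa", scheme)
  sameSA <- outer(saBin, saBin, "==")
  hit <- which(upper.tri(dmin) & sameSA & dmin < maxDist, arr.ind = TRUE)
  if (!nrow(hit)) return(empty)
  i <- hit[, 1L]; j <- hit[, 2L]   # upper triangle: i < j
  ssIdx <- match(r$ss, scheme@ssCategories)
  clBin <- assignBin(n, "cl", scheme)
  data.frame(
    AA1 = match(r$aa[i], scheme@aaOrder),
    AA2 = match(r$aa[j], scheme@aaOrder),
    SA  = saBin[i],
    D   = assignBin(dmin[hit], "dist", scheme),
    SS1 = ssIdx[i],
    SS2 = ssIdx[j],
    CL  = rep.int(clBin, length(i)),
    SD  = assignBin(abs(r$seqIndex[j] - r$seqIndex[i]), "sd", scheme),
    euclid = dmin[hit],
    provenance = paste0(chain@structureId,
                        .pad4(r$authNum[i]), chain@chainId,
                        .pad4(r$authNum[j]), chain@chainId),
    stringsAsFactors = FALSE)
}

#' Detect pairs across a corpus of chains
#'
#' @param corpus list of \linkS4class{ValidatedChain}.
#' @param scheme a \linkS4class{BinScheme}.
#' @return Row-bound pair observations of [findPairs()] over all
#'   chains.
#' @export
findPairsCorpus <- function(corpus, scheme = defaultBinScheme()) {
  do.call(rbind, lapply(corpus, findPairs, scheme = scheme))
}

## internal constructor; cells must already be aggregated and non-zero
.newPairTensor <- function(cells, scheme, dims = .DIM_NAMES,
                           mode = "symmetric", nObs = 0, meta = list()) {
  for (d in dims) cells[[d]] <- as.integer(cells[[d]])
  cells <- cells[, c(dims, "count"), drop = FALSE]
  rownames(cells) <- NULL
  new("PairTensor", cells = cells, scheme = scheme, dims = dims,
      mode = mode, nObs = nObs, meta = meta)
}

#' Accumulate pair observations into the sparse 8-D tensor
#'
#' In \code{"symmetric"} mode (the default) every observation
#' increments both its (AA1,AA2,...,SS1,SS2,...) cell and the swapped
#' (AA2,AA1,...,SS2,SS1,...) cell, so that an A-B pair is counted once
#' in each direction and the tensor total is twice the number of
#' observations. In \code{"canonical"} mode each observation makes a
#' single increment into the cell with AA1 <= AA2 (ties broken by
#' SS1 <= SS2) and the total equals the number of observations.
#'
#' @param observations pair-observation data.frame from [findPairs()]
#'   or [findPairsCorpus()] (all binned under \code{scheme}).
#' @param scheme the \linkS4class{BinScheme} the observations were
#'   binned under.
#' @param mode \code{"symmetric"} or \code{"canonical"}.
#' @param meta optional list of provenance stored with the tensor.
#' @return A \linkS4class{PairTensor}.
#' @export
accumulatePairs <- function(observations, scheme = defaultBinScheme(),
                            mode = c("symmetric", "canonical"),
                            meta = list()) {
  mode <- match.arg(mode)
  obs <- observations
  if (is.null(obs)) obs <- data.frame()
  if (nrow(obs)) {
    bc <- binCounts(scheme)
    for (d in .DIM_NAMES)
      if (anyNA(obs[[d]]) || any(obs[[d]] < 1L) || any(obs[[d]] > bc[[d]]))
        stop("observation indices out of range for this bin scheme (",
             d, "); were they binned under a different scheme?")
  }
  idx <- obs[, .DIM_NAMES, drop = FALSE]
  if (mode == "symmetric" && nrow(idx)) {
    swapped <- idx[, c("AA2", "AA1", "SA", "D", "SS2", "SS1", "CL", "SD"),
                   drop = FALSE]
    names(swapped) <- .DIM_NAMES
    idx <- rbind(idx, swapped)
  } else if (mode == "canonical" && nrow(idx)) {
    flip <- idx$AA1 > idx$AA2 | (idx$AA1 == idx$AA2 & idx$SS1 > idx$SS2)
    tmp <- idx[flip, , drop = FALSE]
    idx[flip, c("AA1", "AA2", "SS1", "SS2")] <-
      tmp[, c("AA2", "AA1", "SS2", "SS1")]
  }
  if (nrow(idx)) {
    dt <- data.table::as.data.table(idx)
    cells <- as.data.frame(dt[, list(count = .N), by = .DIM_NAMES])
    cells <- cells[do.call(order, cells[.DIM_NAMES]), , drop = FALSE]
  } else {
    cells <- cbind(as.data.frame(setNames(rep(list(integer()), 8),
                                          .DIM_NAMES)),
                   count = numeric())
  }
  .newPairTensor(cells, scheme, mode = mode, nObs = nrow(obs), meta = meta)
}

#' Build the observed tensor for a corpus in one call
#'
#' Convenience wrapper: [findPairsCorpus()] then [accumulatePairs()].
#'
#' @inheritParams accumulatePairs
#' @param corpus list of \linkS4class{ValidatedChain}.
#' @return A \linkS4class{PairTensor} with the pair observations kept
#'   in \code{meta$observations}' count.
#' @export
buildTensor <- function(corpus, scheme = defaultBinScheme(),
                        mode = c("symmetric", "canonical"),
                        meta = list()) {
  mode <- match.arg(mode)
  obs <- findPairsCorpus(corpus, scheme)
  meta$nChains <- length(corpus)
  accumulatePairs(obs, scheme, mode, meta = meta)
}
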