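#' @include scalefree.R
NULL

#' Rank predicates for cell selection
#'
#' Select tensor cells by their population: exactly a given rank, or
#' at least a threshold. The reference analyses use
#' \code{rankAtLeast(50)} for the "highly populated" cells and
#' \code{rankEqual(1)} for singletons.
#'
#' @param threshold rank threshold (>= 1).
#' @return A list of class \code{"RankPredicate"} with fields
#'   \code{kind} and \code{threshold}.
#' @export
#' @examples
#' rankAtLeast(50)
rankAtLeast <- function(threshold) {
  stopifnot(threshold >= 1)
  structure(list(kind = "at_least", threshold = threshold),
            class = "RankPredicate")
}

#' @rdname rankAtLeast
#' @export
rankEqual <- function(threshold) {
  stopifnot(threshold >= 1)
  structure(list(kind = "equal", threshold = threshold),
            class = "RankPredicate")
}

#' @export
print.RankPredicate <- function(x, ...) {
  cat(sprintf("RankPredicate: population %s %g\n",
              if (x$kind == "equal") "==" else ">=", x$threshold))
  invisible(x)
}

.predMask <- function(pred, counts) {
  stopifnot(inherits(pred, "RankPredicate"))
  if (pred$kind == "equal") counts == pred$threshold
  else counts >= pred$threshold
}

#' Amino-acid pair matrix of predicate-selected cells
#'
#' Sums the populations of all cells satisfying a rank predicate into
#' a 20 x 20 matrix indexed by (AA1, AA2): the number of pairs (not
#' cells) carried by those cells. Built from a symmetric-mode tensor
#' the matrix is symmetric. The per-residue marginal (attribute
#' \code{"marginals"}) is row + column sums with the diagonal counted
#' once, so that each pair observation involving a type contributes
#' the insertion-mode multiplier to that type's marginal.
#'
#' @param tensor a \linkS4class{PairTensor} containing the AA1 and AA2
#'   dimensions.
#' @param pred a \code{"RankPredicate"}; default selects every
#'   non-zero cell.
#' @return 20 x 20 numeric matrix with residue dimnames and attribute
#'   \code{"marginals"}.
#' @export
pairMatrix <- function(tensor, pred = rankAtLeast(1)) {
  stopifnot(all(c("AA1", "AA2") %in% tensor@dims))
  aa <- tensor@scheme@aaOrder
  M <- matrix(0, 20, 20, dimnames = list(AA1 = aa, AA2 = aa))
  cl <- tensor@cells
  sel <- cl[.predMask(pred, cl$count), , drop = FALSE]
  if (nrow(sel)) {
    agg <- rowsum(sel$count, group = paste(sel$AA1, sel$AA2))
    key <- do.call(rbind, strsplit(rownames(agg), " "))
    M[cbind(as.integer(key[, 1]), as.integer(key[, 2]))] <- agg[, 1]
  }
  attr(M, "marginals") <- rowSums(M) + colSums(M) - diag(M)
  M
}

#' Per-residue rank-frequency curves and maximum ranks
#'
#' For each residue type X, omega_X(R) counts the cells of population
#' R having X as either pair member; cells whose two members are both
#' X are counted once. The maximum rank of X is the largest
#' population among cells involving X (0 when X never appears).
#'
#' @param tensor a \linkS4class{PairTensor} containing AA1 and AA2.
#' @param rMax optional upper rank limit for the curves.
#' @return List with \code{curves} (named list of rank-frequency
#'   data.frames, one per residue type) and \code{maxRank} (named
#'   numeric vector over the 20 types).
#' @export
perResidueRankCurves <- function(tensor, rMax = Inf) {
  stopifnot(all(c("AA1", "AA2") %in% tensor@dims))
  aa <- tensor@scheme@aaOrder
  cl <- tensor@cells
  curves <- list()
  maxRank <- setNames(numeric(20), aa)
  for (k in seq_along(aa)) {
    sel <- cl$AA1 == k | cl$AA2 == k
    counts <- cl$count[sel]
    counts <- counts[counts <= rMax]
    curves[[aa[k]]] <- rankFrequencyFromCounts(counts)
    maxRank[k] <- if (length(cl$count[sel])) max(cl$count[sel]) else 0
  }
  list(curves = curves, maxRank = maxRank)
}

#' Solvent-accessibility by distance histogram of selected cells
#'
#' Populations of cells satisfying the rank predicate summed into
#' their (SA bin, distance bin) coordinates: the environment portrait
#' of a rank class.
#'
#' @param tensor a \linkS4class{PairTensor} containing SA and D.
#' @param pred a \code{"RankPredicate"}.
#' @return 12 x 14 numeric matrix (SA bins x distance bins) with bin
#'   labels as dimnames.
#' @export
saDistanceHistogram <- function(tensor, pred = rankAtLeast(1)) {
  stopifnot(all(c("SA", "D") %in% tensor@dims))
  sch <- tensor@scheme
  H <- matrix(0, binCounts(sch)[["SA"]], binCounts(sch)[["D"]],
              dimnames = list(SA = binLabels("sa", sch),
                              D = binLabels("dist", sch)))
  cl <- tensor@cells
  sel <- cl[.predMask(pred, cl$count), , drop = FALSE]
  if (nrow(sel)) {
    agg <- rowsum(sel$count, group = paste(sel$SA, sel$D))
    key <- do.call(rbind, strsplit(rownames(agg), " "))
    H[cbind(as.integer(key[, 1]), as.integer(key[, 2]))] <- agg[, 1]
  }
  H
}

#' Secondary-structure composition as a function of rank
#'
#' For each secondary-structure category c, omega_c(R) counts the
#' cells of population R having c as either member's category; cells
#' with both members in c are counted once. Shows how helix, strand,
#' turn and coil populations change with rank.
#'
#' @param tensor a \linkS4class{PairTensor} containing SS1 and SS2.
#' @return Named list of rank-frequency data.frames, one per category.
#' @export
ssVsRank <- function(tensor) {
  stopifnot(all(c("SS1", "SS2") %in% tensor@dims))
  cats <- tensor@scheme@ssCategories
  cl <- tensor@cells
  out <- list()
  for (k in seq_along(cats)) {
    sel <- cl$SS1 == k | cl$SS2 == k
    out[[cats[k]]] <- rankFrequencyFromCounts(cl$count[sel])
  }
  out
}

#' Cumulative number of pairs at or above each rank
#'
#' C(R) = sum over R' >= R of R' * omega(R'): the number of pair
#' observations carried by cells of population at least R. Monotone
#' non-increasing, anchored at the tensor total: C(1) equals the total
#' count.
#'
#' @param tensor a \linkS4class{PairTensor}.
#' @param ranks ranks at which to evaluate; defaults to
#'   \code{1:(max population + 1)}.
#' @return data.frame with columns \code{rank} and \code{cumulative}.
#' @export
cumulativePairsAboveRank <- function(tensor, ranks = NULL) {
  rf <- rankFrequency(tensor)
  if (is.null(ranks)) {
    top <- if (nrow(rf)) max(rf$rank) else 0
    ranks <- seq_len(top + 1)
  }
  mass <- rf$rank * rf$omega
  cum <- vapply(ranks, function(R) sum(mass[rf$rank >= R]), 0)
  data.frame(rank = ranks, cumulative = cum)
}

#' Compare natural residue occurrence with pair participation
#'
#' Contrasts the overall amino-acid composition of a corpus with the
#' fraction of pair observations each residue type takes part in
#' (the per-type marginal of [pairMatrix()] over all cells,
#' normalized). The reference result: the types dominating pair
#' participation need not be the most abundant types.
#'
#' @param corpus list of \linkS4class{ValidatedChain} the tensor was
#'   built from.
#' @param tensor the corresponding \linkS4class{PairTensor}.
#' @return data.frame with columns \code{aa}, \code{composition} and
#'   \code{participation}, each fraction column summing to 1
#'   (participation is all-NA, with a warning, for a pair-free
#'   tensor).
#' @export
occurrenceComparison <- function(corpus, tensor) {
  aa <- tensor@scheme@aaOrder
  resCounts <- table(factor(unlist(lapply(corpus,
                                          function(c) residues(c)$aa)),
                            levels = aa))
  comp <- as.numeric(resCounts) / sum(resCounts)
  marg <- attr(pairMatrix(tensor, rankAtLeast(1)), "marginals")
  if (sum(marg) == 0) {
    warning("tensor holds no pairs; participation fractions undefined")
    part <- rep(NA_real_, 20)
  } else part <- as.numeric(marg) / sum(marg)
  data.frame(aa = aa, composition = comp, participation = part,
             stringsAsFactors = FALSE)
}
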