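#' @include pairs.R
NULL

#' @describeIn projectTensor sum counts over dropped dimensions of a
#'   \code{PairTensor}.
#' @export
setMethod("projectTensor", "PairTensor", function(x, keep) {
  if (!length(keep)) stop("keep must name at least one dimension")
  if (!all(keep %in% x@dims))
    stop("cannot keep dimension(s) not present in the tensor: ",
         paste(setdiff(keep, x@dims), collapse = ", "))
  keep <- x@dims[x@dims %in% keep]  # canonical order
  if (identical(keep, x@dims)) return(x)
  dt <- data.table::as.data.table(x@cells)
  proj <- as.data.frame(dt[, list(count = sum(count)), by = keep])
  proj <- proj[do.call(order, proj[keep]), , drop = FALSE]
  .newPairTensor(proj, x@scheme, dims = keep, mode = x@mode,
                 nObs = x@nObs, meta = x@meta)
})

#' @describeIn rankFrequency tabulate cell populations of a
#'   \code{PairTensor}.
#' @export
setMethod("rankFrequency", "PairTensor", function(x) {
  rankFrequencyFromCounts(x@cells$count)
})

#' Rank-frequency table from a vector of cell populations
#'
#' @param counts numeric vector of non-zero cell populations.
#' @return data.frame with columns \code{rank} (the distinct
#'   population sizes R) and \code{omega} (the number of cells with
#'   that population), ordered by rank. Satisfies
#'   \code{sum(omega) == length(counts)} and
#'   \code{sum(rank * omega) == sum(counts)}.
#' @export
rankFrequencyFromCounts <- function(counts) {
  counts <- counts[counts > 0]
  if (!length(counts))
    return(data.frame(rank = numeric(), omega = integer()))
  tab <- table(counts)
  data.frame(rank = as.numeric(names(tab)),
             omega = as.integer(tab),
             row.names = NULL)
}

#' Fit the rank-frequency power law in log2-log2 space
#'
#' Ordinary least squares of log2(omega(R)) on log2(R) over the stored
#' table entries, one unweighted point per distinct rank (ranks with
#' omega = 0 never enter, matching the plotted construction). The
#' slope estimates -lambda of omega(R) = c R^-lambda. Goodness is the
#' absolute Pearson correlation of the log-log points (the
#' conventional closer-to-1-is-better figure of merit) together with
#' the residual RMSE.
#'
#' @param x a rank-frequency data.frame (\code{rank}, \code{omega}) or
#'   a \linkS4class{PairTensor} (its [rankFrequency()] is fitted).
#' @param rMin,rMax fit range on the rank axis, inclusive; defaults to
#'   all observed ranks.
#' @return A \linkS4class{PowerLawFit}.
#' @export
#' @examples
#' r <- 1:64
#' tab <- data.frame(rank = r, omega = 2^(14.3 - 2.26 * log2(r)))
#' fitPowerLaw(tab)   # slope -2.26, intercept 14.3, |r| = 1
fitPowerLaw <- function(x, rMin = 1, rMax = Inf) {
  tab <- if (is(x, "PairTensor")) rankFrequency(x) else x
  stopifnot(all(c("rank", "omega") %in% names(tab)))
  tab <- tab[tab$rank >= rMin & tab$rank <= rMax & tab$omega > 0, ,
             drop = FALSE]
  n <- nrow(tab)
  if (n < 3L)
    stop("fitPowerLaw needs at least 3 distinct ranks in range; got ", n)
  lx <- log2(tab$rank)
  ly <- log2(tab$omega)
  fit <- stats::lm(ly ~ lx)
  cf <- stats::coef(fit)
  ci <- tryCatch(suppressWarnings(stats::confint(fit, "lx", level = 0.95)),
                 error = function(e) matrix(c(cf[2], cf[2]), 1))
  ci <- as.numeric(ci)
  ci[is.na(ci)] <- cf[2]
  r <- suppressWarnings(stats::cor(lx, ly))
  if (is.na(r)) r <- 0  # degenerate: zero variance in omega
  new("PowerLawFit",
      slope     = unname(cf[2]),
      intercept = unname(cf[1]),
      slopeCI   = ci,
      pearsonR  = abs(r),
      rmse      = sqrt(mean(stats::resid(fit)^2)),
      nPoints   = n)
}

#' Largest rank of the contiguous head of a rank-frequency table
#'
#' The largest R such that every rank 1..R is present in the table.
#' Beyond this point the expected number of cells per rank drops below
#' one and the observable omega values are censored at zero (absent
#' ranks never enter a fit) or one, which biases a full-range log-log
#' fit towards shallow slopes; restricting the fit range to the
#' contiguous head avoids that sporadic-tail regime.
#'
#' @param rankTable data.frame with a \code{rank} column.
#' @return Integer, 0 when rank 1 is absent.
#' @seealso [fitPowerLaw()]
#' @export
#' @examples
#' contiguousRankMax(data.frame(rank = c(1, 2, 3, 7), omega = c(9, 4, 2, 1)))
contiguousRankMax <- function(rankTable) {
  r <- rankTable$rank
  k <- 0L
  while ((k + 1L) %in% r) k <- k + 1L
  k
}

#' All dimension subsets containing the two residue-type axes
#'
#' The 64 subsets obtained by always keeping AA1 and AA2 and freely
#' including or excluding the remaining six dimensions, the family
#' scanned when looking for the minimal sub-space that preserves the
#' scale-free signature.
#'
#' @param minExtra minimum number of extra dimensions beyond AA1/AA2.
#' @return List of character vectors.
#' @export
aaSubspaces <- function(minExtra = 0L) {
  extra <- setdiff(.DIM_NAMES, c("AA1", "AA2"))
  subsets <- list()
  for (k in seq(minExtra, length(extra))) {
    if (k == 0L) { subsets[[length(subsets) + 1L]] <- c("AA1", "AA2"); next }
    cmb <- utils::combn(extra, k, simplify = FALSE)
    for (s in cmb)
      subsets[[length(subsets) + 1L]] <- c("AA1", "AA2", s)
  }
  subsets
}

#' Scan dimension subsets for scale-free behaviour
#'
#' For each subset: project the tensor, build the rank-frequency
#' table, fit the power law, and keep the subsets whose goodness
#' (absolute Pearson correlation of the log-log fit) reaches the
#' floor. Rows are sorted by decreasing goodness. Subsets whose fit
#' fails (fewer than 3 distinct ranks) are skipped and reported.
#'
#' @param tensor a \linkS4class{PairTensor}.
#' @param subsets list of character vectors of dimension names;
#'   defaults to [aaSubspaces()].
#' @param goodnessFloor minimum goodness retained (the reference
#'   analysis tabulates subsets at or above 0.980).
#' @param rMin,rMax fit range passed to [fitPowerLaw()].
#' @return data.frame with columns \code{dimensions} (space-separated
#'   names), \code{slope}, \code{ciLow}, \code{ciHigh},
#'   \code{intercept}, \code{goodness}, \code{rmse}, \code{nPoints};
#'   attribute \code{"skipped"} lists subsets that could not be
#'   fitted, with reasons.
#' @export
subspaceScan <- function(tensor, subsets = aaSubspaces(),
                         goodnessFloor = 0.980, rMin = 1, rMax = Inf) {
  rows <- list()
  skipped <- character()
  for (s in subsets) {
    label <- paste(s, collapse = " ")
    fit <- tryCatch(
      fitPowerLaw(projectTensor(tensor, s), rMin = rMin, rMax = rMax),
      error = function(e) conditionMessage(e))
    if (is.character(fit)) {
      skipped[label] <- fit
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      dimensions = label,
      slope = fit@slope, ciLow = fit@slopeCI[1], ciHigh = fit@slopeCI[2],
      intercept = fit@intercept, goodness = fit@pearsonR,
      rmse = fit@rmse, nPoints = fit@nPoints,
      stringsAsFactors = FALSE)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(dimensions = character(), slope = numeric(),
                         ciLow = numeric(), ciHigh = numeric(),
                         intercept = numeric(), goodness = numeric(),
                         rmse = numeric(), nPoints = integer(),
                         stringsAsFactors = FALSE)
  out <- out[out$goodness >= goodnessFloor, , drop = FALSE]
  out <- out[order(-out$goodness), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "skipped") <- skipped
  out
}
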