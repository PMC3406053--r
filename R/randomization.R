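#' @include pairs.R
NULL

#' Shuffle residue-type labels within a chain
#'
#' Applies a uniform random permutation to the residue-type labels of
#' a chain while leaving every positional attribute (C-alpha and
#' functional-atom coordinates, solvent accessibility, secondary
#' structure, sequence index) at its position. The amino-acid
#' composition of the chain is conserved exactly. This is the
#' within-chain null model: positions keep their spatial signature and
#' only the identity written at each position is randomized.
#'
#' @param chain a \linkS4class{ValidatedChain}.
#' @param seed integer seed; the permutation is deterministic given it.
#' @param permutation optional explicit permutation of
#'   \code{seq_len(chainLength(chain))}, overriding the random draw
#'   (the identity permutation reproduces the input, a useful test
#'   hook).
#' @return A \linkS4class{ValidatedChain} with permuted \code{aa}
#'   labels. Note the functional-atom coordinates stay those observed
#'   at each position, so after shuffling they need not match the atom
#'   complement of the new label.
#' @export
shuffleLabels <- function(chain, seed = NULL, permutation = NULL) {
  r <- residues(chain)
  n <- nrow(r)
  if (is.null(permutation)) {
    if (!is.null(seed)) {
      old <- if (exists(".Random.seed", globalenv()))
        get(".Random.seed", globalenv()) else NULL
      on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
      set.seed(as.integer(seed))
    }
    permutation <- sample.int(n)
  }
  stopifnot(length(permutation) == n,
            all(sort(permutation) == seq_len(n)))
  r$aa <- r$aa[permutation]
  methods::initialize(chain, residues = r)
}

#' Build the composition-preserving randomized reference tensor
#'
#' For each of \code{nReps} repetitions, every chain of the corpus is
#' label-shuffled ([shuffleLabels()]) and the full pair pipeline is
#' re-run ([findPairs()] then [accumulatePairs()]); the returned
#' reference is the cell-wise mean of the repetition tensors (counts
#' may therefore be fractional). Deterministic given \code{seed}: one
#' master seed spawns an independent sub-seed per (chain, repetition).
#'
#' @param corpus non-empty list of \linkS4class{ValidatedChain}.
#' @param nReps number of shuffling repetitions to average (>= 1);
#'   the reference study design uses 10.
#' @param seed integer master seed.
#' @param scheme a \linkS4class{BinScheme}.
#' @param mode insertion mode, as in [accumulatePairs()].
#' @param identityPermutation if \code{TRUE} the "shuffle" is the
#'   identity permutation (test hook: the reference then equals the
#'   observed tensor).
#' @return A \linkS4class{ReferenceTensor}.
#' @export
buildReference <- function(corpus, nReps = 10L, seed = 1L,
                           scheme = defaultBinScheme(),
                           mode = c("symmetric", "canonical"),
                           identityPermutation = FALSE) {
  mode <- match.arg(mode)
  if (!length(corpus)) stop("empty corpus")
  nReps <- as.integer(nReps)
  stopifnot(nReps >= 1L)
  nCh <- length(corpus)
  seeds <- matrix(.spawnSeeds(seed, nCh * nReps), nrow = nCh)
  repTensors <- vector("list", nReps)
  for (rep in seq_len(nReps)) {
    obs <- vector("list", nCh)
    for (k in seq_len(nCh)) {
      ch <- if (identityPermutation) corpus[[k]]
            else shuffleLabels(corpus[[k]], seed = seeds[k, rep])
      obs[[k]] <- findPairs(ch, scheme)
    }
    repTensors[[rep]] <- accumulatePairs(do.call(rbind, obs), scheme, mode)
  }
  allCells <- data.table::rbindlist(lapply(repTensors,
                                           function(t) t@cells))
  allCells$count <- allCells$count / nReps
  mean_ <- allCells[, list(count = sum(count)), by = .DIM_NAMES]
  mean_ <- as.data.frame(mean_)
  mean_ <- mean_[do.call(order, mean_[.DIM_NAMES]), , drop = FALSE]
  avg <- .newPairTensor(mean_, scheme, mode = mode,
                        nObs = mean(vapply(repTensors, slot, 0, "nObs")),
                        meta = list(reference = TRUE, nReps = nReps,
                                    seed = as.integer(seed)))
  new("ReferenceTensor", tensor = avg, nReps = nReps,
      seed = as.integer(seed))
}

#' Observed/expected significance ratios per cell
#'
#' For every cell with observed count > 0, the ratio between the
#' observed count and the averaged reference count. Cells observed
#' but never seen in the randomized reference have no finite ratio
#' and are flagged infinite; they are the most significant cells.
#'
#' @param observed a \linkS4class{PairTensor}.
#' @param reference a \linkS4class{ReferenceTensor} (or a
#'   \linkS4class{PairTensor} used directly as the expectation) built
#'   under the same bin scheme, dimensions and insertion mode.
#' @return data.frame with the index columns of \code{observed},
#'   \code{observed}, \code{expected} and \code{ratio} (\code{Inf}
#'   where \code{expected} is 0); attribute \code{"infiniteCells"}
#'   gives the row indices of the infinite-ratio cells.
#' @export
ratioMap <- function(observed, reference) {
  ref <- if (is(reference, "ReferenceTensor")) reference@tensor
         else reference
  if (!identical(observed@dims, ref@dims))
    stop("observed and reference tensors span different dimensions")
  if (!identical(binCounts(observed@scheme), binCounts(ref@scheme)))
    stop("observed and reference tensors use different bin schemes")
  if (!identical(observed@mode, ref@mode))
    stop("observed and reference tensors use different insertion modes")
  d <- observed@dims
  obs <- data.table::as.data.table(observed@cells)
  exp_ <- data.table::as.data.table(ref@cells)
  data.table::setnames(obs, "count", "observed")
  data.table::setnames(exp_, "count", "expected")
  m <- merge(obs, exp_, by = d, all.x = TRUE)
  m$expected[is.na(m$expected)] <- 0
  m$ratio <- ifelse(m$expected > 0, m$observed / m$expected, Inf)
  out <- as.data.frame(m)
  out <- out[do.call(order, out[d]), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "infiniteCells") <- which(is.infinite(out$ratio))
  out
}
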