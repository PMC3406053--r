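# Independent oracles and hand-built fixtures shared across test files.
# Everything here is deliberately literal (double loops, scalar
# arithmetic) so it cannot share a code path with the implementation.

# Build a small ValidatedChain by hand. f1/f2 are n x 3 matrices of
# functional-atom coordinates (f2 rows NA for single-atom types); ca
# defaults to f1.
makeChain <- function(aa, f1, f2 = NULL, sa = NULL, ss = NULL,
                      ca = NULL, structureId = "1TST", chainId = "A",
                      authNum = NULL) {
  n <- length(aa)
  f1 <- matrix(f1, ncol = 3)
  if (is.null(f2)) f2 <- matrix(NA_real_, n, 3)
  if (is.null(ca)) ca <- f1
  if (is.null(sa)) sa <- rep(5, n)
  if (is.null(ss)) ss <- rep("helix", n)
  if (is.null(authNum)) authNum <- seq_len(n)
  resdf <- data.frame(aa = aa, seqIndex = seq_len(n),
                      authNum = authNum, insCode = "_",
                      caX = ca[, 1], caY = ca[, 2], caZ = ca[, 3],
                      f1X = f1[, 1], f1Y = f1[, 2], f1Z = f1[, 3],
                      f2X = f2[, 1], f2Y = f2[, 2], f2Z = f2[, 3],
                      ss = ss, sa = sa, stringsAsFactors = FALSE)
  new("ValidatedChain", structureId = structureId, chainId = chainId,
      residues = resdf)
}

# Scalar Euclidean distance.
.dist3 <- function(a, b) sqrt(sum((a - b)^2))

# Literal minimum functional-atom distance between residue rows i, j
# of a residue data.frame.
oracleMinDist <- function(r, i, j) {
  atoms <- function(k) {
    out <- list(c(r$f1X[k], r$f1Y[k], r$f1Z[k]))
    if (!is.na(r$f2X[k])) out <- c(out, list(c(r$f2X[k], r$f2Y[k], r$f2Z[k])))
    out
  }
  ai <- atoms(i); aj <- atoms(j)
  best <- Inf
  for (a in ai) for (b in aj) best <- min(best, .dist3(a, b))
  best
}

# Brute-force pair finder applying the three rules literally:
# same chain (given), same SA bin, min functional distance < maxDist.
# Returns a data.frame of (i, j, dist) with i < j by seqIndex.
oraclePairs <- function(chain, scheme = defaultBinScheme(),
                        maxDist = 8.25) {
  r <- residues(chain)
  n <- nrow(r)
  out <- list()
  if (n >= 2) {
    saBin <- vapply(r$sa, function(v) assignBin(v, "sa", scheme), 1L)
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        if (saBin[i] != saBin[j]) next
        d <- oracleMinDist(r, i, j)
        if (d < maxDist)
          out[[length(out) + 1L]] <- data.frame(i = i, j = j, dist = d)
      }
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(i = integer(), j = integer(), dist = numeric())
}

# A small random sparse tensor over arbitrary dims, for projection /
# ratio oracles.
randomSparseTensor <- function(nCells = 200, seed = 1,
                               scheme = defaultBinScheme(),
                               maxCount = 9) {
  set.seed(seed)
  bc <- binCounts(scheme)
  repeat {
    idx <- as.data.frame(lapply(bc, function(k)
      sample.int(k, nCells, replace = TRUE)))
    names(idx) <- tensorDimNames()
    if (!anyDuplicated(idx)) break
    nCells <- nCells  # resample on collision
  }
  idx$count <- sample.int(maxCount, nCells, replace = TRUE)
  PairSpace:::.newPairTensor(idx, scheme, mode = "canonical",
                             nObs = sum(idx$count))
}

# Deterministic small synthetic corpus used by several files.
smallCorpus <- function(nChains = 8, lengths = c(40, 80), seed = 424) {
  generateCorpus(corpusParams(nChains = nChains, lengthRange = lengths,
                              seed = seed))
}
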