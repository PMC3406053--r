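test_that("projection conserves totals and the identity projection is a no-op", {
  tt <- randomSparseTensor(nCells = 300, seed = 21)
  expect_identical(projectTensor(tt, tensorDimNames()), tt)
  set.seed(3)
  for (k in 1:6) {
    keep <- sample(tensorDimNames(), sample(1:7, 1))
    pj <- projectTensor(tt, keep)
    expect_equal(tensorTotal(pj), tensorTotal(tt))
    expect_true(all(pj@dims %in% tensorDimNames()))
  }
  expect_error(projectTensor(tt, character()), "at least one")
  # projecting a projection cannot resurrect dropped dimensions
  pj <- projectTensor(tt, c("AA1", "AA2"))
  expect_error(projectTensor(pj, c("AA1", "SA")), "not present")
})

test_that("projection equals an independent nested-loop marginalization", {
  tt <- randomSparseTensor(nCells = 120, seed = 33)
  keep <- c("SA", "D")
  pj <- projectTensor(tt, keep)
  # oracle: accumulate into a dense 12 x 14 array by looping rows
  dense <- matrix(0, 12, 14)
  cl <- tt@cells
  for (k in seq_len(nrow(cl)))
    dense[cl$SA[k], cl$D[k]] <- dense[cl$SA[k], cl$D[k]] + cl$count[k]
  for (k in seq_len(nrow(pj@cells)))
    expect_equal(pj@cells$count[k], dense[pj@cells$SA[k], pj@cells$D[k]])
  expect_identical(nrow(pj@cells), sum(dense > 0))
})

test_that("the residue-plane projection has at most 400 cells", {
  corpus <- smallCorpus(nChains = 5, lengths = c(40, 80), seed = 44)
  tt <- buildTensor(corpus)
  pj <- projectTensor(tt, c("AA1", "AA2"))
  expect_lte(nonzeroCells(pj), 400)
  expect_equal(tensorTotal(pj), tensorTotal(tt))
})

test_that("rank-frequency tables are exact population histograms", {
  t1 <- randomSparseTensor(nCells = 3, seed = 1)
  t1@cells$count <- c(1, 1, 2)
  rf <- rankFrequencyFromCounts(t1@cells$count)
  expect_equal(rf, data.frame(rank = c(1, 2), omega = c(2L, 1L)))
  # all cells equal
  expect_equal(rankFrequencyFromCounts(rep(7, 13)),
               data.frame(rank = 7, omega = 13L))
  # conservation identities on a larger random tensor
  tt <- randomSparseTensor(nCells = 500, seed = 8, maxCount = 30)
  rf2 <- rankFrequency(tt)
  expect_equal(sum(rf2$omega), nonzeroCells(tt))
  expect_equal(sum(rf2$rank * rf2$omega), tensorTotal(tt))
})

test_that("points exactly on a log2 line are recovered to machine precision", {
  r <- 1:80
  tab <- data.frame(rank = r, omega = 2^(14.3 - 2.26 * log2(r)))
  fit <- fitPowerLaw(tab)
  expect_equal(fit@slope, -2.26, tolerance = 1e-12)
  expect_equal(fit@intercept, 14.3, tolerance = 1e-12)
  expect_equal(fit@pearsonR, 1, tolerance = 1e-12)
  expect_lt(fit@rmse, 1e-12)
  expect_identical(fit@nPoints, 80L)
})

test_that("fits require at least three distinct ranks", {
  expect_error(fitPowerLaw(data.frame(rank = c(1, 2), omega = c(5, 2))),
               "got 2")
  expect_error(fitPowerLaw(data.frame(rank = 1:10, omega = rep(1, 10)),
                           rMax = 2), "got 2")
})

test_that("scaling all counts by an integer shifts only the intercept", {
  r <- 1:64
  tab <- data.frame(rank = r, omega = 2^(12 - 1.8 * log2(r)))
  f1 <- fitPowerLaw(tab)
  tab8 <- data.frame(rank = 8 * tab$rank, omega = tab$omega)
  # scaling the cell populations scales the rank axis: slope invariant
  f2 <- fitPowerLaw(tab8)
  expect_equal(f2@slope, f1@slope, tolerance = 1e-10)
  expect_equal(f2@intercept, f1@intercept + 1.8 * 3, tolerance = 1e-10)
})

test_that("generated power-law tensors are recovered within 0.15 over the contiguous head", {
  ok <- 0L
  for (s in 1:6) {
    tt <- generatePowerlawTensor(2.3, 2e4, 1000, seed = s)
    rf <- rankFrequency(tt)
    fit <- fitPowerLaw(rf, rMax = contiguousRankMax(rf))
    if (abs(fit@slope + 2.3) <= 0.2) ok <- ok + 1L
  }
  expect_gte(ok, 5L)
})

test_that("contiguousRankMax finds the first gap in the rank table", {
  expect_identical(contiguousRankMax(data.frame(rank = c(1, 2, 3, 7))), 3L)
  expect_identical(contiguousRankMax(data.frame(rank = c(2, 3))), 0L)
  expect_identical(contiguousRankMax(data.frame(rank = numeric())), 0L)
})

test_that("subspace scans agree with manual per-subset pipelines", {
  corpus <- smallCorpus(nChains = 20, lengths = c(60, 140), seed = 55)
  tt <- buildTensor(corpus)
  full <- subspaceScan(tt, subsets = list(tensorDimNames()),
                       goodnessFloor = 0)
  direct <- fitPowerLaw(tt)
  expect_equal(full$slope, direct@slope)
  expect_equal(full$goodness, direct@pearsonR)
  # a goodness floor above 1 empties the report (|r| <= 1)
  none <- subspaceScan(tt, subsets = list(tensorDimNames()),
                       goodnessFloor = 1.1)
  expect_identical(nrow(none), 0L)
  # compositional oracle over a handful of subsets
  subs <- list(c("AA1", "AA2"), c("AA1", "AA2", "SA"),
               c("AA1", "AA2", "SA", "D"),
               c("AA1", "AA2", "SD", "CL"))
  rep_ <- subspaceScan(tt, subsets = subs, goodnessFloor = 0)
  for (k in seq_len(nrow(rep_))) {
    keep <- strsplit(rep_$dimensions[k], " ")[[1]]
    manual <- fitPowerLaw(rankFrequency(projectTensor(tt, keep)))
    expect_equal(rep_$slope[k], manual@slope)
    expect_equal(rep_$goodness[k], manual@pearsonR)
  }
  # sorted by decreasing goodness
  expect_true(!is.unsorted(rev(rep_$goodness)))
  # subsets that cannot be fitted are reported as skipped
  tiny <- accumulatePairs(
    findPairs(makeChain(c("GLY", "GLY"), f1 = rbind(c(0, 0, 0), c(3, 0, 0)))))
  skipRep <- subspaceScan(tiny, subsets = list(c("AA1", "AA2")),
                          goodnessFloor = 0)
  expect_identical(nrow(skipRep), 0L)
  expect_length(attr(skipRep, "skipped"), 1)
})

test_that("the residue-plane subspace family has 64 members, all containing AA1 and AA2", {
  subs <- aaSubspaces()
  expect_length(subs, 64)
  expect_true(all(vapply(subs, function(s)
    all(c("AA1", "AA2") %in% s), logical(1))))
  expect_length(aaSubspaces(minExtra = 1), 63)
})
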