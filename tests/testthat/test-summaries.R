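aaIdx <- function(code) match(code, aminoAcids3())

# tensor with hand-placed cells for the trivial examples
cellTensor <- function(cells) {
  PairSpace:::.newPairTensor(cells, defaultBinScheme(),
                             mode = "canonical", nObs = sum(cells$count))
}

oneCell <- function(aa1, aa2, count, sa = 2L, d = 6L, ss1 = 1L, ss2 = 1L,
                    cl = 3L, sd = 6L) {
  data.frame(AA1 = aaIdx(aa1), AA2 = aaIdx(aa2), SA = sa, D = d,
             SS1 = ss1, SS2 = ss2, CL = cl, SD = sd, count = count)
}

test_that("pair matrices sum predicate-selected cell populations into residue pairs", {
  tt <- cellTensor(oneCell("LEU", "LEU", 7))
  M <- pairMatrix(tt, rankAtLeast(5))
  expect_equal(M["LEU", "LEU"], 7)
  expect_equal(sum(M), 7)
  expect_equal(sum(pairMatrix(tt, rankAtLeast(8))), 0)  # above max
  expect_equal(sum(pairMatrix(tt, rankEqual(7))), 7)
  expect_equal(sum(pairMatrix(tt, rankEqual(6))), 0)
  # marginals: diagonal counted once
  expect_equal(unname(attr(M, "marginals")[["LEU"]]), 7)
})

test_that("matrix, histogram and rank-1 counting identities hold on random tensors", {
  tt <- randomSparseTensor(nCells = 400, seed = 13, maxCount = 6)
  expect_equal(sum(pairMatrix(tt, rankAtLeast(1))), tensorTotal(tt))
  # rank-1 matrix total = number of rank-1 cells
  rf <- rankFrequency(tt)
  n1 <- rf$omega[rf$rank == 1]
  expect_equal(sum(pairMatrix(tt, rankEqual(1))), n1)
  # histogram and matrix totals agree under every predicate
  for (pred in list(rankAtLeast(1), rankAtLeast(3), rankEqual(2))) {
    expect_equal(sum(saDistanceHistogram(tt, pred)),
                 sum(pairMatrix(tt, pred)))
  }
  # symmetric-mode tensors give symmetric matrices
  sym <- buildTensor(smallCorpus(4, c(40, 70), seed = 14))
  M <- pairMatrix(sym, rankAtLeast(1))
  expect_equal(M, t(M), ignore_attr = TRUE)
})

test_that("per-residue curves count cells once per member type and report max ranks", {
  tt <- cellTensor(oneCell("VAL", "ALA", 12))
  prc <- perResidueRankCurves(tt)
  expect_equal(unname(prc$maxRank[c("VAL", "ALA")]), c(12, 12))
  expect_equal(sum(prc$maxRank) - 24, 0)  # all others 0
  expect_equal(prc$curves$VAL, data.frame(rank = 12, omega = 1L))
  # empty tensor
  empty <- accumulatePairs(
    findPairs(makeChain("GLY", f1 = rbind(c(0, 0, 0)))))
  prcE <- perResidueRankCurves(empty)
  expect_true(all(prcE$maxRank == 0))
  expect_true(all(vapply(prcE$curves, nrow, 1L) == 0L))
  # enumeration oracle: sum over types of curve mass = cells counted
  # once per distinct member type
  tt2 <- randomSparseTensor(nCells = 300, seed = 15)
  prc2 <- perResidueRankCurves(tt2)
  lhs <- sum(vapply(prc2$curves, function(c_) sum(c_$omega), 1))
  rhs <- sum(ifelse(tt2@cells$AA1 == tt2@cells$AA2, 1, 2))
  expect_equal(lhs, rhs)
})

test_that("SA x distance histograms place populations at their bin coordinates", {
  tt <- cellTensor(oneCell("LEU", "ILE", 9, sa = 1L, d = 5L))
  H <- saDistanceHistogram(tt, rankAtLeast(1))
  expect_equal(H[1, 5], 9)
  expect_equal(sum(H), 9)
  expect_identical(dim(H), c(12L, 14L))
  # rank predicate that matches nothing
  tt2 <- cellTensor(rbind(oneCell("LEU", "ILE", 2, sa = 3L),
                          oneCell("ALA", "GLY", 2, sa = 4L)))
  expect_equal(sum(saDistanceHistogram(tt2, rankEqual(1))), 0)
})

test_that("secondary-structure curves count cells once per member category", {
  tt <- cellTensor(oneCell("LEU", "LEU", 50, ss1 = 1L, ss2 = 2L))
  sv <- ssVsRank(tt)
  expect_equal(sv$helix, data.frame(rank = 50, omega = 1L))
  expect_equal(sv$strand, data.frame(rank = 50, omega = 1L))
  expect_identical(nrow(sv$turn), 0L)
  expect_identical(nrow(sv$coil), 0L)
  # enumeration oracle on a random tensor
  tt2 <- randomSparseTensor(nCells = 250, seed = 16)
  sv2 <- ssVsRank(tt2)
  lhs <- sum(vapply(sv2, function(c_) sum(c_$omega), 1))
  rhs <- sum(ifelse(tt2@cells$SS1 == tt2@cells$SS2, 1, 2))
  expect_equal(lhs, rhs)
})

test_that("cumulative pair counts are the tail sums of the rank table", {
  tt <- cellTensor(rbind(oneCell("ALA", "ALA", 1),
                         oneCell("ALA", "GLY", 2),
                         oneCell("GLY", "LEU", 3)))
  cum <- cumulativePairsAboveRank(tt)
  expect_equal(cum$cumulative, c(6, 5, 3, 0))
  # single cell of population k
  single <- cellTensor(oneCell("TRP", "TRP", 5))
  cs <- cumulativePairsAboveRank(single, ranks = 1:6)
  expect_equal(cs$cumulative, c(5, 5, 5, 5, 5, 0))
  # direct-summation oracle + monotonicity + anchoring
  tt2 <- randomSparseTensor(nCells = 350, seed = 17, maxCount = 12)
  cum2 <- cumulativePairsAboveRank(tt2)
  expect_equal(cum2$cumulative[1], tensorTotal(tt2))
  expect_true(all(diff(cum2$cumulative) <= 0))
  cnt <- tt2@cells$count
  for (R in c(1, 3, 7, 12))
    expect_equal(cum2$cumulative[cum2$rank == R], sum(cnt[cnt >= R]))
})

test_that("occurrence comparison contrasts composition with pair participation", {
  mono <- makeChain(rep("ALA", 10),
                    f1 = cbind(seq(0, 27, by = 3), 0, 0))
  tt <- buildTensor(list(mono))
  oc <- occurrenceComparison(list(mono), tt)
  expect_equal(oc$composition[oc$aa == "ALA"], 1)
  expect_equal(sum(oc$composition), 1)
  expect_equal(sum(oc$participation), 1, tolerance = 1e-12)
  # a pair-free corpus flags participation as undefined
  lone <- makeChain("GLY", f1 = rbind(c(0, 0, 0)))
  ttE <- buildTensor(list(lone))
  expect_warning(ocE <- occurrenceComparison(list(lone), ttE),
                 "undefined")
  expect_true(all(is.na(ocE$participation)))
  # fractions sum to 1 on a heterogeneous corpus
  corpus <- smallCorpus(5, c(40, 80), seed = 18)
  ttC <- buildTensor(corpus)
  occ <- occurrenceComparison(corpus, ttC)
  expect_equal(sum(occ$composition), 1, tolerance = 1e-12)
  expect_equal(sum(occ$participation), 1, tolerance = 1e-12)
})
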