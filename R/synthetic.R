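#' @include structureIO.R pairs.R
NULL

## Average amino-acid frequencies of natural globular proteins
## (UniProt-scale composition, percent, renormalized).
.NATURAL_COMPOSITION <- c(
  ALA = 8.25, ARG = 5.53, ASN = 4.06, ASP = 5.45, CYS = 1.38,
  GLN = 3.93, GLU = 6.75, GLY = 7.07, HIS = 2.27, ILE = 5.96,
  LEU = 9.66, LYS = 5.84, MET = 2.42, PHE = 3.86, PRO = 4.70,
  SER = 6.56, THR = 5.34, TRP = 1.08, TYR = 2.92, VAL = 6.87)

## Approximate C-alpha to functional-atom offsets (Angstrom); the
## second entry of two-atom types sits near the first.
.FUNC_OFFSET <- c(
  ALA = 1.5, ARG = 7.0, ASN = 3.5, ASP = 3.6, CYS = 2.8,
  GLN = 4.6, GLU = 4.9, GLY = 0.0, HIS = 3.2, ILE = 2.5,
  LEU = 2.6, LYS = 6.4, MET = 4.0, PHE = 5.0, PRO = 2.4,
  SER = 2.4, THR = 2.4, TRP = 4.5, TYR = 6.5, VAL = 2.5)

.HYDROPHOBIC <- c("ALA", "ILE", "LEU", "VAL", "PHE", "MET")

#' Parameters of the synthetic protein-chain generator
#'
#' Defines the statistical structure the generator emulates: chain
#' lengths, residue composition, secondary-structure segmentation,
#' the burial (solvent-accessibility) mixture and the per-type
#' functional-atom geometry. Defaults describe a natural-composition
#' corpus of single-chain globular proteins at least 40 residues
#' long, with hydrophobic types enriched inside helix/strand segments
#' and biased towards the buried accessibility shell, so that the
#' buried-core pairing signal of real structures has a synthetic
#' analogue.
#'
#' @param nChains number of chains.
#' @param lengthRange integer range chain lengths are drawn from
#'   uniformly (minimum 40, matching the corpus filter of the study
#'   design).
#' @param composition named frequency vector over the 20 residue
#'   types; normalized internally.
#' @param segMeanLen named mean segment lengths per secondary-structure
#'   category.
#' @param segProb named sampling probabilities of segment categories.
#' @param hydroBoost multiplicative enrichment of hydrophobic types
#'   (Ala, Ile, Leu, Val, Phe, Met) inside helix/strand segments.
#' @param buriedProbHydro,buriedProbOther probability that a
#'   hydrophobic / other residue falls in the buried (0,10] SA shell.
#' @param zeroSAProb probability of an exactly-zero SA value (the
#'   SA<=0 bin).
#' @param exposedMaxSA upper bound of the exposed SA draw; above 100
#'   exercises the SA>100 bin.
#' @param seed mandatory integer master seed.
#' @return List of class \code{"CorpusParams"}.
#' @export
corpusParams <- function(nChains = 50L,
                         lengthRange = c(40L, 200L),
                         composition = .NATURAL_COMPOSITION,
                         segMeanLen = c(helix = 10, strand = 6,
                                        turn = 3, coil = 6),
                         segProb = c(helix = 0.32, strand = 0.22,
                                     turn = 0.14, coil = 0.32),
                         hydroBoost = 1.8,
                         buriedProbHydro = 0.65,
                         buriedProbOther = 0.30,
                         zeroSAProb = 0.02,
                         exposedMaxSA = 108,
                         seed) {
  if (missing(seed)) stop("corpusParams: seed is mandatory")
  stopifnot(length(lengthRange) == 2L, lengthRange[1] >= 1L,
            lengthRange[2] >= lengthRange[1],
            setequal(names(composition), .AA3),
            all(composition >= 0), sum(composition) > 0)
  structure(list(nChains = as.integer(nChains),
                 lengthRange = as.integer(lengthRange),
                 composition = composition[.AA3] / sum(composition),
                 segMeanLen = segMeanLen[.SS_CATEGORIES],
                 segProb = segProb[.SS_CATEGORIES] /
                   sum(segProb[.SS_CATEGORIES]),
                 hydroBoost = hydroBoost,
                 buriedProbHydro = buriedProbHydro,
                 buriedProbOther = buriedProbOther,
                 zeroSAProb = zeroSAProb,
                 exposedMaxSA = exposedMaxSA,
                 seed = as.integer(seed)),
            class = "CorpusParams")
}

.unitVec <- function() {
  v <- stats::rnorm(3)
  v / sqrt(sum(v^2))
}

.perpTo <- function(a) {
  v <- .unitVec()
  p <- v - sum(v * a) * a
  n <- sqrt(sum(p^2))
  if (n < 1e-8) return(.perpTo(a))
  p / n
}

## Idealized local segment coordinates relative to its first residue:
## alpha-helix (1.5 A rise, 100 deg twist, 2.3 A radius) or extended
## strand (3.3 A rise, 0.9 A zigzag); both give ~3.8 A consecutive
## C-alpha spacing.
.segmentCoords <- function(kind, len, axis, perp) {
  perp2 <- pracmaCross(axis, perp)
  t <- seq_len(len) - 1
  if (kind == "helix") {
    ang <- t * 100 * pi / 180
    p <- outer(t * 1.5, axis) + 2.3 * (outer(cos(ang), perp) +
                                       outer(sin(ang), perp2))
  } else {
    p <- outer(t * 3.3, axis) + outer(0.9 * (-1)^t, perp)
  }
  sweep(p, 2, p[1, ])  # first residue of the segment at the origin
}

## minimal cross product (avoids an extra dependency)
pracmaCross <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

.minDistToPrev <- function(pos, coords, exclude) {
  if (nrow(coords) <= exclude) return(Inf)
  prev <- coords[seq_len(nrow(coords) - exclude), , drop = FALSE]
  sqrt(min(rowSums(sweep(prev, 2, pos)^2)))
}

#' Generate one synthetic validated chain
#'
#' Residues are placed along a self-avoiding C-alpha walk with ~3.8
#' Angstrom steps: idealized helical and extended segments with
#' random orientations, and centroid-attracted random coil/turn steps
#' (3.0 Angstrom C-alpha exclusion, bounded retries). Residue types
#' are drawn from the composition (hydrophobically enriched inside
#' helix/strand segments), functional atoms are pseudo-atoms at fixed
#' per-type offsets from the C-alpha (two for the two-atom types),
#' and solvent accessibility follows the buried/exposed mixture.
#' Deterministic given \code{chainSeed}.
#'
#' @param params a \code{"CorpusParams"}.
#' @param chainSeed integer seed for this chain.
#' @param structureId 4-character identifier.
#' @param chainId chain identifier.
#' @param length optional explicit chain length; drawn from
#'   \code{params$lengthRange} when NULL.
#' @return A \linkS4class{ValidatedChain}.
#' @export
generateChain <- function(params, chainSeed, structureId = "S001",
                          chainId = "A", length = NULL) {
  ## a dense fold occasionally leaves no room for a rigid segment;
  ## retry the whole chain from derived sub-seeds before giving up
  attempts <- .spawnSeeds(chainSeed, 20L)
  for (a in seq_along(attempts)) {
    ch <- tryCatch(
      .generateChainOnce(params, attempts[a], structureId, chainId,
                         length),
      error = function(e) e)
    if (!inherits(ch, "error")) return(ch)
  }
  stop("generateChain: could not build a clash-free chain after ",
       length(attempts), " attempts (seed ", chainSeed, "): ",
       conditionMessage(ch))
}

.generateChainOnce <- function(params, chainSeed, structureId = "S001",
                               chainId = "A", length = NULL) {
  stopifnot(inherits(params, "CorpusParams"))
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(chainSeed))
  n <- if (is.null(length))
    sample(seq(params$lengthRange[1], params$lengthRange[2]), 1L)
  else as.integer(length)

  ## secondary-structure segmentation
  ss <- character(0)
  segOf <- integer(0)
  seg <- 0L
  while (length(ss) < n) {
    seg <- seg + 1L
    cat_ <- sample(.SS_CATEGORIES, 1L, prob = params$segProb)
    len <- 1L + stats::rpois(1L, max(params$segMeanLen[[cat_]] - 1, 0))
    ss <- c(ss, rep(cat_, len))
    segOf <- c(segOf, rep(seg, len))
  }
  ss <- ss[seq_len(n)]
  segOf <- segOf[seq_len(n)]

  ## residue types: composition, hydrophobically boosted in helix/strand
  comp <- params$composition
  boosted <- comp
  boosted[.HYDROPHOBIC] <- boosted[.HYDROPHOBIC] * params$hydroBoost
  boosted <- boosted / sum(boosted)
  aa <- character(n)
  for (s in unique(segOf)) {
    idx <- which(segOf == s)
    p <- if (ss[idx[1]] %in% c("helix", "strand")) boosted else comp
    aa[idx] <- sample(.AA3, length(idx), replace = TRUE, prob = p)
  }

  ## C-alpha walk
  coords <- matrix(NA_real_, n, 3)
  coords[1, ] <- c(0, 0, 0)
  i <- 2L
  dir <- .unitVec()
  while (i <= n) {
    segIdx <- which(segOf == segOf[i] & seq_len(n) >= i)
    kind <- ss[i]
    placed <- FALSE
    centroid <- colMeans(coords[seq_len(i - 1L), , drop = FALSE])
    outward <- coords[i - 1L, ] - centroid
    oN <- sqrt(sum(outward^2))
    outward <- if (oN > 1e-8) outward / oN else .unitVec()
    rigid <- kind %in% c("helix", "strand") && length(segIdx) > 1L
    if (rigid) {
      for (try in seq_len(160L)) {
        ## after enough blind tries, escape outward where room is
        ## guaranteed
        bias <- if (try > 80L) outward else c(0, 0, 0)
        axis <- bias + .unitVec()
        axis <- axis / sqrt(sum(axis^2))
        perp <- .perpTo(axis)
        local <- .segmentCoords(kind, length(segIdx), axis, perp)
        d0 <- bias + .unitVec()
        start <- coords[i - 1L, ] + 3.8 * d0 / sqrt(sum(d0^2))
        cand <- sweep(local, 2, start, "+")
        ok <- TRUE
        tmp <- coords[seq_len(i - 1L), , drop = FALSE]
        for (j in seq_len(nrow(cand))) {
          if (.minDistToPrev(cand[j, ], rbind(tmp, cand[seq_len(j - 1L), ,
                                                        drop = FALSE]),
                             exclude = 1L) < 3.0) { ok <- FALSE; break }
        }
        if (ok) {
          coords[segIdx, ] <- cand
          dir <- axis
          i <- segIdx[length(segIdx)] + 1L
          placed <- TRUE
          break
        }
      }
    }
    if (!placed) {
      ## coil/turn step, also the flexible fallback when no rigid
      ## segment orientation fits: advance one residue and retry the
      ## remaining segment from there
      for (try in seq_len(120L)) {
        toC <- -outward
        d <- if (try > 60L) outward + 0.5 * .unitVec()
             else 0.5 * dir + .unitVec() + 0.3 * toC
        d <- d / sqrt(sum(d^2))
        cand <- coords[i - 1L, ] + 3.8 * d
        if (.minDistToPrev(cand, coords[seq_len(i - 1L), , drop = FALSE],
                           exclude = 1L) >= 3.0) {
          coords[i, ] <- cand
          dir <- d
          i <- i + 1L
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("generateChain: self-avoiding walk stuck ",
                        "(chain seed ", chainSeed, ")")
    }
  }

  ## functional pseudo-atoms
  fat <- functionalAtomTable()
  f1 <- matrix(NA_real_, n, 3)
  f2 <- matrix(NA_real_, n, 3)
  for (k in seq_len(n)) {
    mag <- .FUNC_OFFSET[[aa[k]]]
    if (mag == 0) { f1[k, ] <- coords[k, ]; next }
    d1 <- .unitVec()
    f1[k, ] <- coords[k, ] + mag * d1
    if (length(fat[[aa[k]]]) > 1L) {
      p <- .perpTo(d1)
      d2 <- d1 + 0.8 * p
      d2 <- d2 / sqrt(sum(d2^2))
      f2[k, ] <- coords[k, ] + mag * d2
    }
  }

  ## solvent accessibility: buried/exposed mixture
  pBuried <- ifelse(aa %in% .HYDROPHOBIC, params$buriedProbHydro,
                    params$buriedProbOther)
  u <- stats::runif(n)
  sa <- numeric(n)
  zero <- u < params$zeroSAProb
  buried <- !zero & u < params$zeroSAProb + pBuried
  sa[zero] <- 0
  sa[buried] <- stats::runif(sum(buried), 0, 10)
  sa[!zero & !buried] <- stats::runif(sum(!zero & !buried), 10,
                                      params$exposedMaxSA)

  resdf <- data.frame(aa = aa, seqIndex = seq_len(n),
                      authNum = seq_len(n), insCode = "_",
                      caX = coords[, 1], caY = coords[, 2],
                      caZ = coords[, 3],
                      f1X = f1[, 1], f1Y = f1[, 2], f1Z = f1[, 3],
                      f2X = f2[, 1], f2Y = f2[, 2], f2Z = f2[, 3],
                      ss = ss, sa = sa, stringsAsFactors = FALSE)
  new("ValidatedChain", structureId = structureId, chainId = chainId,
      residues = resdf)
}

#' Generate a synthetic corpus (optionally written to disk)
#'
#' Vectorized [generateChain()]: per-chain sub-seeds are spawned from
#' the master seed, so the corpus is reproducible as a whole. With
#' \code{dir} set, each chain is written as a PDB coordinate file plus
#' an annotation TSV, and a tab-separated manifest
#' (\code{manifest.tsv}: structure_id, chain_id, pdb, annotation,
#' length) is created; the files are re-ingestable through
#' [readStructure()], [readAnnotations()] and [mergeAndValidate()].
#'
#' @param params a \code{"CorpusParams"}.
#' @param dir optional output directory.
#' @return List of \linkS4class{ValidatedChain}; when writing, the
#'   manifest path is attached as attribute \code{"manifest"}.
#' @export
generateCorpus <- function(params, dir = NULL) {
  stopifnot(inherits(params, "CorpusParams"))
  n <- params$nChains
  seeds <- if (n > 0L) .spawnSeeds(params$seed, n) else integer()
  chains <- vector("list", n)
  for (k in seq_len(n))
    chains[[k]] <- generateChain(params, chainSeed = seeds[k],
                                 structureId = sprintf("S%03d", k),
                                 chainId = "A")
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    man <- data.frame(structure_id = character(), chain_id = character(),
                      pdb = character(), annotation = character(),
                      length = integer(), stringsAsFactors = FALSE)
    for (k in seq_len(n)) {
      ch <- chains[[k]]
      pdb <- file.path(dir, paste0(ch@structureId, ".pdb"))
      ann <- file.path(dir, paste0(ch@structureId, ".tsv"))
      writeChainPDB(ch, pdb)
      writeAnnotationTSV(ch, ann)
      man[k, ] <- list(ch@structureId, ch@chainId, basename(pdb),
                       basename(ann), chainLength(ch))
    }
    manPath <- file.path(dir, "manifest.tsv")
    utils::write.table(man, manPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    attr(chains, "manifest") <- manPath
  }
  chains
}

#' Generate a sparse tensor with a known power-law rank profile
#'
#' Draws \code{nCells} cell populations i.i.d. from the discrete
#' distribution P(R) proportional to R^-lambda on 1..\code{rMax} and
#' scatters them over distinct random 8-D cell indices. The
#' rank-frequency table of the result follows the target power law up
#' to sampling noise, making it the ground-truth input for
#' exponent-recovery checks of [fitPowerLaw()].
#'
#' @param lambda power-law exponent (> 1).
#' @param nCells number of non-zero cells (>= 100).
#' @param rMax largest population drawn.
#' @param seed integer seed.
#' @param scheme a \linkS4class{BinScheme}.
#' @return A \linkS4class{PairTensor} (canonical mode).
#' @export
generatePowerlawTensor <- function(lambda, nCells, rMax = 1000L,
                                   seed = 1L,
                                   scheme = defaultBinScheme()) {
  stopifnot(lambda > 1, nCells >= 100L)
  space <- tensorSize(scheme)
  if (nCells > space)
    stop("nCells exceeds the tensor index space (", space, ")")
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))
  r <- seq_len(rMax)
  pops <- sample(r, nCells, replace = TRUE, prob = r^(-lambda))
  lin <- sample.int(space, nCells)   # distinct indices
  bc <- binCounts(scheme)
  idx <- arrayInd(lin, .dim = unname(bc))
  cells <- as.data.frame(idx)
  names(cells) <- .DIM_NAMES
  cells$count <- as.numeric(pops)
  cells <- cells[do.call(order, cells[.DIM_NAMES]), , drop = FALSE]
  .newPairTensor(cells, scheme, mode = "canonical", nObs = sum(pops),
                 meta = list(generator = "powerlaw", lambda = lambda,
                             rMax = rMax, seed = as.integer(seed)))
}
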