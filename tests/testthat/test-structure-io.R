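pdbLine <- function(serial, name, resid, chain, resno, x, y, z,
                    record = "ATOM  ", alt = " ") {
  nm <- if (nchar(name) < 4) sprintf(" %-3s", name) else name
  sprintf("%s%5d %s%s%3s %s%4d    %8.3f%8.3f%8.3f  1.00  0.00          %2s",
          record, serial, nm, alt, resid, chain, resno, x, y, z,
          substr(name, 1, 1))
}

test_that("a minimal one-residue file parses to one chain, one residue, one atom", {
  txt <- paste(pdbLine(1, "CA", "GLY", "A", 1, 1, 2, 3), "END", sep = "\n")
  st <- readStructure(txt, structureId = "1TST")
  expect_s3_class(st, "RawStructure")
  expect_identical(st$structureId, "1TST")
  expect_identical(nrow(st$atoms), 1L)
  expect_identical(st$atoms$chain, "A")
  expect_equal(unlist(st$atoms[1, c("x", "y", "z")]), c(x = 1, y = 2, z = 3))
})

test_that("chains are preserved in file order; HETATM and altlocs are resolved", {
  txt <- paste(
    pdbLine(1, "CA", "GLY", "B", 1, 0, 0, 0),
    pdbLine(2, "CA", "ALA", "B", 2, 3.8, 0, 0),
    pdbLine(3, "CB", "ALA", "B", 2, 4.8, 1, 0),
    pdbLine(4, "CA", "GLY", "A", 1, 20, 0, 0),
    pdbLine(5, "O", "HOH", "A", 90, 9, 9, 9, record = "HETATM"),
    pdbLine(6, "CA", "LEU", "A", 2, 23.8, 0, 0, alt = "A"),
    pdbLine(7, "CA", "LEU", "A", 2, 23.9, 0, 0, alt = "B"),
    "END", sep = "\n")
  st <- readStructure(txt, structureId = "2TST")
  expect_identical(unique(st$atoms$chain), c("B", "A"))
  expect_false(any(st$atoms$resid == "HOH"))
  leu <- st$atoms[st$atoms$resid == "LEU", ]
  expect_identical(nrow(leu), 1L)       # first conformer kept
  expect_equal(leu$x, 23.8)
})

test_that("unparseable and empty coordinate input raise hard errors naming the problem", {
  bad <- paste(pdbLine(1, "CA", "GLY", "A", 1, 1, 2, 3),
               "ATOM      2  CA  GLY A   2      xxxxxxx   0.000   0.000",
               sep = "\n")
  expect_error(readStructure(bad), "line 2")
  expect_error(readStructure("\n\n"), "empty")
  expect_error(readStructure("REMARK nothing here\nEND\n"), "no ATOM")
  expect_error(readStructure(tempfile()), "no such file")
})

test_that("TSV annotation rows map fields directly and malformed rows are counted", {
  txt <- paste(
    "structure_id\tchain_id\tseq_number\tinsertion_code\taa_1letter\tss_code\tsa_percent",
    "1ABC\tA\t102\t_\tL\tH\t3.5",
    "1ABC\tA\t103\t_\tV\tE",              # missing sa column -> dropped
    "1ABC\tA\t104\t_\tG\tC\t55.0",
    sep = "\n")
  expect_warning(ann <- readAnnotations(txt, dialect = "tsv"), "malformed")
  expect_identical(nrow(ann), 2L)
  expect_identical(attr(ann, "dropped"), 1L)
  expect_identical(ann$aa[1], "LEU")
  expect_identical(ann$ssRaw[1], "H")
  expect_equal(ann$sa[1], 3.5)
  expect_identical(ann$authNum[1], 102L)
  expect_error(suppressWarnings(readAnnotations("h\nbad row", dialect = "tsv")),
               "no usable")
})

test_that("HSSP-dialect residue lines parse chain, number, type, SS and accessibility", {
  hline <- function(no, pdbno, ch, aa, ss, acc)
    sprintf("%5d%5d %s %s  %s%17s%4d", no, pdbno, ch, aa, ss, "", acc)
  txt <- c("HSSP  HOMOLOGY DERIVED SECONDARY STRUCTURE",
           "PDBID 1ABC",
           "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC",
           hline(1, 11, "A", "L", "H", 7),
           hline(2, 12, "A", "V", "E", 43),
           "    3   !     chain break")
  expect_warning(ann <- readAnnotations(paste(txt, collapse = "\n"),
                                        dialect = "hssp"),
                 "dropped")
  expect_identical(nrow(ann), 2L)
  expect_identical(ann$structureId[1], "1ABC")
  expect_identical(ann$aa, c("LEU", "VAL"))
  expect_identical(ann$ssRaw, c("H", "E"))
  expect_equal(ann$sa, c(7, 43))
  expect_identical(ann$authNum, c(11L, 12L))
})

test_that("validation discards incomplete residues and keeps the rest of the chain", {
  txt <- paste(
    pdbLine(1, "CA", "GLY", "A", 1, 0, 0, 0),
    pdbLine(2, "CA", "ALA", "A", 2, 3.8, 0, 0),   # ALA without CB
    pdbLine(3, "CA", "LEU", "A", 3, 7.6, 0, 0),
    pdbLine(4, "CG", "LEU", "A", 3, 8.6, 1, 0),
    pdbLine(5, "CA", "VAL", "A", 4, 11.4, 0, 0),  # not annotated
    pdbLine(6, "CG1", "VAL", "A", 4, 12, 1, 0),
    pdbLine(7, "CG2", "VAL", "A", 4, 12, -1, 0),
    "END", sep = "\n")
  ann <- readAnnotations(paste(
    "structure_id\tchain_id\tseq_number\tinsertion_code\taa_1letter\tss_code\tsa_percent",
    "1TST\tA\t1\t_\tG\tC\t20",
    "1TST\tA\t2\t_\tA\tH\t5",
    "1TST\tA\t3\t_\tL\tH\t5",
    sep = "\n"), dialect = "tsv")
  st <- readStructure(txt, structureId = "1TST")
  chains <- mergeAndValidate(st, ann)
  expect_length(chains, 1)
  ch <- chains[[1]]
  expect_identical(chainLength(ch), 2L)
  expect_identical(residues(ch)$aa, c("GLY", "LEU"))
  expect_identical(residues(ch)$seqIndex, 1:2)  # ordinal after discard
  d <- attr(chains, "discards")
  expect_identical(unname(d["missing_functional"]), 1L)
  expect_identical(unname(d["no_annotation"]), 1L)
  # conservation: input residues = validated + discarded
  nInput <- length(unique(paste(st$atoms$chain, st$atoms$resno)))
  expect_identical(nInput, chainLength(ch) + sum(d))
})

test_that("annotation residue type wins over the coordinate file on conflict", {
  txt <- paste(pdbLine(1, "CA", "GLY", "A", 1, 0, 0, 0), "END", sep = "\n")
  ann <- readAnnotations(paste(
    "structure_id\tchain_id\tseq_number\tinsertion_code\taa_1letter\tss_code\tsa_percent",
    "1TST\tA\t1\t_\tG\tH\t5",
    "1TST\tB\t9\t_\tL\tH\t5",
    sep = "\n"), dialect = "tsv")
  st <- readStructure(txt, structureId = "1TST")
  chains <- mergeAndValidate(st, ann)
  expect_identical(residues(chains[[1]])$aa, "GLY")
  expect_identical(residues(chains[[1]])$ss, "helix")
})

test_that("synthetic chains round-trip through PDB + TSV within fixed-width precision", {
  p <- corpusParams(nChains = 1, seed = 303)
  ch <- generateChain(p, 9090, length = 50)
  d <- withr::local_tempdir()
  writeChainPDB(ch, file.path(d, "S001.pdb"))
  writeAnnotationTSV(ch, file.path(d, "S001.tsv"))
  st <- readStructure(file.path(d, "S001.pdb"), structureId = "S001")
  ann <- readAnnotations(file.path(d, "S001.tsv"), dialect = "tsv")
  back <- mergeAndValidate(st, ann)
  expect_length(back, 1)
  expect_identical(sum(attr(back, "discards")), 0L)
  r0 <- residues(ch); r1 <- residues(back[[1]])
  expect_identical(r0$aa, r1$aa)
  expect_identical(r0$ss, r1$ss)
  expect_equal(r1$sa, r0$sa, tolerance = 1e-4)
  for (col in c("caX", "caY", "caZ", "f1X", "f1Y", "f1Z", "f2X"))
    expect_equal(r1[[col]], r0[[col]], tolerance = 1e-3,
                 info = col)
  # idempotence: re-validating the round-tripped chain changes nothing
  writeChainPDB(back[[1]], file.path(d, "again.pdb"))
  writeAnnotationTSV(back[[1]], file.path(d, "again.tsv"))
  again <- mergeAndValidate(
    readStructure(file.path(d, "again.pdb"), structureId = "S001"),
    readAnnotations(file.path(d, "again.tsv"), dialect = "tsv"))
  expect_equal(residues(again[[1]]), residues(back[[1]]), tolerance = 1e-9)
})

test_that("the default secondary-structure map sends H/E/T to their categories, the rest to coil", {
  m <- defaultSSMap()
  expect_identical(unname(m[c("H", "E", "T")]), c("helix", "strand", "turn"))
  expect_true(all(m[c("G", "I", "B", "S", "C")] == "coil"))
  expect_identical(PairSpace:::.mapSS(c("H", "E", "T", "Z", " "), m),
                   c("helix", "strand", "turn", "coil", "coil"))
})
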