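#' @include AllClasses.R utils.R binScheme.R
NULL

## ---- coordinate files ---------------------------------------------

#' Read a PDB-format coordinate file
#'
#' Parses ATOM records of a PDB-format file (or literal text) into a
#' raw structure: per-chain, per-residue atom coordinates in file
#' order. HETATM records and non-standard residues are excluded,
#' alternate locations are resolved to the first conformer, and only
#' the first model of multi-model files is kept. Parsing is delegated
#' to \code{bio3d::read.pdb}.
#'
#' @param src path to a PDB file, or a character scalar containing
#'   PDB-format text (detected by embedded newlines).
#' @param structureId optional 4-character identifier; defaults to the
#'   HEADER record's ID code, else the file basename.
#' @return A list of class \code{"RawStructure"} with elements
#'   \code{structureId} and \code{atoms} (data.frame: \code{chain,
#'   resno, insCode, resid, elety, x, y, z} in file order).
#' @export
#' @examples
#' txt <- paste(
#'  "ATOM      1  CA  GLY A   1       0.000   0.000   0.000  1.00  0.00           C",
#'  "END", sep = "\n")
#' readStructure(txt, structureId = "1TST")
readStructure <- function(src, structureId = NULL) {
  isText <- length(src) > 1L || grepl("\n", src, fixed = TRUE)
  if (isText) {
    path <- tempfile(fileext = ".pdb")
    on.exit(unlink(path))
    writeLines(if (length(src) > 1L) src else strsplit(src, "\n")[[1]], path)
  } else {
    if (!file.exists(src)) stop("no such file: ", src)
    path <- src
  }
  lines <- readLines(path, warn = FALSE)
  if (!length(lines) || !any(nzchar(lines)))
    stop("empty coordinate file: ", if (isText) "<text>" else src)
  atomLines <- which(startsWith(lines, "ATOM"))
  if (!length(atomLines))
    stop("no ATOM records in ", if (isText) "<text>" else src)
  ## pre-validate coordinate fields so a hard error can name the line
  for (i in atomLines) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (anyNA(xyz) || any(!is.finite(xyz)))
      stop("unparseable ATOM coordinates at line ", i, ": ", lines[i])
  }
  if (is.null(structureId)) {
    hdr <- lines[startsWith(lines, "HEADER")]
    if (length(hdr) && nchar(hdr[1]) >= 66)
      structureId <- trimws(substr(hdr[1], 63, 66))
    if (is.null(structureId) || !nzchar(structureId))
      structureId <- toupper(substr(sub("\\.(pdb|ent)$", "",
                                        basename(if (isText) "XXXX" else src)), 1, 4))
  }
  pdb <- bio3d::read.pdb(path, multi = FALSE, verbose = FALSE)
  at <- pdb$atom
  at <- at[at$type == "ATOM" & at$resid %in% .AA3, , drop = FALSE]
  if (!nrow(at))
    stop("no standard-residue ATOM records in ",
         if (isText) "<text>" else src)
  ## first conformer only: keep the first occurrence of each atom key
  key <- paste(at$chain, at$resno,
               ifelse(is.na(at$insert), "", at$insert), at$elety)
  at <- at[!duplicated(key), , drop = FALSE]
  atoms <- data.frame(chain   = at$chain,
                      resno   = as.integer(at$resno),
                      insCode = ifelse(is.na(at$insert), "_", at$insert),
                      resid   = at$resid,
                      elety   = at$elety,
                      x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  structure(list(structureId = structureId, atoms = atoms),
            class = "RawStructure")
}

#' @export
print.RawStructure <- function(x, ...) {
  cat(sprintf("RawStructure %s: %d atoms, %d chain(s) [%s]\n",
              x$structureId, nrow(x$atoms),
              length(unique(x$atoms$chain)),
              paste(unique(x$atoms$chain), collapse = ",")))
  invisible(x)
}

## ---- annotations ---------------------------------------------------

#' Read per-residue annotations
#'
#' Loads residue type, raw secondary-structure code and relative
#' solvent accessibility (percent, may exceed 100) keyed by
#' (structure, chain, author residue number, insertion code).
#' Malformed rows are dropped with a warning and counted, never fatal;
#' duplicate keys keep the first row.
#'
#' Two dialects are supported:
#' \describe{
#'   \item{\code{"tsv"}}{tab-separated, one header line, columns
#'     \code{structure_id, chain_id, seq_number, insertion_code}
#'     (\code{"_"} if none)\code{, aa_1letter, ss_code, sa_percent}.}
#'   \item{\code{"hssp"}}{DSSP-style fixed-column residue lines
#'     following the \code{"  #  RESIDUE"} header: author number in
#'     columns 6-10, insertion code column 11, chain column 12,
#'     one-letter residue column 14, secondary-structure code column
#'     17, accessibility in columns 35-38 (taken as the percent SA
#'     value).}
#' }
#'
#' @param src path or literal text (detected by embedded newlines).
#' @param dialect \code{"tsv"} or \code{"hssp"}.
#' @param structureId identifier to assign for the \code{"hssp"}
#'   dialect (taken from a \code{PDBID} header line when present).
#' @return A data.frame of class \code{"AnnotationTable"} with columns
#'   \code{structureId, chainId, authNum, insCode, aa, ssRaw, sa}
#'   (residue type as three-letter code, \code{NA} if unknown) and
#'   attribute \code{"dropped"}, the number of discarded rows.
#' @export
readAnnotations <- function(src, dialect = c("tsv", "hssp"),
                            structureId = NULL) {
  dialect <- match.arg(dialect)
  lines <- if (length(src) > 1L || grepl("\n", src, fixed = TRUE)) {
    if (length(src) > 1L) src else strsplit(src, "\n")[[1]]
  } else {
    if (!file.exists(src)) stop("no such file: ", src)
    readLines(src, warn = FALSE)
  }
  if (dialect == "tsv") tab <- .parseAnnotationTSV(lines)
  else tab <- .parseAnnotationHSSP(lines, structureId)
  dup <- duplicated(tab[, c("structureId", "chainId", "authNum", "insCode")])
  if (any(dup)) {
    warning(sum(dup), " duplicate annotation key(s) dropped (first kept)")
    attr(tab, "dropped") <- attr(tab, "dropped") + sum(dup)
    tab <- tab[!dup, , drop = FALSE]
  }
  if (!nrow(tab)) stop("no usable annotation rows")
  rownames(tab) <- NULL
  class(tab) <- c("AnnotationTable", "data.frame")
  tab
}

.parseAnnotationTSV <- function(lines) {
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("annotation TSV has no data rows")
  body <- lines[-1L]
  parts <- strsplit(body, "\t", fixed = TRUE)
  ok <- vapply(parts, function(p) {
    length(p) >= 7L && nzchar(p[1]) && nzchar(p[2]) &&
      !is.na(suppressWarnings(as.integer(p[3]))) &&
      !is.na(suppressWarnings(as.numeric(p[7]))) &&
      is.finite(suppressWarnings(as.numeric(p[7])))
  }, logical(1))
  if (any(!ok))
    warning(sum(!ok), " malformed annotation row(s) dropped")
  parts <- parts[ok]
  tab <- data.frame(
    structureId = vapply(parts, `[`, "", 1L),
    chainId     = vapply(parts, `[`, "", 2L),
    authNum     = as.integer(vapply(parts, `[`, "", 3L)),
    insCode     = vapply(parts, `[`, "", 4L),
    aa          = aaTo3(vapply(parts, `[`, "", 5L)),
    ssRaw       = vapply(parts, `[`, "", 6L),
    sa          = as.numeric(vapply(parts, `[`, "", 7L)),
    stringsAsFactors = FALSE)
  attr(tab, "dropped") <- sum(!ok)
  tab
}

.parseAnnotationHSSP <- function(lines, structureId = NULL) {
  if (is.null(structureId)) {
    idl <- grep("^PDBID", lines, value = TRUE)
    structureId <- if (length(idl)) trimws(sub("^PDBID\\s+", "", idl[1]))
                   else "XXXX"
  }
  start <- grep("^\\s*#\\s+RESIDUE", lines)
  if (!length(start)) stop("no residue block ('#  RESIDUE' header) found")
  body <- lines[seq(start[1] + 1L, length(lines))]
  body <- body[nzchar(trimws(body))]
  body <- body[!startsWith(body, "##")]
  nDropped <- 0L
  rows <- lapply(body, function(l) {
    if (nchar(l) < 38) return(NULL)
    authNum <- suppressWarnings(as.integer(substr(l, 6, 10)))
    insCode <- trimws(substr(l, 11, 11))
    chain   <- trimws(substr(l, 12, 12))
    aa1     <- trimws(substr(l, 14, 14))
    ss      <- substr(l, 17, 17)
    sa      <- suppressWarnings(as.numeric(substr(l, 35, 38)))
    ## residue/chain mapping is mandatory: lines without it (HSSP
    ## chain breaks '!' etc.) are dropped and counted
    if (is.na(authNum) || !nzchar(chain) || !nzchar(aa1) || is.na(sa) ||
        !is.finite(sa))
      return(NULL)
    data.frame(structureId = structureId, chainId = chain,
               authNum = authNum,
               insCode = if (nzchar(insCode)) insCode else "_",
               aa = aaTo3(aa1), ssRaw = ss, sa = sa,
               stringsAsFactors = FALSE)
  })
  nDropped <- sum(vapply(rows, is.null, logical(1)))
  if (nDropped)
    warning(nDropped, " unusable HSSP residue line(s) dropped")
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (!length(rows)) stop("no usable annotation rows")
  tab <- do.call(rbind, rows)
  attr(tab, "dropped") <- nDropped
  tab
}

#' Default secondary-structure code mapping
#'
#' DSSP/HSSP single-letter codes to the four categories: H maps to
#' helix, E to strand, T to turn; everything else (G, I, B, S, C,
#' blank) to coil. The four categories do not uniquely partition the
#' DSSP alphabet, so the mapping is an explicit, overridable table.
#'
#' @return Named character vector mapping codes to categories; codes
#'   absent from the table fall back to \code{"coil"}.
#' @export
#' @examples
#' defaultSSMap()["H"]
defaultSSMap <- function() {
  c(H = "helix", G = "coil", I = "coil",
    E = "strand", B = "coil",
    T = "turn", S = "coil", C = "coil")
}

.mapSS <- function(code, ssMap = defaultSSMap()) {
  out <- unname(ssMap[code])
  out[is.na(out)] <- "coil"
  out
}

## ---- merge + validation -------------------------------------------

#' Merge coordinates with annotations and validate residues
#'
#' Joins a raw structure with its annotation table and applies the
#' validation rules: a residue is kept only if it has a C-alpha atom,
#' every functional atom its (annotation-assigned) type prescribes, an
#' annotation row, and a finite solvent accessibility. Residue-type
#' conflicts between the coordinate file and the annotation are
#' resolved in favour of the annotation and logged. Discarded residues
#' are counted per reason; chain length is the number of residues that
#' survive. Chains left with zero valid residues are omitted with a
#' warning.
#'
#' @param struct a \code{"RawStructure"} from [readStructure()].
#' @param annotations an \code{"AnnotationTable"} from
#'   [readAnnotations()] covering the same structure.
#' @param ssMap named character vector mapping raw secondary-structure
#'   codes to the four categories (see [defaultSSMap()]).
#' @return List of \linkS4class{ValidatedChain}, with attribute
#'   \code{"discards"}: a named integer vector of residues discarded
#'   per reason (\code{no_annotation, unknown_type, missing_ca,
#'   missing_functional}).
#' @export
mergeAndValidate <- function(struct, annotations, ssMap = defaultSSMap()) {
  stopifnot(inherits(struct, "RawStructure"),
            inherits(annotations, "AnnotationTable"))
  ann <- annotations[annotations$structureId == struct$structureId, ,
                     drop = FALSE]
  fat <- functionalAtomTable()
  discards <- c(no_annotation = 0L, unknown_type = 0L,
                missing_ca = 0L, missing_functional = 0L)
  chains <- list()
  at <- struct$atoms
  for (ch in unique(at$chain)) {
    ca <- at[at$chain == ch, , drop = FALSE]
    resKey <- paste(ca$resno, ca$insCode)
    rows <- list()
    for (k in unique(resKey)) {
      ra <- ca[resKey == k, , drop = FALSE]
      authNum <- ra$resno[1]; ins <- ra$insCode[1]
      hit <- which(ann$chainId == ch & ann$authNum == authNum &
                   ann$insCode == ins)
      if (!length(hit)) {
        discards["no_annotation"] <- discards["no_annotation"] + 1L
        next
      }
      aa <- ann$aa[hit[1]]
      if (is.na(aa)) {
        discards["unknown_type"] <- discards["unknown_type"] + 1L
        next
      }
      if (aa != ra$resid[1])
        .psLog(sprintf("%s %s %d%s: residue type %s (coordinates) vs %s (annotation); annotation wins",
                       struct$structureId, ch, authNum, ins,
                       ra$resid[1], aa))
      caIdx <- match("CA", ra$elety)
      if (is.na(caIdx)) {
        discards["missing_ca"] <- discards["missing_ca"] + 1L
        next
      }
      fnames <- fat[[aa]]
      fIdx <- match(fnames, ra$elety)
      if (anyNA(fIdx)) {
        discards["missing_functional"] <- discards["missing_functional"] + 1L
        next
      }
      f2 <- if (length(fIdx) > 1L)
        c(ra$x[fIdx[2]], ra$y[fIdx[2]], ra$z[fIdx[2]]) else rep(NA_real_, 3)
      rows[[length(rows) + 1L]] <- data.frame(
        aa = aa, seqIndex = 0L, authNum = authNum, insCode = ins,
        caX = ra$x[caIdx], caY = ra$y[caIdx], caZ = ra$z[caIdx],
        f1X = ra$x[fIdx[1]], f1Y = ra$y[fIdx[1]], f1Z = ra$z[fIdx[1]],
        f2X = f2[1], f2Y = f2[2], f2Z = f2[3],
        ss = .mapSS(ann$ssRaw[hit[1]], ssMap),
        sa = ann$sa[hit[1]],
        stringsAsFactors = FALSE)
    }
    if (!length(rows)) {
      warning("chain ", ch, " of ", struct$structureId,
              " has no valid residues; omitted")
      next
    }
    resdf <- do.call(rbind, rows)
    resdf$seqIndex <- seq_len(nrow(resdf))
    chains[[length(chains) + 1L]] <-
      new("ValidatedChain", structureId = struct$structureId,
          chainId = ch, residues = resdf)
  }
  attr(chains, "discards") <- discards
  chains
}

## ---- writers (round-trip support) ---------------------------------

#' Write a chain as a PDB-format coordinate file
#'
#' Emits one ATOM record for the C-alpha plus one per functional atom
#' of each residue (for glycine the functional atom is the C-alpha
#' itself and is written once). Fixed-width PDB format, so coordinates
#' round-trip to 1e-3 Angstrom.
#'
#' @param chain a \linkS4class{ValidatedChain}.
#' @param path output file; when \code{NULL} the lines are returned
#'   invisibly instead.
#' @return Invisibly, the character vector of file lines.
#' @export
writeChainPDB <- function(chain, path = NULL) {
  r <- residues(chain)
  fat <- functionalAtomTable()
  lines <- character()
  serial <- 0L
  fmt <- function(serial, name, resid, ch, resno, ins, x, y, z) {
    nm <- if (nchar(name) < 4L) sprintf(" %-3s", name) else name
    sprintf("ATOM  %5d %s %3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
            serial, nm, resid, ch, resno,
            ifelse(ins == "_", " ", ins), x, y, z, 1, 0,
            substr(name, 1, 1))
  }
  for (i in seq_len(nrow(r))) {
    serial <- serial + 1L
    lines <- c(lines, fmt(serial, "CA", r$aa[i], chain@chainId,
                          r$authNum[i], r$insCode[i],
                          r$caX[i], r$caY[i], r$caZ[i]))
    fnames <- fat[[r$aa[i]]]
    if (identical(fnames, "CA")) next
    lines <- c(lines, fmt(serial <- serial + 1L, fnames[1], r$aa[i],
                          chain@chainId, r$authNum[i], r$insCode[i],
                          r$f1X[i], r$f1Y[i], r$f1Z[i]))
    if (length(fnames) > 1L)
      lines <- c(lines, fmt(serial <- serial + 1L, fnames[2], r$aa[i],
                            chain@chainId, r$authNum[i], r$insCode[i],
                            r$f2X[i], r$f2Y[i], r$f2Z[i]))
  }
  lines <- c(lines, "END")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Write chains as an annotation table in the TSV dialect
#'
#' @param chains a \linkS4class{ValidatedChain} or list of them.
#' @param path output file; when \code{NULL} the lines are returned.
#' @param ssCodes named character vector mapping the four categories
#'   back to single-letter codes.
#' @return Invisibly, the character vector of file lines.
#' @export
writeAnnotationTSV <- function(chains, path = NULL,
                               ssCodes = c(helix = "H", strand = "E",
                                           turn = "T", coil = "C")) {
  if (is(chains, "ValidatedChain")) chains <- list(chains)
  header <- paste("structure_id", "chain_id", "seq_number",
                  "insertion_code", "aa_1letter", "ss_code",
                  "sa_percent", sep = "\t")
  body <- unlist(lapply(chains, function(ch) {
    r <- residues(ch)
    paste(ch@structureId, ch@chainId, r$authNum, r$insCode,
          aaTo1(r$aa), unname(ssCodes[r$ss]),
          formatC(r$sa, format = "fg", digits = 8), sep = "\t")
  }))
  lines <- c(header, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}
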