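#' @include pairs.R
NULL

## ---- sparse tensor files ------------------------------------------
## Plain-text, tab-separated, diffable. Header lines start with '#':
##   # PairSpace sparse tensor v1
##   # dims: AA1 AA2 ...
##   # shape: 20 20 ...
##   # mode: symmetric
##   # nObs: 1234
##   # total: 2468
##   # reference: 10 42        (nReps seed; reference tensors only)
## then one line per non-zero cell: indices... count.

#' Write a sparse tensor to a tab-separated text file
#'
#' @param x a \linkS4class{PairTensor} or
#'   \linkS4class{ReferenceTensor}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @seealso [readTensor()] for the exact round-trip read.
#' @export
writeTensor <- function(x, path) {
  ref <- NULL
  if (is(x, "ReferenceTensor")) {
    ref <- c(x@nReps, x@seed)
    x <- x@tensor
  }
  bc <- binCounts(x@scheme)[x@dims]
  hdr <- c("# PairSpace sparse tensor v1",
           paste("# dims:", paste(x@dims, collapse = " ")),
           paste("# shape:", paste(bc, collapse = " ")),
           paste("# mode:", x@mode),
           paste("# nObs:", format(x@nObs, digits = 17)),
           paste("# total:", format(tensorTotal(x), digits = 17)))
  if (!is.null(ref))
    hdr <- c(hdr, paste("# reference:", ref[1], ref[2]))
  body <- do.call(paste, c(unname(as.list(x@cells[x@dims])),
                           list(format(x@cells$count, digits = 17,
                                       trim = TRUE, scientific = FALSE)),
                           sep = "\t"))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a sparse tensor written by [writeTensor()]
#'
#' @param path input file.
#' @param scheme the \linkS4class{BinScheme} to attach; its bin counts
#'   must match the stored shape.
#' @return The \linkS4class{PairTensor} (or
#'   \linkS4class{ReferenceTensor} if the file carries a reference
#'   header).
#' @export
readTensor <- function(path, scheme = defaultBinScheme()) {
  lines <- readLines(path, warn = FALSE)
  hdr <- lines[startsWith(lines, "#")]
  body <- lines[!startsWith(lines, "#") & nzchar(lines)]
  field <- function(key) {
    l <- hdr[startsWith(hdr, paste0("# ", key, ":"))]
    if (!length(l)) return(NULL)
    trimws(sub(paste0("^# ", key, ":"), "", l[1]))
  }
  dims <- strsplit(field("dims"), " +")[[1]]
  shape <- as.integer(strsplit(field("shape"), " +")[[1]])
  if (!identical(unname(binCounts(scheme)[dims]), shape))
    stop("stored shape does not match the supplied bin scheme")
  mode <- field("mode")
  nObs <- as.numeric(field("nObs"))
  if (length(body)) {
    parts <- strsplit(body, "\t", fixed = TRUE)
    m <- matrix(unlist(parts), ncol = length(dims) + 1L, byrow = TRUE)
    cells <- as.data.frame(lapply(seq_along(dims),
                                  function(i) as.integer(m[, i])))
    names(cells) <- dims
    cells$count <- as.numeric(m[, length(dims) + 1L])
  } else {
    cells <- cbind(as.data.frame(setNames(rep(list(integer()),
                                              length(dims)), dims)),
                   count = numeric())
  }
  x <- .newPairTensor(cells, scheme, dims = dims, mode = mode, nObs = nObs)
  refLine <- field("reference")
  if (!is.null(refLine)) {
    rs <- as.integer(strsplit(refLine, " +")[[1]])
    return(new("ReferenceTensor", tensor = x, nReps = rs[1], seed = rs[2]))
  }
  x
}

#' Write the index/provenance file of a pair-observation set
#'
#' One line per insertion: the provenance string, a tab, then the 8
#' bin indices (tab-separated), so the local structural context behind
#' every cell count can be recovered.
#'
#' @param observations data.frame from [findPairs()] /
#'   [findPairsCorpus()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeIndexFile <- function(observations, path) {
  body <- do.call(paste, c(list(observations$provenance),
                           unname(as.list(observations[.DIM_NAMES])),
                           sep = "\t"))
  writeLines(body, path)
  invisible(path)
}

#' Write a rank-frequency table as TSV
#'
#' @param rankTable data.frame with columns \code{rank}, \code{omega}.
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRankTable <- function(rankTable, path) {
  utils::write.table(rankTable, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write an observed/expected ratio map as TSV
#'
#' Infinite ratios (observed without any reference mass) are written
#' as the literal string \code{"inf"}.
#'
#' @param ratios data.frame from [ratioMap()].
#' @param path output file.
#' @return \code{path}, invisibly.
#' @export
writeRatioMap <- function(ratios, path) {
  out <- ratios
  out$ratio <- ifelse(is.infinite(out$ratio), "inf",
                      format(out$ratio, digits = 10))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
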