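#' @include AllClasses.R
NULL

.datatable.aware <- TRUE

## stderr logging with levels; quiet unless options(PairSpace.verbose=TRUE)
## for "info", warnings always shown.
.psLog <- function(..., level = "info") {
  if (level == "info" && !isTRUE(getOption("PairSpace.verbose", FALSE)))
    return(invisible(NULL))
  message(sprintf("[%s] %s", level, paste0(...)))
}

#' Convert between one- and three-letter residue codes
#'
#' @param x character vector of residue codes.
#' @return Character vector of the converted codes; unknown codes map
#'   to \code{NA}.
#' @export
#' @examples
#' aaTo3("L")    # "LEU"
#' aaTo1("TRP")  # "W"
aaTo3 <- function(x) {
  out <- .AA3[match(toupper(x), .AA1)]
  out
}

#' @rdname aaTo3
#' @export
aaTo1 <- function(x) {
  .AA1[match(toupper(x), .AA3)]
}

## All-pairs Euclidean distances between the rows of two n x 3
## coordinate matrices; NA rows (absent second functional atom)
## propagate to NA distances.
.crossDist <- function(A, B) {
  d2 <- outer(rowSums(A^2), rowSums(B^2), "+") - 2 * tcrossprod(A, B)
  d2[d2 < 0] <- 0  # guard tiny negative round-off
  sqrt(d2)
}

## Draw n sub-seeds below 2^31 deterministically from a master seed
## without disturbing the caller's RNG more than once.
.spawnSeeds <- function(master, n) {
  stopifnot(is.finite(master))
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

## Zero-padded 4-digit residue number for provenance strings; numbers
## wider than 4 digits are emitted unpadded (format cannot hold them).
.pad4 <- function(n) {
  wide <- n > 9999L
  if (any(wide))
    warning("residue number(s) > 9999 cannot be zero-padded to 4 digits; ",
            "emitted unpadded")
  ifelse(wide, as.character(n), sprintf("%04d", n))
}
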