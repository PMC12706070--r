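#' @importFrom data.table data.table := setorder setnames rbindlist copy as.data.table setDT dcast .N .SD
#' @importFrom methods new validObject is slot show
#' @importFrom stats rpois rnorm rmultinom rgamma rlnorm runif median cor t.test setNames
#' @importFrom utils head combn packageVersion
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

DNA_ALPHABET <- c("A", "C", "G", "T")

#' Generate random DNA strings
#'
#' Uniform i.i.d. sequences over A/C/G/T, used for barcodes and UMIs.
#'
#' @param n number of strings
#' @param width string length in nucleotides
#' @return character vector of length `n`
#' @keywords internal
randomDna <- function(n, width) {
  if (n == 0L) return(character(0))
  m <- matrix(sample(DNA_ALPHABET, n * width, replace = TRUE), nrow = n)
  apply(m, 1L, paste0, collapse = "")
}

# unique random DNA strings; errors if the space is too small to satisfy n
uniqueRandomDna <- function(n, width) {
  if (n > 4^width)
    stop("cannot draw ", n, " unique sequences of width ", width)
  out <- character(0)
  while (length(out) < n) {
    out <- unique(c(out, randomDna(n - length(out) + 8L, width)))
  }
  out[seq_len(n)]
}

#' Hamming distance between equal-length strings
#' @param a,b character scalars of equal nchar
#' @return integer distance
#' @keywords internal
hammingDistance <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("hammingDistance: unequal lengths")
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

# Derive a per-stage seed from a global seed. Fixed multiplicative hash,
# kept below 2^31 so it is a valid R integer seed.
deriveSeed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  h <- sum(utf8ToInt(stage) * seq_len(nchar(stage)))
  as.integer((as.numeric(seed) * 48271 + h * 16807) %% 2147483647)
}

stopInvalid <- function(...) {
  stop(structure(class = c("combiscreen_invalid_argument", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stopInsufficient <- function(...) {
  stop(structure(class = c("combiscreen_insufficient_data", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}
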