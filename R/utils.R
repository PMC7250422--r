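#' @useDynLib intequant, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats lm coef cor.test rbinom rpois runif rmultinom quantile setNames predict
#' @importFrom utils read.delim write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of DNA strings
#'
#' Thin wrapper around [Biostrings::reverseComplement()] operating on plain
#' character vectors, which is how reads are held internally.
#'
#' @param x character vector of DNA sequences (A/C/G/T/N).
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x) {
  if (length(x) == 0L) return(character(0))
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

#' Mean base quality of quality strings
#'
#' @param qual character vector of Phred+33 quality strings.
#' @return numeric vector of mean Phred scores.
#' @export
mean_qual <- function(qual) {
  vapply(qual, function(q) {
    if (nchar(q) == 0L) return(NA_real_)
    mean(as.integer(charToRaw(q)) - 33L)
  }, numeric(1), USE.NAMES = FALSE)
}

phred_char <- function(q) {
  q <- max(0L, min(93L, as.integer(round(q))))
  rawToChar(as.raw(q + 33L))
}

## error rate -> constant Phred quality string
const_qual <- function(error_rate, len) {
  q <- if (error_rate <= 0) 40L else as.integer(round(-10 * log10(error_rate)))
  strrep(phred_char(q), len)
}

is_dna <- function(x, allow_n = FALSE) {
  pat <- if (allow_n) "^[ACGTN]*$" else "^[ACGT]*$"
  grepl(pat, x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
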