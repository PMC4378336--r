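#' @useDynLib plantmir, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats rlnorm runif setNames
#' @importFrom utils read.delim write.table
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Convert a nucleotide string to the internal RNA alphabet
#'
#' Uppercases and replaces T with U. The pipeline works in RNA space
#' throughout; DNA inputs are converted on read.
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,U,N\}.
#' @export
as_rna <- function(x) {
  chartr("acgutT", "ACGUUU", x)
}

#' Convert a nucleotide string to DNA
#'
#' Uppercases and replaces U with T (used for primer output and for
#' matching reads against DNA references).
#'
#' @param x character vector of sequences.
#' @return character vector over \{A,C,G,T,N\}.
#' @export
as_dna <- function(x) {
  chartr("acgutU", "ACGTTT", x)
}

#' Reverse complement
#'
#' @param x character vector of sequences.
#' @param alphabet `"rna"` or `"dna"`; controls whether the complement of A
#'   is written U or T.
#' @return character vector of reverse complements.
#' @export
revcomp <- function(x, alphabet = c("rna", "dna")) {
  alphabet <- match.arg(alphabet)
  x <- if (alphabet == "rna") as_rna(x) else as_dna(x)
  comp <- if (alphabet == "rna") chartr("ACGU", "UGCA", x) else chartr("ACGT", "TGCA", x)
  vapply(strsplit(comp, "", fixed = TRUE),
         function(ch) paste(rev(ch), collapse = ""), character(1))
}

# Round half away from zero (base round() is banker's rounding); report
# percentages follow the usual half-up convention.
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# Integer codes A=1 C=2 G=3 U=4, NA otherwise.
seq_to_codes <- function(x) {
  match(strsplit(x, "", fixed = TRUE)[[1]], RNA_BASES)
}

codes_to_seq <- function(codes) {
  paste(RNA_BASES[codes], collapse = "")
}

assert_rna <- function(x, what = "sequence") {
  bad <- grepl("[^ACGUN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside the RNA alphabet (A,C,G,U,N): %s",
                 what, x[bad][1]), call. = FALSE)
  }
  invisible(x)
}

# Watson-Crick complement lookup in code space (A<->U, C<->G).
WC_PARTNER <- c(4L, 3L, 2L, 1L)

is_wc <- function(a, b) WC_PARTNER[a] == b
is_gu <- function(a, b) (a == 3L & b == 4L) | (a == 4L & b == 3L)

`%||%` <- function(a, b) if (is.null(a)) b else a
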