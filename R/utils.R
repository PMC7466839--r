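#' @useDynLib plastocomp, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats cor median pnorm pt qnorm rbinom rgeom rpois runif setNames
#' @importFrom utils combn head read.delim write.table
NULL

DNA_BASES <- c("A", "C", "G", "T")

#' Reverse complement of a DNA string
#'
#' IUPAC-unaware beyond {A,C,G,T,N}: N maps to N.
#' @param x character scalar over {A,C,G,T,N}
#' @return character scalar
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

complement_seq <- function(x) chartr("ACGTN", "TGCAN", x)

reverse_seq <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

seq_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]

#' Round half-up to a fixed number of decimals
#'
#' Unlike [base::round()], ties go away from zero (0.125 -> 0.13 at 2 d.p.),
#' the convention used by the printed genome summary tables this package
#' reproduces.
#' @param x numeric
#' @param digits integer
#' @return numeric
#' @keywords internal
round_half_up <- function(x, digits = 2L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

`%||%` <- function(a, b) if (is.null(a)) b else a

assert_that <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# canonical (lexicographically smallest) rotation of a motif
canonical_rotation <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(motif)
  rots <- vapply(seq_len(k), function(i) {
    paste0(substring(motif, i, k), substring(motif, 1L, i - 1L))
  }, character(1L))
  min(rots)
}

# smallest period of a string (k such that the string is a prefix of the
# infinite repetition of its first k characters)
smallest_period <- function(x) {
  n <- nchar(x)
  ch <- seq_chars(x)
  for (k in seq_len(n)) {
    if (n %% k == 0L && all(ch == rep_len(ch[seq_len(k)], n))) return(k)
  }
  n
}
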