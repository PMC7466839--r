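#' Detect dispersed repeats (REPuter-style)
#'
#' Finds maximal pairs of matching segments of length >= `min_len` with at
#' most `max_hamming` mismatches, in four orientations: forward (segment
#' matches segment), reverse (matches the reversed segment), complement
#' (matches the complemented segment) and palindromic (matches the
#' reverse-complement, i.e. an inverted repeat pair). Detection is
#' seed-and-extend with exact seeds of length
#' `floor(min_len / (max_hamming + 1))`; by the pigeonhole principle no
#' qualifying pair is missed. Self-overlapping pairs are excluded. A pair
#' that happens to qualify in more than one orientation is reported once,
#' with priority forward > palindromic > reverse > complement.
#'
#' @param seq DNA string
#' @param min_len minimum repeat length in bp (default 21)
#' @param max_hamming maximum Hamming distance (default 2)
#' @return data.frame: kind, len, pos1, pos2 (1-based starts, pos1 < pos2 or
#'   equal-start forbidden), mismatches
#' @export
find_dispersed_repeats <- function(seq, min_len = 21L, max_hamming = 2L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  seed <- max(2L, min_len %/% (max_hamming + 1L))
  empty <- data.frame(kind = character(), len = integer(), pos1 = integer(),
                      pos2 = integer(), mismatches = integer())
  if (n < min_len) return(empty)
  scans <- list(
    forward = list(t = seq, self = TRUE,
                   map = function(j, len) j),
    palindromic = list(t = revcomp(seq), self = FALSE,
                       map = function(j, len) n - (j + len - 1L) + 1L),
    reverse = list(t = reverse_seq(seq), self = FALSE,
                   map = function(j, len) n - (j + len - 1L) + 1L),
    complement = list(t = complement_seq(seq), self = FALSE,
                      map = function(j, len) j))
  out <- list()
  for (kind in names(scans)) {
    sc <- scans[[kind]]
    h <- cpp_pair_scan(seq, sc$t, as.integer(min_len),
                       as.integer(max_hamming), as.integer(seed), sc$self)
    if (nrow(h) == 0L) next
    p1 <- h$start_a
    p2 <- sc$map(h$start_b, h$len)
    lo <- pmin(p1, p2); hi <- pmax(p1, p2)
    keep <- lo + h$len - 1L < hi  # disjoint, and forbids pos1 == pos2
    if (!any(keep)) next
    df <- data.frame(kind = kind, len = h$len[keep], pos1 = lo[keep],
                     pos2 = hi[keep], mismatches = h$mm[keep])
    out[[kind]] <- unique(df)
  }
  if (length(out) == 0L) return(empty)
  res <- do.call(rbind, out)
  # orientation priority dedupe on identical (pos1, pos2, len)
  prio <- match(res$kind, c("forward", "palindromic", "reverse", "complement"))
  res <- res[order(res$pos1, res$pos2, res$len, prio), , drop = FALSE]
  res <- res[!duplicated(res[, c("pos1", "pos2", "len")]), , drop = FALSE]
  res <- res[order(res$pos1, res$pos2), , drop = FALSE]
  rownames(res) <- NULL
  res
}
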