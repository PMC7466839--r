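#' Detect simple sequence repeats (microsatellites)
#'
#' MISA-style SSR search: maximal perfect runs of a 1-6 bp motif, with
#' class-specific minimum copy numbers (default 10 for mononucleotides, 6 for
#' dinucleotides, 5 for tri- to hexanucleotides). A run whose motif is itself
#' periodic is reported only at the smallest motif length. N breaks runs.
#' Simple SSRs closer than `join_dist` bp (spacer length; MISA's composite
#' rule, default 100) are merged into one composite hit that retains its
#' member SSRs; a negative `join_dist` disables composite merging and
#' reports all simple runs, which may then overlap. Motifs of length >= 2 are canonicalized to the
#' lexicographically smallest rotation; mononucleotide motifs are reported as
#' the literal base.
#'
#' @param seq DNA string over {A,C,G,T,N}
#' @param minima named integer vector: minimum copies per motif length 1-6
#' @param join_dist composite-join distance in bp
#' @return data.frame: motif, start, end, copies, ssr_class (p1..p6 or
#'   composite), components (";"-separated member descriptors for composites)
#' @export
find_ssrs <- function(seq,
                      minima = c(`1` = 10L, `2` = 6L, `3` = 5L, `4` = 5L,
                                 `5` = 5L, `6` = 5L),
                      join_dist = 100L) {
  seq <- toupper(seq)
  n <- nchar(seq)
  ch <- seq_chars(seq)
  hits <- list()
  for (k in 1:6) {
    if (n < 2L * k) next
    m <- ch[seq_len(n - k)] == ch[(k + 1L):n] & ch[seq_len(n - k)] != "N"
    r <- rle(m)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    runs <- which(r$values & r$lengths >= k) # >= 2 full copies
    for (q in runs) {
      a <- starts[q]
      total <- r$lengths[q] + k            # perfect run length in bp
      copies <- total %/% k
      if (copies < minima[[as.character(k)]]) next
      motif <- substring(seq, a, a + k - 1L)
      if (smallest_period(motif) < k) next # reported at the smaller length
      hits[[length(hits) + 1L]] <- data.frame(
        motif = if (k == 1L) motif else canonical_rotation(motif),
        start = a, end = a + copies * k - 1L, copies = copies,
        ssr_class = paste0("p", k), components = NA_character_)
    }
  }
  if (length(hits) == 0L) {
    return(data.frame(motif = character(), start = integer(), end = integer(),
                      copies = numeric(), ssr_class = character(),
                      components = character()))
  }
  out <- do.call(rbind, hits)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  if (join_dist < 0L) return(out)
  merge_composites(out, join_dist)
}

# merge simple SSRs whose spacer is <= join_dist into composite hits
merge_composites <- function(out, join_dist) {
  if (nrow(out) < 2L) { rownames(out) <- NULL; return(out) }
  grp <- cumsum(c(1L, as.integer(out$start[-1L] - out$end[-nrow(out)] - 1L >
                                   join_dist)))
  rows <- lapply(split(seq_len(nrow(out)), grp), function(idx) {
    if (length(idx) == 1L) return(out[idx, , drop = FALSE])
    comp <- out[idx, , drop = FALSE]
    # trim overlapping members so that components stay disjoint
    for (i in seq_len(nrow(comp) - 1L)) {
      if (comp$start[i + 1L] <= comp$end[i]) {
        k <- nchar(comp$motif[i + 1L])
        shift <- comp$end[i] + 1L - comp$start[i + 1L]
        shift <- k * ceiling(shift / k) # keep whole copies
        comp$start[i + 1L] <- comp$start[i + 1L] + shift
        comp$copies[i + 1L] <- (comp$end[i + 1L] - comp$start[i + 1L] + 1L) %/% k
      }
    }
    comp <- comp[comp$copies >= 1L, , drop = FALSE]
    if (nrow(comp) == 1L) return(comp)
    data.frame(motif = paste(comp$motif, collapse = "+"),
               start = min(comp$start), end = max(comp$end),
               copies = NA_real_, ssr_class = "composite",
               components = paste(sprintf("%s:%d-%d", comp$motif, comp$start,
                                          comp$end), collapse = ";"))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}
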