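#' Collinear pairwise alignment of two plastomes
#'
#' Anchored global alignment for collinear (rearrangement-free) genome pairs:
#' shared k-mers that are unique in both sequences are chained by a
#' highest-weight strictly increasing chain; the segments between anchors are
#' aligned globally with affine gaps (match +1, mismatch -2, gap open -5, gap
#' extend -2), recursing with segment-local anchors when a segment is larger
#' than `max_gap_span` (this is how the duplicated IR, whose k-mers are not
#' genome-unique, gets anchored). An anchor chain that would imply an
#' inversion or transposition raises a "non-collinear" error.
#'
#' @param ref,qry [plastome()] objects or plain DNA strings
#' @param k anchor k-mer size
#' @param max_gap_span largest inter-anchor segment aligned by dynamic
#'   programming before recursive re-anchoring is attempted
#' @return a `pairwise_alignment`: ref_id, qry_id, ref_aln, qry_aln (equal
#'   length, gaps as "-", no gap-in-both column), n_anchors
#' @export
align_collinear <- function(ref, qry, k = 21L, max_gap_span = 5000L) {
  ref_id <- if (inherits(ref, "plastome")) ref$id else "ref"
  qry_id <- if (inherits(qry, "plastome")) qry$id else "qry"
  rs <- if (inherits(ref, "plastome")) ref$sequence else toupper(ref)
  qs <- if (inherits(qry, "plastome")) qry$sequence else toupper(qry)
  assert_that(nchar(rs) > 0L && nchar(qs) > 0L, "both sequences must be non-empty")
  chunks <- align_rec(rs, qs, k, max_gap_span, depth = 0L)
  ra <- paste(chunks$ref, collapse = "")
  qa <- paste(chunks$qry, collapse = "")
  if (gsub("-", "", ra, fixed = TRUE) != rs ||
      gsub("-", "", qa, fixed = TRUE) != qs) {
    stop("internal error: alignment does not round-trip its inputs")
  }
  structure(list(ref_id = ref_id, qry_id = qry_id, ref_aln = ra, qry_aln = qa,
                 n_anchors = chunks$n_anchors),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat(sprintf("<pairwise_alignment> %s vs %s: %d columns, %d anchors\n",
              x$ref_id, x$qry_id, nchar(x$ref_aln), x$n_anchors))
  invisible(x)
}

# recursive anchored alignment; returns list(ref=, qry= chunk vectors)
align_rec <- function(rs, qs, k, max_gap_span, depth) {
  nr <- nchar(rs); nq <- nchar(qs)
  if (rs == qs) return(list(ref = rs, qry = qs, n_anchors = 0L))
  if (nr == 0L) return(list(ref = strrep("-", nq), qry = qs, n_anchors = 0L))
  if (nq == 0L) return(list(ref = rs, qry = strrep("-", nr), n_anchors = 0L))
  if (max(nr, nq) <= max_gap_span || depth > 12L) {
    if (max(nr, nq) > 4L * max_gap_span) {
      stop("non-collinear: unanchorable segment of ", max(nr, nq), " bp",
           call. = FALSE)
    }
    return(c(dp_align(rs, qs), list(n_anchors = 0L)))
  }
  blocks <- anchor_blocks(rs, qs, k)
  if (nrow(blocks) == 0L) {
    stop(sprintf(paste0("non-collinear: no shared unique %d-mers in a %d/%d",
                        " bp segment (inversion or transposition?)"), k, nr,
                 nq), call. = FALSE)
  }
  chain <- chain_blocks(blocks)
  if (sum(chain$len) < 0.5 * sum(blocks$len)) {
    stop(paste0("non-collinear: best collinear anchor chain covers under ",
                "half of the anchorable sequence (inversion or ",
                "transposition?)"), call. = FALSE)
  }
  ref_chunks <- character(); qry_chunks <- character()
  n_anchors <- nrow(chain)
  cur_r <- 1L; cur_q <- 1L
  for (i in seq_len(nrow(chain))) {
    ri <- chain$r[i]; qi <- chain$q[i]; len <- chain$len[i]
    delta <- max(cur_r - ri, cur_q - qi, 0L)
    ri <- ri + delta; qi <- qi + delta; len <- len - delta
    if (len <= 0L) next
    sub <- align_rec(substring(rs, cur_r, ri - 1L), substring(qs, cur_q, qi - 1L),
                     k, max_gap_span, depth + 1L)
    ref_chunks <- c(ref_chunks, sub$ref)
    qry_chunks <- c(qry_chunks, sub$qry)
    n_anchors <- n_anchors + sub$n_anchors
    ref_chunks <- c(ref_chunks, substring(rs, ri, ri + len - 1L))
    qry_chunks <- c(qry_chunks, substring(qs, qi, qi + len - 1L))
    cur_r <- ri + len; cur_q <- qi + len
  }
  tail <- align_rec(substring(rs, cur_r, nr), substring(qs, cur_q, nq),
                    k, max_gap_span, depth + 1L)
  list(ref = c(ref_chunks, tail$ref), qry = c(qry_chunks, tail$qry),
       n_anchors = n_anchors + tail$n_anchors)
}

# shared k-mers unique in both sequences, collapsed into same-diagonal blocks
anchor_blocks <- function(rs, qs, k) {
  nr <- nchar(rs); nq <- nchar(qs)
  if (nr < k || nq < k) {
    return(data.frame(r = integer(), q = integer(), len = integer()))
  }
  kr <- substring(rs, seq_len(nr - k + 1L), k:nr)
  kq <- substring(qs, seq_len(nq - k + 1L), k:nq)
  uniq <- function(x) !(duplicated(x) | duplicated(x, fromLast = TRUE))
  ur <- uniq(kr); uq <- uniq(kq)
  pos_q <- match(kr, kq)
  ok <- ur & !is.na(pos_q) & uq[ifelse(is.na(pos_q), 1L, pos_q)]
  r <- which(ok); q <- pos_q[ok]
  if (length(r) == 0L) {
    return(data.frame(r = integer(), q = integer(), len = integer()))
  }
  o <- order(r)
  r <- r[o]; q <- q[o]
  new_block <- c(TRUE, diff(r) != 1L | diff(q) != 1L)
  id <- cumsum(new_block)
  first <- !duplicated(id)
  data.frame(r = r[first], q = q[first],
             len = as.integer(tabulate(id)) + k - 1L)
}

# highest-weight chain with strictly increasing r and q (quadratic DP;
# block counts are small for near-identical genomes)
chain_blocks <- function(blocks) {
  b <- blocks[order(blocks$r, blocks$q), , drop = FALSE]
  n <- nrow(b)
  score <- b$len
  prev <- rep(0L, n)
  for (i in seq_len(n)) {
    cand <- which(b$r[seq_len(i - 1L)] < b$r[i] & b$q[seq_len(i - 1L)] < b$q[i])
    if (length(cand)) {
      j <- cand[which.max(score[cand])]
      if (score[j] + b$len[i] > score[i]) {
        score[i] <- score[j] + b$len[i]
        prev[i] <- j
      }
    }
  }
  i <- which.max(score)
  path <- integer()
  while (i != 0L) { path <- c(i, path); i <- prev[i] }
  b[path, , drop = FALSE]
}

# global affine-gap DP on one segment pair (Biostrings)
dp_align <- function(rs, qs) {
  mat <- matrix(-2, 5L, 5L, dimnames = list(c(DNA_BASES, "N"),
                                            c(DNA_BASES, "N")))
  diag(mat) <- 1
  aln <- Biostrings::pairwiseAlignment(qs, rs, type = "global",
                                       substitutionMatrix = mat,
                                       gapOpening = 5, gapExtension = 2)
  list(ref = as.character(Biostrings::alignedSubject(aln)),
       qry = as.character(Biostrings::alignedPattern(aln)))
}

#' Call variant events from a pairwise alignment
#'
#' Maximal gap runs in the query become deletions, maximal gap runs in the
#' reference become insertions (anchored at the reference base immediately
#' 5', left-normalized VCF-style); isolated mismatch columns become SNPs and
#' runs of two or more contiguous mismatch columns become one substitution
#' block.
#'
#' @param aln a `pairwise_alignment`
#' @return data.frame: qry_id, kind (SNP, substitution_block, insertion,
#'   deletion), ref_pos, length, ref_allele, qry_allele
#' @export
call_variants <- function(aln) {
  stopifnot(inherits(aln, "pairwise_alignment"))
  rc <- seq_chars(aln$ref_aln)
  qc <- seq_chars(aln$qry_aln)
  stopifnot(length(rc) == length(qc), !any(rc == "-" & qc == "-"))
  refpos <- cumsum(rc != "-")
  rs <- gsub("-", "", aln$ref_aln, fixed = TRUE)
  ev <- list()
  add <- function(kind, pos, len, ra, qa) {
    ev[[length(ev) + 1L]] <<- data.frame(qry_id = aln$qry_id, kind = kind,
                                         ref_pos = pos, length = len,
                                         ref_allele = ra, qry_allele = qa)
  }
  # deletions: gap runs in qry
  for (run in which_runs(qc == "-")) {
    a <- refpos[run[1L]]; b <- refpos[run[2L]]
    # left-normalize on the reference
    while (a > 1L && substring(rs, a - 1L, a - 1L) == substring(rs, b, b)) {
      a <- a - 1L; b <- b - 1L
    }
    add("deletion", a, b - a + 1L, substring(rs, a, b), "")
  }
  # insertions: gap runs in ref
  for (run in which_runs(rc == "-")) {
    p <- if (run[1L] > 1L) refpos[run[1L] - 1L] else 0L
    ins <- paste(qc[run[1L]:run[2L]], collapse = "")
    while (p >= 1L &&
           substring(rs, p, p) == substring(ins, nchar(ins), nchar(ins))) {
      ins <- paste0(substring(rs, p, p),
                    substring(ins, 1L, nchar(ins) - 1L))
      p <- p - 1L
    }
    add("insertion", p, nchar(ins), "", ins)
  }
  # mismatch columns: isolated -> SNP; contiguous runs -> substitution block
  for (run in which_runs(rc != "-" & qc != "-" & rc != qc)) {
    a <- run[1L]; b <- run[2L]
    kind <- if (b == a) "SNP" else "substitution_block"
    add(kind, refpos[a], b - a + 1L,
        paste(rc[a:b], collapse = ""), paste(qc[a:b], collapse = ""))
  }
  if (length(ev) == 0L) {
    return(data.frame(qry_id = character(), kind = character(),
                      ref_pos = integer(), length = integer(),
                      ref_allele = character(), qry_allele = character()))
  }
  out <- do.call(rbind, ev)
  out <- out[order(out$ref_pos, out$kind), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# maximal TRUE runs of a logical vector, as list of c(start, end)
which_runs <- function(x) {
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  idx <- which(r$values)
  lapply(idx, function(i) c(starts[i], ends[i]))
}

#' Fraction of indels falling inside tandem-repeat loci
#'
#' An event is "within" a tandem array when its reference anchor position
#' lies inside `[start - flank, end + flank]` of any tandem hit.
#'
#' @param events variant table from [call_variants()] (possibly pooled)
#' @param tandems tandem table from [find_tandem_repeats()] on the reference
#' @param flank extra bp on each side of every array
#' @return list: insertion_fraction, deletion_fraction, n_insertions,
#'   n_deletions, n_insertions_in_tandem, n_deletions_in_tandem
#' @export
tandem_overlap_fractions <- function(events, tandems, flank = 0L) {
  in_tandem <- function(pos) {
    if (nrow(tandems) == 0L || length(pos) == 0L) {
      return(rep(FALSE, length(pos)))
    }
    vapply(pos, function(x) any(x >= tandems$start - flank &
                                  x <= tandems$end + flank), logical(1L))
  }
  ins <- events[events$kind == "insertion", , drop = FALSE]
  del <- events[events$kind == "deletion", , drop = FALSE]
  n_ins_in <- sum(in_tandem(ins$ref_pos))
  n_del_in <- sum(in_tandem(del$ref_pos))
  list(insertion_fraction = if (nrow(ins)) n_ins_in / nrow(ins) else 0,
       deletion_fraction = if (nrow(del)) n_del_in / nrow(del) else 0,
       n_insertions = nrow(ins), n_deletions = nrow(del),
       n_insertions_in_tandem = n_ins_in, n_deletions_in_tandem = n_del_in)
}
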