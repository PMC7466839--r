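#' Multiple alignment of one locus across species
#'
#' Deterministic center-star progressive alignment for the highly similar
#' sequences of one plastome locus: the medoid by 4-mer frequency distance
#' (ties to the alphabetically first member id) is the center; every other
#' member is aligned to the center globally with affine gaps; insertions
#' relative to the center are merged by position (left-justified, padded to
#' the longest insertion).
#'
#' @param seqs named character vector of >= 2 locus sequences
#' @param locus,cls,region optional metadata carried along
#' @return a `locus_alignment`: locus, class, region, ids, aln (named,
#'   equal-length, gapped with "-")
#' @export
align_locus <- function(seqs, locus = NA_character_, cls = NA_character_,
                        region = NA_character_) {
  assert_that(length(seqs) >= 2L, "need at least two sequences")
  ids <- names(seqs) %||% paste0("seq", seq_along(seqs))
  names(seqs) <- ids
  if (length(unique(seqs)) == 1L) {
    aln <- seqs
  } else {
    kf <- Biostrings::oligonucleotideFrequency(
      Biostrings::DNAStringSet(gsub("N", "A", seqs)), width = 4L)
    dtot <- rowSums(as.matrix(stats::dist(kf, method = "manhattan")))
    center_id <- sort(ids[dtot == min(dtot)])[1L]
    center <- seqs[[center_id]]
    lc <- nchar(center)
    # per-member: character of member at each center position, plus the
    # insertion string after each center position (index 0 = before start)
    pieces <- lapply(ids, function(id) {
      if (id == center_id || seqs[[id]] == center) {
        return(list(at = seq_chars(center), ins = rep("", lc + 1L)))
      }
      pa <- dp_align(center, seqs[[id]])
      cc <- seq_chars(pa$ref); mc <- seq_chars(pa$qry)
      cpos <- cumsum(cc != "-")
      at <- rep("-", lc)
      at[cpos[cc != "-"]] <- mc[cc != "-"]
      ins <- rep("", lc + 1L)
      gp <- which(cc == "-")
      if (length(gp)) {
        for (run in which_runs(cc == "-")) {
          after <- cpos[run[1L]] # center position the insertion follows
          ins[after + 1L] <- paste(mc[run[1L]:run[2L]], collapse = "")
        }
      }
      list(at = at, ins = ins)
    })
    names(pieces) <- ids
    ins_len <- apply(vapply(pieces, function(p) nchar(p$ins),
                            numeric(lc + 1L)), 1L, max)
    aln <- vapply(pieces, function(p) {
      blocks <- character(2L * lc + 1L)
      pad <- function(x, w) paste0(x, strrep("-", w - nchar(x)))
      blocks[1L] <- pad(p$ins[1L], ins_len[1L])
      blocks[seq_len(lc) * 2L] <- p$at
      blocks[seq_len(lc) * 2L + 1L] <- pad(p$ins[seq_len(lc) + 1L],
                                           ins_len[seq_len(lc) + 1L])
      paste(blocks, collapse = "")
    }, character(1L))
    names(aln) <- ids
  }
  structure(list(locus = locus, class = cls, region = region, ids = ids,
                 aln = aln), class = "locus_alignment")
}

#' Nucleotide diversity (Pi) of a locus alignment
#'
#' Pi = (2 / (n(n-1))) * sum over pairs of d_ij / L_ij, where d_ij counts
#' differing columns and L_ij counts columns with no gap (and no N) in either
#' member — pairwise deletion, the convention of standard polymorphism
#' software. With `complete_deletion = TRUE` only columns gap-free in all
#' members are used.
#'
#' @param aln a `locus_alignment` (or named character vector of equal-length
#'   gapped strings)
#' @param complete_deletion drop columns with any gap anywhere first
#' @return list: locus, pi, n, sites_used (mean pairwise comparable columns)
#' @export
nucleotide_diversity <- function(aln, complete_deletion = FALSE) {
  seqs <- if (inherits(aln, "locus_alignment")) aln$aln else aln
  n <- length(seqs)
  assert_that(n >= 2L, "need >= 2 aligned sequences")
  lens <- nchar(seqs)
  assert_that(length(unique(lens)) == 1L, "aligned rows must be equal length")
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  valid <- m != "-" & m != "N"
  if (complete_deletion) {
    keep <- colSums(valid) == n
    m <- m[, keep, drop = FALSE]
    valid <- valid[, keep, drop = FALSE]
  }
  tot <- 0
  l_sum <- 0
  npairs <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      lij <- sum(ok)
      if (lij == 0L) next
      tot <- tot + sum(m[i, ok] != m[j, ok]) / lij
      l_sum <- l_sum + lij
      npairs <- npairs + 1L
    }
  }
  if (npairs == 0L) {
    stop("Pi undefined: no pair shares a gap-free column", call. = FALSE)
  }
  list(locus = if (inherits(aln, "locus_alignment")) aln$locus else NA_character_,
       pi = 2 / (n * (n - 1)) * tot, n = n,
       sites_used = floor(l_sum / npairs))
}

#' Rank diversity hotspots
#'
#' Genes and intergenic loci ranked separately by descending Pi, ties broken
#' by locus name for determinism.
#' @param results data.frame with columns locus, class, pi (one row per locus)
#' @param top how many to return per class
#' @return list with `genes` and `intergenic` data.frames carrying a rank
#'   column
#' @export
rank_hotspots <- function(results, top = 10L) {
  rank_one <- function(df) {
    df <- df[order(-df$pi, df$locus), , drop = FALSE]
    df$rank <- seq_len(nrow(df))
    head(df, top)
  }
  list(genes = rank_one(results[results$class == "gene", , drop = FALSE]),
       intergenic = rank_one(results[results$class == "intergenic", ,
                                     drop = FALSE]))
}
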