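#' Plastome and feature containers
#'
#' A `Plastome` is a lightweight S3 container for one chloroplast genome
#' record: an id, the (upper-case) sequence, a circularity flag and a list of
#' annotated features. Coordinates are 1-based inclusive throughout, matching
#' the GenBank convention; the BED track writer is the only 0-based surface.
#'
#' @param id non-empty accession or label
#' @param sequence DNA string over {A,C,G,T,N}
#' @param circular logical flag
#' @param features list of objects built with [feature()]
#' @return an object of class `plastome`
#' @examples
#' p <- plastome("toy", "ATGAAATGACCC",
#'               features = list(feature("g1", "CDS", "+", cbind(1, 9))))
#' gc_content(p)
#' @export
plastome <- function(id, sequence, circular = TRUE, features = list()) {
  assert_that(is.character(id) && length(id) == 1L && nzchar(id),
              "plastome id must be a non-empty string")
  assert_that(is.character(sequence) && length(sequence) == 1L &&
                nchar(sequence) > 0L, "plastome sequence must be non-empty")
  sequence <- toupper(sequence)
  bad <- gsub("[ACGTN]", "", sequence)
  assert_that(nchar(bad) == 0L,
              paste0("sequence contains non-ACGTN characters: ",
                     substr(bad, 1L, 10L)))
  n <- nchar(sequence)
  for (f in features) {
    assert_that(inherits(f, "plastome_feature"),
                "features must be built with feature()")
    if (any(f$parts[, 1L] < 1L) || any(f$parts[, 2L] > n)) {
      stop(sprintf("feature '%s' has an interval outside [1, %d]", f$name, n),
           call. = FALSE)
    }
  }
  structure(list(id = id, sequence = sequence, circular = isTRUE(circular),
                 features = features),
            class = "plastome")
}

#' @param name gene or locus symbol
#' @param kind one of CDS, gene, tRNA, rRNA, intron, exon, intergenic
#' @param strand "+" or "-"
#' @param parts integer matrix with columns start, end (1-based inclusive);
#'   one row per exon/part, in transcript order (compound locations)
#' @param trans_spliced flag for trans-spliced genes (e.g. rps12, whose 5'
#'   exon sits in the LSC while exons 2-3 sit in the IR)
#' @param codon_start reading-frame offset (1, 2 or 3), as in GenBank
#' @rdname plastome
#' @export
feature <- function(name, kind, strand = "+", parts,
                    trans_spliced = FALSE, codon_start = 1L) {
  kind <- match.arg(kind, c("CDS", "gene", "tRNA", "rRNA", "intron", "exon",
                            "intergenic"))
  strand <- match.arg(strand, c("+", "-"))
  parts <- matrix(as.integer(parts), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  assert_that(nrow(parts) >= 1L && all(parts[, 2L] >= parts[, 1L]),
              sprintf("feature '%s': parts must be non-empty and non-degenerate",
                      name))
  structure(list(name = name, kind = kind, strand = strand, parts = parts,
                 trans_spliced = isTRUE(trans_spliced),
                 codon_start = as.integer(codon_start)),
            class = "plastome_feature")
}

#' @export
print.plastome <- function(x, ...) {
  cat(sprintf("<plastome> %s: %s bp, %s, %d features\n", x$id,
              format(nchar(x$sequence), big.mark = ","),
              if (x$circular) "circular" else "linear", length(x$features)))
  invisible(x)
}

#' @export
length.plastome <- function(x) nchar(x$sequence)

# total feature span on the genome (union not taken; per-part sum)
feature_length <- function(f) sum(f$parts[, 2L] - f$parts[, 1L] + 1L)

# extract the strand-oriented, exon-joined sequence of a feature
feature_sequence <- function(p, f) {
  pieces <- substring(p$sequence, f$parts[, 1L], f$parts[, 2L])
  if (f$strand == "-") {
    paste(vapply(rev(pieces), revcomp, character(1L)), collapse = "")
  } else {
    paste(pieces, collapse = "")
  }
}

#' GC content of a plastome
#'
#' 100 * (#G + #C) / (#A + #C + #G + #T); N excluded from the denominator.
#' Reported rounded half-up to 2 decimals, the precision of published genome
#' summary tables.
#' @param p a [plastome()]
#' @return percent, 2 decimals
#' @export
gc_content <- function(p) {
  stopifnot(inherits(p, "plastome"))
  counts <- table(factor(seq_chars(p$sequence), levels = c(DNA_BASES, "N")))
  denom <- sum(counts[DNA_BASES])
  if (denom == 0L) stop("GC content undefined: sequence is all N", call. = FALSE)
  round_half_up(100 * sum(counts[c("G", "C")]) / denom, 2L)
}
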