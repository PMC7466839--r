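#' Extract gene, intron and intergenic loci
#'
#' Gene sequences are strand-oriented and exon-joined; introns are the gaps
#' between consecutive exons of a multi-part feature; intergenic loci are the
#' gaps between adjacent gene spans in genome order, named "geneA-geneB".
#' Each locus is assigned to a region (LSC/SSC/IRB/IRA) by its midpoint.
#' Duplicate locus names within one region are disambiguated with numeric
#' suffixes (with a warning).
#'
#' @param p a [plastome()]
#' @param part a `region_partition`, or NULL to skip region assignment (the
#'   region column is then NA; useful when loci of a derived genome inherit
#'   their region from the reference by locus name)
#' @return data.frame: locus, class (gene/intron/intergenic), region, start,
#'   end, strand, sequence (oriented for genes/introns; forward-strand for
#'   intergenic loci)
#' @export
extract_loci <- function(p, part = NULL) {
  stopifnot(inherits(p, "plastome"),
            is.null(part) || inherits(part, "region_partition"))
  kinds <- vapply(p$features, `[[`, character(1L), "kind")
  coding <- which(kinds %in% c("CDS", "tRNA", "rRNA"))
  use <- if (length(coding)) coding else which(kinds == "gene")
  rows <- list()
  spans <- list()
  for (i in use) {
    f <- p$features[[i]]
    span <- c(min(f$parts[, 1L]), max(f$parts[, 2L]))
    spans[[length(spans) + 1L]] <- data.frame(name = f$name, start = span[1L],
                                              end = span[2L])
    rows[[length(rows) + 1L]] <- data.frame(
      locus = f$name, class = "gene",
      start = span[1L], end = span[2L], strand = f$strand,
      sequence = feature_sequence(p, f))
    if (nrow(f$parts) > 1L && !f$trans_spliced) {
      parts <- f$parts[order(f$parts[, 1L]), , drop = FALSE]
      for (k in seq_len(nrow(parts) - 1L)) {
        is_ <- parts[k, 2L] + 1L
        ie <- parts[k + 1L, 1L] - 1L
        if (ie < is_) next
        iseq <- substring(p$sequence, is_, ie)
        if (f$strand == "-") iseq <- revcomp(iseq)
        rows[[length(rows) + 1L]] <- data.frame(
          locus = sprintf("%s.intron%d", f$name, k), class = "intron",
          start = is_, end = ie, strand = f$strand, sequence = iseq)
      }
    }
  }
  if (length(spans)) {
    sp <- do.call(rbind, spans)
    sp <- sp[order(sp$start, sp$end), , drop = FALSE]
    # merge overlapping gene spans so gaps are genuinely intergenic
    k <- 1L
    while (k < nrow(sp)) {
      gap_s <- sp$end[k] + 1L
      gap_e <- sp$start[k + 1L] - 1L
      if (gap_e >= gap_s) {
        rows[[length(rows) + 1L]] <- data.frame(
          locus = sprintf("%s-%s", sp$name[k], sp$name[k + 1L]),
          class = "intergenic", start = gap_s, end = gap_e, strand = "+",
          sequence = substring(p$sequence, gap_s, gap_e))
      }
      k <- k + 1L
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(locus = character(), class = character(),
                      region = character(), start = integer(),
                      end = integer(), strand = character(),
                      sequence = character()))
  }
  out <- do.call(rbind, rows)
  out$region <- if (is.null(part)) NA_character_ else
    region_of(part, floor((out$start + out$end) / 2))
  out <- out[, c("locus", "class", "region", "start", "end", "strand",
                 "sequence")]
  # disambiguate duplicate names within a region
  key <- paste(out$region, out$class, out$locus)
  dup <- duplicated(key) | duplicated(key, fromLast = TRUE)
  if (any(dup)) {
    warning("duplicate locus names within a region; adding suffixes")
    for (k in unique(key[dup])) {
      idx <- which(key == k)
      out$locus[idx[-1L]] <- sprintf("%s_%d", out$locus[idx[-1L]],
                                     seq_along(idx[-1L]) + 1L)
    }
  }
  rownames(out) <- NULL
  out
}
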