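#' Classify repeat hits by genomic region and annotation context
#'
#' Each hit is assigned by its midpoint to a region (LSC, SSC or IR — the two
#' IR copies are pooled) and an annotation context: CDS (exonic part of any
#' coding/tRNA/rRNA feature), intron (inside a gene span but between exons),
#' or IGS (intergenic spacer). Hits straddling a junction are still assigned
#' by midpoint and flagged.
#'
#' @param hits data.frame with `start` and `end` columns (for dispersed
#'   repeats pass the first copy as start/end)
#' @param part a `region_partition`
#' @param features list of [feature()] objects (or a [plastome()])
#' @return list: `assignments` (hits + region, context, straddles_junction),
#'   `counts` (region x context matrix), `percent`
#' @export
classify_locations <- function(hits, part, features) {
  stopifnot(is.data.frame(hits), inherits(part, "region_partition"))
  if (inherits(features, "plastome")) features <- features$features
  regions <- c("LSC", "SSC", "IR")
  contexts <- c("CDS", "intron", "IGS")
  counts <- matrix(0L, nrow = 3L, ncol = 3L,
                   dimnames = list(regions, contexts))
  if (nrow(hits) == 0L) {
    return(list(assignments = cbind(hits, region = character(0),
                                    context = character(0)),
                counts = counts, percent = counts))
  }
  mid <- floor((hits$start + hits$end) / 2)
  reg <- region_of(part, mid)
  reg[reg %in% c("IRB", "IRA")] <- "IR"
  # exonic intervals and gene spans
  kinds <- vapply(features, `[[`, character(1L), "kind")
  use <- which(kinds %in% c("CDS", "tRNA", "rRNA", "gene"))
  exon_iv <- do.call(rbind, c(list(matrix(integer(), ncol = 2L)),
                              lapply(features[use], `[[`, "parts")))
  span_iv <- do.call(rbind, c(list(matrix(integer(), ncol = 2L)),
                              lapply(features[use], function(f)
                                cbind(min(f$parts[, 1L]), max(f$parts[, 2L])))))
  in_any <- function(pos, iv) {
    if (nrow(iv) == 0L) return(rep(FALSE, length(pos)))
    vapply(pos, function(x) any(x >= iv[, 1L] & x <= iv[, 2L]), logical(1L))
  }
  ctx <- ifelse(in_any(mid, exon_iv), "CDS",
                ifelse(in_any(mid, span_iv), "intron", "IGS"))
  bounds <- c(part$lsc[2L], part$irb[2L], part$ssc[2L])
  straddle <- vapply(seq_len(nrow(hits)), function(i)
    any(hits$start[i] <= bounds & hits$end[i] > bounds), logical(1L))
  for (i in seq_along(mid)) counts[reg[i], ctx[i]] <- counts[reg[i], ctx[i]] + 1L
  pct <- if (sum(counts) > 0L) round(100 * counts / sum(counts), 2L) else counts
  list(assignments = cbind(hits, region = reg, context = ctx,
                           straddles_junction = straddle),
       counts = counts, percent = pct)
}
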