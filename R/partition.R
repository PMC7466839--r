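#' Detect the quadripartite plastome structure
#'
#' Finds the maximal pair of near-identical inverted segments (the IRs) and
#' derives the LSC / IRB / SSC / IRA partition. Plastomes are analyzed as
#' linearized in the deposited orientation, with the origin inside the LSC and
#' region order LSC, IRB, SSC, IRA along the sequence (the grass convention);
#' IR detection does not wrap the origin. The IR copy encountered first after
#' the large single-copy region is labeled IRB.
#'
#' @param p a [plastome()]
#' @param min_ir_len minimum IR length in bp to accept (default 10000)
#' @param max_mismatch_frac maximum fraction of non-identical positions
#'   between IRB and reverse-complement(IRA) (default 0.001)
#' @return a `region_partition`: 1-based inclusive intervals `lsc`, `irb`,
#'   `ssc`, `ira`, plus `ir_length` and `mismatches`
#' @export
detect_quadripartite <- function(p, min_ir_len = 10000L,
                                 max_mismatch_frac = 0.001) {
  stopifnot(inherits(p, "plastome"))
  s <- p$sequence
  n <- nchar(s)
  rc <- revcomp(s)
  budget <- max(0L, floor(max_mismatch_frac * n))
  seed <- max(12L, min(31L, min_ir_len %/% (budget + 1L)))
  hits <- cpp_pair_scan(s, rc, as.integer(min_ir_len),
                        as.integer(budget), as.integer(seed), FALSE)
  cand <- if (nrow(hits) == 0L) {
    data.frame(s1 = integer(), s2 = integer(), len = integer(),
               mm = integer())
  } else {
    # the seed scan locates candidate diagonals; the length-maximal window
    # satisfying the mismatch-fraction constraint is then found per diagonal
    diags <- unique(hits$start_b - hits$start_a)
    do.call(rbind, lapply(diags, function(d)
      best_ir_window(s, rc, d, min_ir_len, max_mismatch_frac, budget)))
  }
  if (is.null(cand) || nrow(cand) == 0L) {
    stop(sprintf("no-IR: no inverted repeat pair of length >= %d found",
                 min_ir_len), call. = FALSE)
  }
  best_len <- max(cand$len)
  best <- cand[cand$len == best_len, , drop = FALSE]
  if (nrow(best) > 1L) {
    # non-nested distinct maximal pairs of equal length are ambiguous
    dedup <- unique(best[, c("s1", "s2", "len")])
    if (nrow(dedup) > 1L) {
      stop(paste0("ambiguous IR detection: multiple maximal inverted pairs: ",
                  paste(sprintf("[%d-%d]~[%d-%d]", dedup$s1,
                                dedup$s1 + dedup$len - 1L, dedup$s2,
                                dedup$s2 + dedup$len - 1L), collapse = ", ")),
           call. = FALSE)
    }
    best <- best[1L, , drop = FALSE]
  }
  a <- best$s1; b <- best$s1 + best$len - 1L
  c_ <- best$s2; d <- best$s2 + best$len - 1L
  if (d != n) {
    stop(paste0("sequence not in the deposited orientation: the second IR ",
                "copy does not end at the sequence end (origin must lie in ",
                "the LSC; origin re-rotation is out of scope)"), call. = FALSE)
  }
  outer_len <- a - 1L
  inner_len <- c_ - b - 1L
  if (outer_len <= inner_len) {
    stop(paste0("sequence not in the deposited orientation: the larger ",
                "single-copy region (LSC) must precede the first IR copy"),
         call. = FALSE)
  }
  irb <- substring(s, a, b)
  ira <- substring(s, c_, d)
  mm <- sum(seq_chars(irb) != seq_chars(revcomp(ira)))
  if (mm / best$len > max_mismatch_frac) {
    stop("no-IR: best inverted pair exceeds the mismatch tolerance",
         call. = FALSE)
  }
  structure(list(lsc = c(1L, a - 1L), irb = c(a, b),
                 ssc = c(b + 1L, c_ - 1L), ira = c(c_, d),
                 ir_length = as.integer(best$len), mismatches = as.integer(mm)),
            class = "region_partition")
}

# longest window on one diagonal of the s-vs-revcomp(s) comparison whose
# mismatch count stays within max_mismatch_frac of its length; returns the
# implied (disjoint, canonicalized) inverted pair(s), possibly several ties
best_ir_window <- function(s, rc, d, min_ir_len, max_mismatch_frac, budget) {
  n <- nchar(s)
  lo <- max(1L, 1L - d)
  hi <- min(n, n - d)
  if (hi - lo + 1L < min_ir_len) return(NULL)
  sa <- seq_chars(substring(s, lo, hi))
  sb <- seq_chars(substring(rc, lo + d, hi + d))
  mmpos <- c(lo - 1L, lo - 1L + which(sa != sb | sa == "N" | sb == "N"),
             hi + 1L)
  nm <- length(mmpos) - 2L
  out <- NULL
  best_len <- min_ir_len - 1L
  for (k in 0:min(budget, nm)) {
    # windows containing exactly k mismatches, maximal between neighbours
    i <- seq_len(nm - k + 1L)
    ws <- mmpos[i] + 1L
    we <- mmpos[i + k + 1L] - 1L
    len <- we - ws + 1L
    ok <- len > best_len & k <= max_mismatch_frac * len
    if (k >= 1L) {
      # ends must be match columns (windows whose boundary mismatches are
      # trimmed off re-appear at a smaller k)
      ok <- ok & mmpos[i + 1L] > ws & mmpos[i + k] < we
    }
    if (!any(ok)) next
    lmax <- max(len[ok])
    sel <- which(ok & len == lmax)
    s1 <- ws[sel]
    s2 <- n - (ws[sel] + d + lmax - 1L) + 1L
    plo <- pmin(s1, s2); phi <- pmax(s1, s2)
    disjoint <- plo + lmax - 1L < phi
    if (!any(disjoint)) next
    best_len <- lmax
    out <- unique(data.frame(s1 = plo[disjoint], s2 = phi[disjoint],
                             len = lmax, mm = k))
  }
  out
}

#' @export
print.region_partition <- function(x, ...) {
  cat(sprintf(paste0("<region_partition> LSC %d-%d | IRB %d-%d | SSC %d-%d |",
                     " IRA %d-%d (IR %d bp, %d mismatches)\n"),
              x$lsc[1L], x$lsc[2L], x$irb[1L], x$irb[2L], x$ssc[1L],
              x$ssc[2L], x$ira[1L], x$ira[2L], x$ir_length, x$mismatches))
  invisible(x)
}

# region label ("LSC","IRB","SSC","IRA") of a position by containment
region_of <- function(part, pos) {
  out <- character(length(pos))
  for (r in c("lsc", "irb", "ssc", "ira")) {
    iv <- part[[r]]
    out[pos >= iv[1L] & pos <= iv[2L]] <- toupper(r)
  }
  out
}

partition_length <- function(part) {
  sum(vapply(c("lsc", "irb", "ssc", "ira"),
             function(r) part[[r]][2L] - part[[r]][1L] + 1L, numeric(1L)))
}

#' Gene distances to the IR/SC junctions
#'
#' For each of the four junctions (LSC/IRB, IRB/SSC, SSC/IRA, IRA/LSC) the
#' nearest annotated gene on each side is reported with its distance in bp
#' from the gene boundary to the junction; genes straddling a junction are
#' flagged with both flank lengths (which sum to the gene span). Because the
#' IRA/LSC junction coincides with the linearization origin of circular
#' records, a circular distance (shortest way around the molecule) is
#' reported alongside the linear one.
#'
#' @param p a [plastome()]
#' @param part a `region_partition` from [detect_quadripartite()]
#' @return data.frame: gene, junction, side (`inside-SC`, `inside-IR`,
#'   `straddling`), distance, distance_circular, overhang_left, overhang_right
#' @export
junction_distances <- function(p, part) {
  stopifnot(inherits(p, "plastome"), inherits(part, "region_partition"))
  genes <- gene_spans(p)
  cols <- c("gene", "junction", "side", "distance", "distance_circular",
            "overhang_left", "overhang_right")
  if (nrow(genes) == 0L) {
    out <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    out$distance <- numeric(0); out$distance_circular <- numeric(0)
    return(out)
  }
  n <- nchar(p$sequence)
  junctions <- c("LSC/IRB" = part$lsc[2L], "IRB/SSC" = part$irb[2L],
                 "SSC/IRA" = part$ssc[2L], "IRA/LSC" = part$ira[2L])
  rows <- list()
  for (jn in names(junctions)) {
    b <- junctions[[jn]]  # junction sits between positions b and b+1 (mod n)
    gs <- genes$start; ge <- genes$end
    straddle <- gs <= b & ge > b
    left <- ge <= b
    right <- gs > b
    d_left <- b - ge            # gap from gene end to junction
    d_right <- gs - b - 1L      # gap from junction to gene start
    # circular distances to the junction point
    d_circ <- pmin(ifelse(left | right, pmin((b - ge) %% n, (gs - 1L - b) %% n),
                          0L), n)
    add_row <- function(i, side, dist, dc, ol = NA_integer_, or = NA_integer_) {
      data.frame(gene = genes$name[i], junction = jn, side = side,
                 distance = dist, distance_circular = dc,
                 overhang_left = ol, overhang_right = or)
    }
    for (i in which(straddle)) {
      rows[[length(rows) + 1L]] <-
        add_row(i, "straddling", 0L, 0L, b - gs[i] + 1L, ge[i] - b)
    }
    side_of <- function(i) {
      mid <- (gs[i] + ge[i]) / 2
      if (region_of(part, floor(mid)) %in% c("IRB", "IRA")) "inside-IR"
      else "inside-SC"
    }
    if (any(left)) {
      i <- which(left)[which.min(d_left[left])]
      rows[[length(rows) + 1L]] <- add_row(i, side_of(i), d_left[i], d_circ[i])
    }
    if (any(right)) {
      i <- which(right)[which.min(d_right[right])]
      rows[[length(rows) + 1L]] <- add_row(i, side_of(i), d_right[i], d_circ[i])
    }
  }
  do.call(rbind, rows)
}

# one span per named gene-like feature (gene preferred over CDS/tRNA/rRNA)
gene_spans <- function(p) {
  kinds <- vapply(p$features, `[[`, character(1L), "kind")
  use <- if (any(kinds == "gene")) which(kinds == "gene") else
    which(kinds %in% c("CDS", "tRNA", "rRNA"))
  if (length(use) == 0L) {
    return(data.frame(name = character(), start = integer(), end = integer(),
                      strand = character(), idx = integer()))
  }
  df <- do.call(rbind, lapply(use, function(i) {
    f <- p$features[[i]]
    data.frame(name = f$name, start = min(f$parts[, 1L]),
               end = max(f$parts[, 2L]), strand = f$strand, idx = i)
  }))
  df <- df[!duplicated(df[, c("name", "start", "end")]), , drop = FALSE]
  df[order(df$start, df$end), , drop = FALSE]
}
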