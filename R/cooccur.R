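#' Bin tandem repeats and variant events into fixed windows
#'
#' Non-overlapping windows of `w` bp tile the reference; bin `b` covers
#' `[(b-1)w + 1, min(bw, ref_len)]` and the short final bin is retained so
#' column sums equal the pooled event totals. Variant events are assigned by
#' their reference anchor (an insertion normalized to anchor 0 falls in bin
#' 1); tandem arrays by their midpoint.
#'
#' @param events pooled variant table ([call_variants()] rows, any number of
#'   query genomes)
#' @param tandems tandem table on the same reference coordinates
#' @param ref_len reference length in bp
#' @param w window width in bp (default 150)
#' @return data.frame: bin, start, end, tandem, indel, snp, substitution
#' @export
bin_counts <- function(events, tandems, ref_len, w = 150L) {
  nb <- ceiling(ref_len / w)
  if (nrow(events) > 0L && (any(events$ref_pos > ref_len) ||
                            any(events$ref_pos < 0L))) {
    stop("event coordinates outside [0, ref_len]", call. = FALSE)
  }
  if (nrow(tandems) > 0L && any(tandems$end > ref_len)) {
    stop("tandem coordinates outside the reference", call. = FALSE)
  }
  bin_of <- function(pos) pmin(pmax(ceiling(pos / w), 1L), nb)
  wt <- data.frame(bin = seq_len(nb),
                   start = (seq_len(nb) - 1L) * w + 1L,
                   end = pmin(seq_len(nb) * w, ref_len))
  cnt <- function(pos) tabulate(bin_of(pos), nbins = nb)
  wt$tandem <- if (nrow(tandems)) cnt(floor((tandems$start + tandems$end) / 2))
  else integer(nb)
  wt$indel <- cnt(events$ref_pos[events$kind %in% c("insertion", "deletion")])
  wt$snp <- cnt(events$ref_pos[events$kind == "SNP"])
  wt$substitution <- cnt(events$ref_pos[events$kind == "substitution_block"])
  wt
}

#' Spearman rank correlation with exact small-sample p-value
#'
#' Rho is the Pearson correlation of average ranks (ties shared). The
#' two-sided p-value uses the exact permutation distribution for
#' `n <= exact_n` (computed by a subset-sum dynamic program over all n!
#' permutations, so ties are handled exactly) and the t approximation with
#' n - 2 degrees of freedom above that.
#'
#' @param x,y equal-length count vectors (length >= 3, not constant)
#' @param exact_n exact-enumeration cutoff (default 10)
#' @return list: rho, p_value, n, strength, method
#' @export
spearman <- function(x, y, exact_n = 10L) {
  n <- length(x)
  assert_that(length(y) == n && n >= 3L, "need equal lengths >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L) {
    stop("undefined correlation: constant vector", call. = FALSE)
  }
  rx <- rank(x); ry <- rank(y)
  rho <- cor(rx, ry)
  if (n <= exact_n) {
    p <- spearman_exact_p(rx, ry)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / max(1 - rho^2, .Machine$double.eps))
    p <- 2 * pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(p, 1), n = n, strength = strength_label(rho),
       method = method)
}

# exact two-sided permutation p for the rank correlation, by a subset-sum DP
# over the distribution of S = sum(rx * ry[perm]); denominators are
# permutation-invariant so the tail of S gives the tail of |rho|.
spearman_exact_p <- function(rx, ry) {
  n <- length(rx)
  a <- as.integer(round(2 * rx)); b <- as.integer(round(2 * ry))
  s_obs <- sum(a * b)
  mu <- sum(a) * sum(b) / n  # permutation mean of S
  dev_obs <- abs(s_obs - mu)
  smax <- sum(sort(a, decreasing = TRUE) * sort(b, decreasing = TRUE))
  # f[[mask+1]] = counts over S values (offset by 1) using the b's in mask
  f <- vector("list", 2^n)
  f[[1L]] <- c(1)  # S = 0
  names(f)[1L] <- "0"
  masks <- 0:(2^n - 1)
  sizes <- vapply(masks, function(m) sum(bitwAnd(m, 2^(0:(n - 1))) > 0),
                  numeric(1L))
  sizes_of <- function(m) sizes[m + 1L]
  for (m in masks[order(sizes)]) {
    g <- f[[m + 1L]]
    if (is.null(g)) next
    i <- sizes_of(m) + 1L  # next a index to place
    if (i > n) next
    for (j in seq_len(n)) {
      bit <- bitwShiftL(1L, j - 1L)
      if (bitwAnd(m, bit) > 0L) next
      add <- a[i] * b[j]
      m2 <- m + bit
      g2 <- f[[m2 + 1L]]
      if (is.null(g2)) g2 <- numeric(smax + 1L)
      # g is dense over 0..smax (offset add)
      if (length(g) < smax + 1L) g <- c(g, numeric(smax + 1L - length(g)))
      shifted <- c(numeric(add), g[seq_len(smax + 1L - add)])
      f[[m2 + 1L]] <- g2 + shifted
    }
  }
  dist <- f[[2^n]]
  svals <- seq_along(dist) - 1L
  total <- sum(dist)
  sum(dist[abs(svals - mu) >= dev_obs - 1e-9]) / total
}

#' Correlation strength label (Akoglu bands)
#'
#' Bands on |rho|: under 0.1 "none"; 0.1-0.19 "very weak"; 0.20-0.29 "weak";
#' 0.30-0.39 "moderate"; 0.40-0.69 "strong"; 0.70-1.00 "very strong" (the
#' last band is an extension beyond the published table).
#' @param rho correlation in [-1, 1]
#' @return character label
#' @export
strength_label <- function(rho) {
  r <- abs(rho)
  assert_that(r <= 1 + 1e-12, "|rho| must be <= 1")
  if (r < 0.1) "none"
  else if (r < 0.2) "very weak"
  else if (r < 0.3) "weak"
  else if (r < 0.4) "moderate"
  else if (r < 0.7) "strong"
  else "very strong"
}

#' Mann-Whitney U test
#'
#' U for the "present" group against the "absent" group, with the exact
#' permutation distribution (all group assignments, ties handled exactly)
#' when n1 + n2 <= `exact_n`, and the tie-corrected normal approximation with
#' continuity correction otherwise. Two-sided.
#'
#' @param values_present,values_absent outcome values in windows with and
#'   without tandem repeats (both non-empty)
#' @param exact_n exact-enumeration cutoff on n1 + n2 (default 12)
#' @return list: U, p_value, n_present, n_absent, median_present,
#'   median_absent, method
#' @export
mann_whitney <- function(values_present, values_absent, exact_n = 12L) {
  n1 <- length(values_present); n2 <- length(values_absent)
  assert_that(n1 > 0L && n2 > 0L, "both groups must be non-empty")
  all_v <- c(values_present, values_absent)
  r <- rank(all_v)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  if (n1 + n2 <= exact_n) {
    # exact: U over all choose(n1+n2, n1) assignments of the observed values
    combos <- combn(n1 + n2, n1)
    devs <- apply(combos, 2L, function(idx) {
      abs(sum(r[idx]) - n1 * (n1 + 1) / 2 - mu)
    })
    p <- mean(devs >= abs(U - mu) - 1e-9)
    method <- "exact enumeration"
  } else {
    nn <- n1 + n2
    ties <- table(all_v)
    sigma2 <- n1 * n2 / 12 * ((nn + 1) - sum(ties^3 - ties) / (nn * (nn - 1)))
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sigma2)
      p <- 2 * pnorm(-abs(z))
    }
    method <- "normal approximation"
  }
  list(U = U, p_value = min(p, 1), n_present = n1, n_absent = n2,
       median_present = median(values_present),
       median_absent = median(values_absent), method = method)
}

#' Windowed association report
#'
#' All three pairwise Spearman correlations (tandem-indel, tandem-SNP,
#' indel-SNP) with strength labels and significance flags at `alpha`, plus
#' both Mann-Whitney tests (indel and SNP counts in tandem-present vs
#' tandem-absent windows). No multiple-testing correction is applied (the
#' convention of the comparative-plastome literature this reproduces); the
#' report says so.
#'
#' @param wt a window table from [bin_counts()]
#' @param alpha significance level (default 0.01)
#' @return list: correlations (data.frame), mann_whitney (list of two),
#'   alpha, note
#' @export
association_report <- function(wt, alpha = 0.01) {
  pairs <- list(c("tandem", "indel"), c("tandem", "snp"), c("indel", "snp"))
  cors <- do.call(rbind, lapply(pairs, function(pr) {
    s <- spearman(wt[[pr[1L]]], wt[[pr[2L]]])
    data.frame(pair = paste(pr, collapse = "-"), rho = s$rho,
               p_value = s$p_value, n = s$n, strength = s$strength,
               significant = s$p_value < alpha)
  }))
  present <- wt$tandem > 0L
  assert_that(any(present) && any(!present),
              "need both tandem-present and tandem-absent windows")
  mwu <- list(
    indel = mann_whitney(wt$indel[present], wt$indel[!present]),
    snp = mann_whitney(wt$snp[present], wt$snp[!present]))
  list(correlations = cors, mann_whitney = mwu, alpha = alpha,
       note = "p-values are unadjusted (no multiple-testing correction)")
}
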