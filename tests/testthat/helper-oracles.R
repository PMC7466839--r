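# Brute-force reference implementations used as oracles. Deliberately written
# as plain loops over characters / diagonals / permutations, independent of
# the package's vectorized and seed-based detectors.

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
comp1 <- function(x) chartr("ACGTN", "TGCAN", x)

# ---- SSR oracle -----------------------------------------------------------

oracle_primitive <- function(motif) {
  k <- nchar(motif)
  if (k == 1L) return(TRUE)
  for (p in seq_len(k - 1L)) {
    if (k %% p == 0L) {
      rep_m <- paste(rep(substring(motif, 1L, p), k / p), collapse = "")
      if (rep_m == motif) return(FALSE)
    }
  }
  TRUE
}

oracle_canonical <- function(motif) {
  k <- nchar(motif)
  best <- motif
  for (i in seq_len(k)) {
    r <- paste0(substring(motif, i, k), substring(motif, 1L, i - 1L))
    if (r < best) best <- r
  }
  best
}

oracle_simple_ssrs <- function(seq, minima = c(10L, 6L, 5L, 5L, 5L, 5L)) {
  ch <- chars(seq)
  n <- length(ch)
  hits <- NULL
  for (k in 1:6) {
    a <- 1L
    while (a + 2L * k - 1L <= n) {
      # maximal run of period k starting at a (left-maximality required)
      left_ok <- a == 1L || ch[a - 1L] == "N" || ch[a - 1L] != ch[a - 1L + k]
      if (!left_ok || ch[a] == "N") { a <- a + 1L; next }
      e <- a
      while (e + k <= n && ch[e] != "N" && ch[e + k] != "N" &&
             ch[e] == ch[e + k]) e <- e + 1L
      run <- e - a  # matched period positions
      total <- run + k
      copies <- total %/% k
      motif <- paste(ch[a:(a + k - 1L)], collapse = "")
      if (run >= k && copies >= minima[k] && oracle_primitive(motif)) {
        hits <- rbind(hits, data.frame(
          motif = if (k == 1L) motif else oracle_canonical(motif),
          start = a, end = a + copies * k - 1L, copies = copies,
          ssr_class = paste0("p", k)))
      }
      a <- a + 1L
    }
  }
  if (is.null(hits)) {
    return(data.frame(motif = character(), start = integer(),
                      end = integer(), copies = numeric(),
                      ssr_class = character()))
  }
  hits[order(hits$start, hits$end), , drop = FALSE]
}

# ---- tandem oracle --------------------------------------------------------

oracle_consensus_identity <- function(ch, s, e, u) {
  len <- e - s + 1L
  matches <- 0L
  unit <- character(u)
  for (p in 0:(u - 1L)) {
    col <- ch[seq(s + p, e, by = u)]
    col <- col[col != "N"]
    if (length(col) == 0L) { unit[p + 1L] <- "A"; next }
    best_b <- "Z"; best_c <- -1L
    for (b in c("A", "C", "G", "T")) {
      cb <- sum(col == b)
      if (cb > best_c) { best_c <- cb; best_b <- b }
    }
    unit[p + 1L] <- best_b
    matches <- matches + best_c
  }
  list(unit = paste(unit, collapse = ""), identity = 100 * matches / len,
       matches = matches)
}

oracle_tandems <- function(seq, unit_min, unit_max, min_identity = 85,
                           min_copies = 2) {
  ch <- chars(seq)
  n <- length(ch)
  cand <- NULL
  for (u in unit_min:min(unit_max, floor(n / min_copies))) {
    m <- logical(n - u)
    for (i in seq_len(n - u)) m[i] <- ch[i] != "N" && ch[i] == ch[i + u]
    g <- min(u, 3L)
    i <- 1L
    while (i <= length(m)) {
      if (!m[i]) { i <- i + 1L; next }
      # collect the TRUE runs of one segment (no >= g FALSE run inside)
      runs <- NULL
      j <- i
      cur_start <- i; cur_end <- i; fr <- 0L
      while (j < length(m)) {
        j <- j + 1L
        if (m[j]) {
          if (fr > 0L) { runs <- rbind(runs, c(cur_start, cur_end));
            cur_start <- j }
          cur_end <- j; fr <- 0L
        } else {
          fr <- fr + 1L
          if (fr >= g) break
        }
      }
      runs <- rbind(runs, c(cur_start, cur_end))
      i <- j + 1L
      # terminal-run trimming until the consensus identity passes
      ci <- NULL
      repeat {
        s0 <- runs[1L, 1L]; e0 <- runs[nrow(runs), 2L] + u
        if (e0 - s0 + 1L < min_copies * u) { ci <- NULL; break }
        ci <- oracle_consensus_identity(ch, s0, e0, u)
        if (ci$identity >= min_identity) break
        if (nrow(runs) == 1L) { ci <- NULL; break }
        lf <- runs[1L, 2L] - runs[1L, 1L] + 1L
        ll <- runs[nrow(runs), 2L] - runs[nrow(runs), 1L] + 1L
        runs <- if (lf < ll) runs[-1L, , drop = FALSE] else
          runs[-nrow(runs), , drop = FALSE]
        ci <- NULL
      }
      if (is.null(ci)) next
      cand <- rbind(cand, data.frame(
        unit = ci$unit, unit_len = u, start = s0, end = e0,
        copies = (e0 - s0 + 1L) / u, identity = ci$identity,
        score = ci$matches))
    }
  }
  if (is.null(cand)) {
    return(data.frame(unit = character(), unit_len = integer(),
                      start = integer(), end = integer(), copies = numeric(),
                      identity = numeric()))
  }
  ord <- order(-cand$score, cand$unit_len, cand$start)
  occupied <- logical(n)
  keep <- logical(nrow(cand))
  for (q in ord) {
    span <- cand$start[q]:cand$end[q]
    if (!any(occupied[span])) { keep[q] <- TRUE; occupied[span] <- TRUE }
  }
  out <- cand[keep, setdiff(names(cand), "score"), drop = FALSE]
  out <- out[order(out$start), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# ---- dispersed-repeat oracle ---------------------------------------------

# maximal <=B-mismatch windows along every diagonal of a vs b, len >= min_len
oracle_diag_windows <- function(ca, cb, min_len, B) {
  na <- length(ca); nb <- length(cb)
  out <- NULL
  for (d in (1L - na):(nb - 1L)) {
    lo <- max(1L, 1L - d); hi <- min(na, nb - d)
    if (hi - lo + 1L < min_len) next
    va <- ca[lo:hi]; vb <- cb[(lo + d):(hi + d)]
    mm <- lo - 1L + which(va != vb | va == "N" | vb == "N")
    mmx <- c(lo - 1L, mm, hi + 1L)
    nmm <- length(mm)
    for (i in seq_len(max(0L, nmm - B + 1L) + B)) {
      if (i + B + 1L > length(mmx)) break
      ws <- mmx[i] + 1L
      we <- mmx[i + B + 1L] - 1L
      if (we - ws + 1L >= min_len) {
        used <- sum(mm >= ws & mm <= we)
        out <- rbind(out, data.frame(ta = ws, tb = ws + d,
                                     len = we - ws + 1L, mm = used))
      }
    }
    if (nmm <= B) {
      if (hi - lo + 1L >= min_len) {
        out <- rbind(out, data.frame(ta = lo, tb = lo + d,
                                     len = hi - lo + 1L, mm = nmm))
      }
    }
  }
  unique(out)
}

oracle_dispersed <- function(seq, min_len = 21L, max_hamming = 2L) {
  ch <- chars(seq)
  n <- length(ch)
  rev_ch <- rev(ch)
  com_ch <- comp1(ch)
  rc_ch <- rev(com_ch)
  res <- NULL
  for (kind in c("forward", "palindromic", "reverse", "complement")) {
    cb <- switch(kind, forward = ch, palindromic = rc_ch, reverse = rev_ch,
                 complement = com_ch)
    w <- oracle_diag_windows(ch, cb, min_len, max_hamming)
    if (is.null(w) || nrow(w) == 0L) next
    if (kind == "forward") w <- w[w$ta != w$tb, , drop = FALSE]
    p2 <- switch(kind,
                 forward = w$tb,
                 palindromic = n - (w$tb + w$len - 1L) + 1L,
                 reverse = n - (w$tb + w$len - 1L) + 1L,
                 complement = w$tb)
    lo <- pmin(w$ta, p2); hi <- pmax(w$ta, p2)
    keep <- lo + w$len - 1L < hi
    if (!any(keep)) next
    res <- rbind(res, unique(data.frame(kind = kind, len = w$len[keep],
                                        pos1 = lo[keep], pos2 = hi[keep],
                                        mismatches = w$mm[keep])))
  }
  if (is.null(res)) {
    return(data.frame(kind = character(), len = integer(), pos1 = integer(),
                      pos2 = integer(), mismatches = integer()))
  }
  prio <- match(res$kind, c("forward", "palindromic", "reverse", "complement"))
  res <- res[order(res$pos1, res$pos2, res$len, prio), , drop = FALSE]
  res <- res[!duplicated(res[, c("pos1", "pos2", "len")]), , drop = FALSE]
  res <- res[order(res$pos1, res$pos2), , drop = FALSE]
  rownames(res) <- NULL
  res
}

# longest exact inverted pair via all-diagonal scan (IR oracle)
oracle_max_inverted <- function(seq, min_len) {
  ch <- chars(seq)
  n <- length(ch)
  rc_ch <- rev(comp1(ch))
  best <- NULL
  for (d in (1L - n):(n - 1L)) {
    lo <- max(1L, 1L - d); hi <- min(n, n - d)
    if (hi - lo + 1L < min_len) next
    va <- ch[lo:hi]; vb <- rc_ch[(lo + d):(hi + d)]
    eq <- va == vb & va != "N"
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    for (q in which(r$values & r$lengths >= min_len)) {
      run <- r$lengths[q]
      ws <- lo - 1L + ends[q] - run + 1L
      s2 <- n - (ws + d + run - 1L) + 1L
      p1 <- min(ws, s2); p2 <- max(ws, s2)
      if (p1 + run - 1L < p2 && (is.null(best) || run > best$len)) {
        best <- list(s1 = p1, s2 = p2, len = run)
      }
    }
  }
  best
}

# ---- alignment score oracle (Gotoh affine DP) -----------------------------

oracle_align_score <- function(a, b, match = 1, mism = -2, go = 5, ge = 2) {
  ca <- chars(a); cb <- chars(b)
  n <- length(ca); m <- length(cb)
  NEG <- -1e9
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in b (consume a)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in a (consume b)
  M[1L, 1L] <- 0
  for (i in 2L:(n + 1L)) X[i, 1L] <- -go - ge * (i - 1L)
  for (j in 2L:(m + 1L)) Y[1L, j] <- -go - ge * (j - 1L)
  for (i in 2L:(n + 1L)) {
    for (j in 2L:(m + 1L)) {
      sc <- if (ca[i - 1L] == cb[j - 1L] && ca[i - 1L] != "N") match else mism
      M[i, j] <- max(M[i - 1L, j - 1L], X[i - 1L, j - 1L],
                     Y[i - 1L, j - 1L]) + sc
      X[i, j] <- max(M[i - 1L, j] - go - ge, X[i - 1L, j] - ge,
                     Y[i - 1L, j] - go - ge)
      Y[i, j] <- max(M[i, j - 1L] - go - ge, Y[i, j - 1L] - ge,
                     X[i, j - 1L] - go - ge)
    }
  }
  max(M[n + 1L, m + 1L], X[n + 1L, m + 1L], Y[n + 1L, m + 1L])
}

score_alignment <- function(ra, qa, match = 1, mism = -2, go = 5, ge = 2) {
  rc <- chars(ra); qc <- chars(qa)
  sc <- 0
  in_gap <- FALSE
  for (t in seq_along(rc)) {
    if (rc[t] == "-" || qc[t] == "-") {
      sc <- sc - ge - (if (in_gap) 0 else go)
      in_gap <- TRUE
    } else {
      sc <- sc + if (rc[t] == qc[t] && rc[t] != "N") match else mism
      in_gap <- FALSE
    }
  }
  sc
}

# ---- exact permutation oracles -------------------------------------------

all_perms <- function(n) {
  if (n == 1L) return(matrix(1L, 1L, 1L))
  sub <- all_perms(n - 1L)
  out <- NULL
  for (k in seq_len(n)) {
    block <- cbind(k, sub + (sub >= k))
    out <- rbind(out, block)
  }
  out
}

oracle_spearman_exact <- function(x, y) {
  n <- length(x)
  rx <- rank(x); ry <- rank(y)
  rho_obs <- suppressWarnings(cor(rx, ry))
  pm <- all_perms(n)
  # |rho| ordering equals |S - mu| ordering, S = sum(rx * ry[perm])
  ryp <- matrix(ry[pm], nrow(pm), n)
  S <- as.vector(ryp %*% rx)
  mu <- sum(rx) * sum(ry) / n
  s_obs <- sum(rx * ry)
  list(rho = rho_obs,
       p = mean(abs(S - mu) >= abs(s_obs - mu) - 1e-9))
}

oracle_mwu_exact <- function(g1, g2) {
  n1 <- length(g1); n2 <- length(g2)
  vals <- c(g1, g2)
  r <- rank(vals)
  U_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  cmb <- combn(n1 + n2, n1)
  devs <- numeric(ncol(cmb))
  for (q in seq_len(ncol(cmb))) {
    devs[q] <- abs(sum(r[cmb[, q]]) - n1 * (n1 + 1) / 2 - mu)
  }
  list(U = U_obs, p = mean(devs >= abs(U_obs - mu) - 1e-9))
}

# ---- NG86 single-codon oracle (translation via seqinr) --------------------

oracle_translate <- function(codon) {
  seqinr::translate(strsplit(codon, "")[[1L]], numcode = 11)
}

oracle_syn_sites <- function(codon) {
  aa0 <- oracle_translate(codon)
  s <- 0
  for (pos in 1:3) {
    for (nb in c("A", "C", "G", "T")) {
      if (nb == substring(codon, pos, pos)) next
      mut <- codon
      substring(mut, pos, pos) <- nb
      aam <- oracle_translate(mut)
      if (aam != "*" && aam == aa0) s <- s + 1 / 3
    }
  }
  s
}

oracle_pair_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1L]] != strsplit(c2, "")[[1L]])
  if (length(pos) == 0L) return(c(sd = 0, nd = 0))
  pm <- all_perms(length(pos))
  res <- NULL
  for (q in seq_len(nrow(pm))) {
    cur <- c1; sd <- 0; nd <- 0; okpath <- TRUE
    for (p in pos[pm[q, ]]) {
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      if (oracle_translate(nxt) == "*") { okpath <- FALSE; break }
      if (oracle_translate(nxt) == oracle_translate(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    if (okpath) res <- rbind(res, c(sd = sd, nd = nd))
  }
  if (is.null(res)) return(c(sd = 0, nd = length(pos)))
  colMeans(res)
}

oracle_ng86 <- function(a, b) {
  ca <- substring(a, seq(1, nchar(a), 3), seq(3, nchar(a), 3))
  cb <- substring(b, seq(1, nchar(b), 3), seq(3, nchar(b), 3))
  S <- 0; Nn <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (oracle_syn_sites(ca[i]) + oracle_syn_sites(cb[i])) / 2
    Nn <- Nn + 3 - (oracle_syn_sites(ca[i]) + oracle_syn_sites(cb[i])) / 2
    d <- oracle_pair_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]; Nd <- Nd + d[["nd"]]
  }
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  pn <- if (Nn > 0) Nd / Nn else 0
  ps <- if (S > 0) Sd / S else 0
  list(s_sites = S, n_sites = Nn, sd = Sd, nd = Nd, pn = pn, ps = ps,
       ka = jc(pn), ks = jc(ps))
}

# ---- Pi oracle ------------------------------------------------------------

oracle_pi <- function(seqs) {
  n <- length(seqs)
  rows <- lapply(seqs, chars)
  tot <- 0
  for (i in 1:(n - 1L)) {
    for (j in (i + 1L):n) {
      d <- 0L; l <- 0L
      for (t in seq_along(rows[[i]])) {
        a <- rows[[i]][t]; b <- rows[[j]][t]
        if (a == "-" || b == "-" || a == "N" || b == "N") next
        l <- l + 1L
        if (a != b) d <- d + 1L
      }
      tot <- tot + d / l
    }
  }
  2 / (n * (n - 1)) * tot
}

# ---- random sequences -----------------------------------------------------

rand_dna <- function(n, gc = 0.5) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE,
               prob = c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)),
        collapse = "")
}
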