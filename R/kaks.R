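#' Nei-Gojobori (1986) Ka/Ks for a pair of coding sequences
#'
#' Unweighted pathway counting with Jukes-Cantor correction: synonymous and
#' nonsynonymous site counts are computed per codon (a position contributes
#' the fraction of its three possible changes that are synonymous; changes
#' creating a stop codon count as nonsynonymous) and averaged over the two
#' sequences; codon pairs differing at d positions average the synonymous /
#' nonsynonymous step classification over all d! minimal substitution
#' pathways, excluding pathways that pass through a stop codon (if every
#' pathway is blocked, all steps count as nonsynonymous). pN and pS receive
#' the Jukes-Cantor correction -(3/4) log(1 - 4p/3); `ka`/`ks` are NA where
#' the correction is undefined (p >= 3/4). The plastid genetic code
#' (translation table 11, identical codon assignments to the standard table)
#' is used.
#'
#' Codon pairs containing an ambiguous base (N) are excluded. A shared
#' terminal stop codon is trimmed; an internal stop is an error naming the
#' codon position.
#'
#' @param cdsA,cdsB in-frame coding sequences (lengths equal after trimming
#'   incomplete terminal codons)
#' @return list: ka, ks, ratio (NA when ks is 0 or NA), pn, ps, n_sites,
#'   s_sites, nd, sd, codons
#' @export
kaks_ng86 <- function(cdsA, cdsB) {
  a <- trim_to_codons(toupper(cdsA))
  b <- trim_to_codons(toupper(cdsB))
  if (nchar(a) != nchar(b)) {
    stop("CDS length mismatch after codon trimming: ", nchar(a), " vs ",
         nchar(b), call. = FALSE)
  }
  ca <- codon_split(a)
  cb <- codon_split(b)
  nc <- length(ca)
  # trim one shared terminal stop codon
  if (nc > 0L && is_stop(ca[nc]) && is_stop(cb[nc])) {
    ca <- ca[-nc]; cb <- cb[-nc]; nc <- nc - 1L
  }
  st_a <- which(is_stop(ca)); st_b <- which(is_stop(cb))
  if (length(st_a)) stop("internal stop codon in first CDS at codon ",
                         st_a[1L], call. = FALSE)
  if (length(st_b)) stop("internal stop codon in second CDS at codon ",
                         st_b[1L], call. = FALSE)
  clean <- !grepl("N", ca, fixed = TRUE) & !grepl("N", cb, fixed = TRUE)
  ca <- ca[clean]; cb <- cb[clean]
  S <- 0; Nn <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(ca)) {
    S <- S + (syn_sites(ca[i]) + syn_sites(cb[i])) / 2
    Nn <- Nn + (3 - syn_sites(ca[i]) + 3 - syn_sites(cb[i])) / 2
    d <- codon_pair_diffs(ca[i], cb[i])
    Sd <- Sd + d[["sd"]]
    Nd <- Nd + d[["nd"]]
  }
  pn <- if (Nn > 0) Nd / Nn else 0
  ps <- if (S > 0) Sd / S else 0
  jc <- function(p) if (p < 0.75) -0.75 * log(1 - 4 * p / 3) else NA_real_
  ka <- jc(pn); ks <- jc(ps)
  ratio <- if (is.na(ks) || is.na(ka) || ks == 0) NA_real_ else ka / ks
  list(ka = ka, ks = ks, ratio = ratio, pn = pn, ps = ps,
       n_sites = Nn, s_sites = S, nd = Nd, sd = Sd, codons = length(ca))
}

trim_to_codons <- function(x) substring(x, 1L, 3L * (nchar(x) %/% 3L))

codon_split <- function(x) {
  n <- nchar(x) %/% 3L
  if (n == 0L) return(character())
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

translate_codon <- function(codon) {
  aa <- Biostrings::GENETIC_CODE[codon]
  ifelse(is.na(aa), "X", aa)
}

is_stop <- function(codon) translate_codon(codon) == "*"

# synonymous site count of one codon: per position, the fraction of the
# three alternative bases whose change is synonymous (stop targets count as
# nonsynonymous); memoized over the 64 codons
.ng86_cache <- new.env(parent = emptyenv())

syn_sites <- function(codon) {
  hit <- .ng86_cache[[codon]]
  if (!is.null(hit)) return(hit)
  aa0 <- translate_codon(codon)
  s <- 0
  for (pos in 1:3) {
    for (nb in setdiff(DNA_BASES, substring(codon, pos, pos))) {
      mut <- codon
      substring(mut, pos, pos) <- nb
      if (!is_stop(mut) && translate_codon(mut) == aa0) s <- s + 1 / 3
    }
  }
  .ng86_cache[[codon]] <- s
  s
}

# average synonymous/nonsynonymous difference counts over all minimal
# substitution pathways between two codons, excluding pathways through stops;
# memoized per ordered codon pair
codon_pair_diffs <- function(c1, c2) {
  key <- paste0(c1, c2)
  hit <- .ng86_cache[[key]]
  if (!is.null(hit)) return(hit)
  out <- codon_pair_diffs_raw(c1, c2)
  .ng86_cache[[key]] <- out
  out
}

codon_pair_diffs_raw <- function(c1, c2) {
  pos <- which(seq_chars(c1) != seq_chars(c2))
  d <- length(pos)
  if (d == 0L) return(c(sd = 0, nd = 0))
  perms <- list(pos)
  if (d == 2L) perms <- list(pos, rev(pos))
  if (d == 3L) {
    perms <- lapply(list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3), c(2, 3, 1),
                         c(3, 1, 2), c(3, 2, 1)), function(o) pos[o])
  }
  path_counts <- function(order_) {
    cur <- c1
    sd <- 0; nd <- 0
    for (p in order_) {
      nxt <- cur
      substring(nxt, p, p) <- substring(c2, p, p)
      if (is_stop(nxt)) return(NULL) # pathway through a stop codon
      if (translate_codon(nxt) == translate_codon(cur)) sd <- sd + 1
      else nd <- nd + 1
      cur <- nxt
    }
    c(sd = sd, nd = nd)
  }
  res <- Filter(Negate(is.null), lapply(perms, path_counts))
  if (length(res) == 0L) return(c(sd = 0, nd = d)) # all blocked: nonsynonymous
  colMeans(do.call(rbind, res))
}
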