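#' Count codons over a set of coding sequences
#'
#' Every annotated CDS instance is counted (so genes duplicated in the IRs
#' contribute per occurrence), stop codons included. The reading frame
#' honors `codon_start` when a [plastome()] is given. A CDS whose length is
#' not a multiple of 3 raises a warning and its trailing partial codon is
#' dropped. Codons containing N are ignored.
#'
#' @param x a [plastome()] (its CDS features are extracted and oriented) or
#'   a character vector of in-frame CDS sequences
#' @return a `codon_table`: named 64-codon count vector (DNA alphabet) and
#'   total
#' @export
count_codons <- function(x) {
  cds <- if (inherits(x, "plastome")) cds_sequences(x) else toupper(x)
  codons <- character()
  for (s in cds) {
    if (nchar(s) %% 3L != 0L) {
      warning("CDS length not a multiple of 3; dropping trailing partial codon")
      s <- trim_to_codons(s)
    }
    codons <- c(codons, codon_split(s))
  }
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  counts <- table(factor(codons, levels = all_codons()))
  structure(list(counts = setNames(as.integer(counts), names(counts)),
                 total = length(codons), genetic_code = "11 (plastid)"),
            class = "codon_table")
}

#' @export
print.codon_table <- function(x, ...) {
  cat(sprintf("<codon_table> %d codons, genetic code %s\n", x$total,
              x$genetic_code))
  invisible(x)
}

all_codons <- function() {
  g <- expand.grid(b3 = DNA_BASES, b2 = DNA_BASES, b1 = DNA_BASES,
                   stringsAsFactors = FALSE)
  paste0(g$b1, g$b2, g$b3)
}

# oriented CDS sequences of a plastome, codon_start honored
cds_sequences <- function(p) {
  cds <- Filter(function(f) f$kind == "CDS", p$features)
  vapply(cds, function(f) {
    s <- feature_sequence(p, f)
    substring(s, f$codon_start, nchar(s))
  }, character(1L))
}

#' Relative synonymous codon usage (RSCU)
#'
#' RSCU of a codon is its count divided by the mean count of its synonymous
#' family; families follow genetic code 11 and the three stop codons form
#' one family (the CodonW convention). Single-codon families (AUG, UGG) have
#' RSCU identically 1. A family with zero total count gets RSCU 0 for all
#' members and is flagged. Codons are reported in the RNA alphabet.
#'
#' @param ct a `codon_table` from [count_codons()]
#' @return data.frame: codon (RNA), aa, count, rscu, ending ("A/U" or
#'   "C/G"), empty_family
#' @export
rscu <- function(ct) {
  stopifnot(inherits(ct, "codon_table"))
  assert_that(ct$total > 0L, "empty codon table")
  codons <- all_codons()
  aa <- translate_codon(codons)
  counts <- ct$counts[codons]
  fam_mean <- tapply(counts, aa, mean)[aa]
  vals <- ifelse(fam_mean > 0, counts / fam_mean, 0)
  third <- substring(codons, 3L, 3L)
  out <- data.frame(codon = chartr("T", "U", codons), aa = aa,
                    count = as.integer(counts), rscu = as.numeric(vals),
                    ending = ifelse(third %in% c("A", "T"), "A/U", "C/G"),
                    empty_family = as.vector(fam_mean[aa] == 0))
  single <- names(table(aa))[table(aa) == 1L]
  out$rscu[out$aa %in% single & !out$empty_family] <- 1
  rownames(out) <- NULL
  out
}

#' Base composition by codon position
#'
#' AT% and GC% at codon positions 1, 2 and 3 across a CDS set:
#' AT% at position k = 100 * (#A + #T at position k) / total codons.
#'
#' @param x a [plastome()] or character vector of in-frame CDS sequences
#' @return data.frame: position, at_percent, gc_percent
#' @export
positional_composition <- function(x) {
  cds <- if (inherits(x, "plastome")) cds_sequences(x) else toupper(x)
  codons <- unlist(lapply(cds, function(s) codon_split(trim_to_codons(s))),
                   use.names = FALSE)
  codons <- codons[!grepl("N", codons, fixed = TRUE)]
  assert_that(length(codons) > 0L, "no complete codons")
  do.call(rbind, lapply(1:3, function(k) {
    bk <- substring(codons, k, k)
    data.frame(position = k,
               at_percent = round_half_up(100 * mean(bk %in% c("A", "T")), 2L),
               gc_percent = round_half_up(100 * mean(bk %in% c("G", "C")), 2L))
  }))
}

#' Amino-acid usage percentages
#'
#' Percent of total codons per amino-acid family; stop codons are one row
#' labeled "*". Percentages sum to 100.
#' @param ct a `codon_table`
#' @return data.frame: aa, count, percent
#' @export
amino_acid_usage <- function(ct) {
  stopifnot(inherits(ct, "codon_table"))
  assert_that(ct$total > 0L, "empty codon table")
  codons <- all_codons()
  aa <- translate_codon(codons)
  fam <- tapply(ct$counts[codons], aa, sum)
  out <- data.frame(aa = names(fam), count = as.integer(fam),
                    percent = 100 * as.numeric(fam) / ct$total)
  rownames(out) <- NULL
  out[order(-out$percent, out$aa), ]
}
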