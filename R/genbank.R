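#' Read a GenBank flat-file into a Plastome
#'
#' Parses LOCUS, the FEATURES table and the ORIGIN sequence of a single-record
#' GenBank flat-file. Captured feature kinds: gene, CDS, tRNA, rRNA, intron,
#' exon. Compound locations (`join(...)`, `order(...)`, `complement(...)`) are
#' preserved part-by-part; `order()` joins across the genome mark the feature
#' trans-spliced, as do explicit `/trans_splicing` qualifiers. `/codon_start`
#' is honored. The sequence is upper-cased.
#'
#' @param path path to a GenBank flat-file with an ORIGIN section
#' @return a [plastome()]
#' @export
read_genbank <- function(path) {
  assert_that(file.exists(path), paste0("no such file: ", path))
  lines <- readLines(path, warn = FALSE)

  locus <- grep("^LOCUS", lines, value = TRUE)
  id <- if (length(locus)) strsplit(trimws(locus[1L]), "[ \t]+")[[1L]][2L] else
    sub("\\.[^.]*$", "", basename(path))
  circular <- length(locus) > 0L && grepl("circular", locus[1L], ignore.case = TRUE)

  ori <- grep("^ORIGIN", lines)
  if (length(ori) == 0L) stop("GenBank parse error: no ORIGIN sequence", call. = FALSE)
  endrec <- grep("^//", lines)
  endrec <- if (length(endrec)) endrec[endrec > ori[1L]][1L] else length(lines) + 1L
  seq_lines <- lines[(ori[1L] + 1L):(endrec - 1L)]
  sequence <- toupper(gsub("[^A-Za-z]", "", paste(seq_lines, collapse = "")))
  if (nchar(sequence) == 0L) stop("GenBank parse error: empty ORIGIN sequence",
                                  call. = FALSE)

  feat_start <- grep("^FEATURES", lines)
  features <- list()
  if (length(feat_start)) {
    block <- lines[(feat_start[1L] + 1L):(ori[1L] - 1L)]
    # a feature line has a key in columns 6-20; qualifier/continuation lines
    # start at column 22
    is_key <- grepl("^ {5}\\S", block)
    idx <- which(is_key)
    for (h in seq_along(idx)) {
      first <- idx[h]
      last <- if (h < length(idx)) idx[h + 1L] - 1L else length(block)
      key <- sub("^ {5}(\\S+).*", "\\1", block[first])
      if (!key %in% c("gene", "CDS", "tRNA", "rRNA", "intron", "exon")) next
      body <- paste(trimws(block[first:last]), collapse = "\n")
      # location possibly wrapped over lines before the first qualifier
      loc_lines <- character()
      for (ln in block[first:last]) {
        t <- trimws(ln)
        if (ln != block[first] && startsWith(t, "/")) break
        loc_lines <- c(loc_lines, if (ln == block[first])
          sub("^\\S+\\s+", "", t) else t)
      }
      loc <- gsub("[ \t]", "", paste(loc_lines, collapse = ""))
      parsed <- parse_gb_location(loc)
      name <- gb_qualifier(body, "gene") %||% gb_qualifier(body, "locus_tag") %||%
        paste0(key, "_", h)
      cs <- gb_qualifier(body, "codon_start")
      kind <- if (key == "gene") "gene" else key
      f <- feature(name, kind, parsed$strand, parsed$parts,
                   trans_spliced = parsed$trans_spliced ||
                     grepl("/trans_splicing", body, fixed = TRUE),
                   codon_start = if (is.null(cs)) 1L else as.integer(cs))
      if (any(f$parts[, 2L] > nchar(sequence)) || any(f$parts[, 1L] < 1L)) {
        stop(sprintf("feature '%s' (%s) lies outside the sequence [1, %d]",
                     name, loc, nchar(sequence)), call. = FALSE)
      }
      features <- c(features, list(f))
    }
  }
  plastome(id, sequence, circular, features)
}

# parse a GenBank location string into strand + part matrix
parse_gb_location <- function(loc) {
  strand <- "+"
  trans <- grepl("order(", loc, fixed = TRUE)
  x <- loc
  if (startsWith(x, "complement(")) {
    strand <- "-"
    x <- sub("^complement\\((.*)\\)$", "\\1", x)
  }
  x <- sub("^(join|order)\\((.*)\\)$", "\\2", x)
  parts_txt <- strsplit(x, ",", fixed = TRUE)[[1L]]
  parts <- t(vapply(parts_txt, function(pt) {
    neg <- startsWith(pt, "complement(")
    pt <- sub("^complement\\((.*)\\)$", "\\1", pt)
    pt <- gsub("[<>]", "", pt)
    nums <- as.integer(strsplit(pt, "\\.\\.")[[1L]])
    if (length(nums) == 1L) nums <- c(nums, nums)
    if (neg) nums <- c(nums, -1L) else nums <- c(nums, 1L)
    nums
  }, integer(3L)))
  if (all(parts[, 3L] == -1L)) strand <- "-"
  list(strand = strand, parts = parts[, 1:2, drop = FALSE],
       trans_spliced = trans)
}

gb_qualifier <- function(body, what) {
  m <- regmatches(body, regexpr(sprintf('/%s=("[^"]*"|\\S+)', what), body))
  if (length(m) == 0L) return(NULL)
  gsub('"', "", sub(sprintf("/%s=", what), "", m))
}

#' Write a Plastome as a minimal GenBank flat-file
#'
#' Emits LOCUS, a FEATURES table (gene/CDS/tRNA/rRNA with joins and
#' complements) and the ORIGIN sequence in 60-column blocks. Intended for the
#' synthetic fixture suite; round-trips through [read_genbank()].
#' @param p a [plastome()]
#' @param path output path
#' @return path, invisibly
#' @export
write_genbank <- function(p, path) {
  stopifnot(inherits(p, "plastome"))
  n <- nchar(p$sequence)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("LOCUS       %s %d bp    DNA     %s PLN",
                     p$id, n, if (p$circular) "circular" else "linear"), con)
  writeLines("FEATURES             Location/Qualifiers", con)
  writeLines(sprintf("     source          1..%d", n), con)
  for (f in p$features) {
    segs <- sprintf("%d..%d", f$parts[, 1L], f$parts[, 2L])
    loc <- if (length(segs) > 1L)
      sprintf("%s(%s)", if (f$trans_spliced) "order" else "join",
              paste(segs, collapse = ",")) else segs
    if (f$strand == "-") loc <- sprintf("complement(%s)", loc)
    writeLines(sprintf("     %-15s %s", f$kind, loc), con)
    writeLines(sprintf('                     /gene="%s"', f$name), con)
    if (f$kind == "CDS" && f$codon_start != 1L)
      writeLines(sprintf("                     /codon_start=%d", f$codon_start), con)
    if (f$trans_spliced)
      writeLines("                     /trans_splicing", con)
  }
  writeLines("ORIGIN", con)
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    chunk <- substring(p$sequence, s, min(s + 59L, n))
    tens <- substring(chunk, seq(1L, nchar(chunk), 10L),
                      pmin(seq(10L, nchar(chunk) + 9L, 10L), nchar(chunk)))
    writeLines(sprintf("%9d %s", s, tolower(paste(tens, collapse = " "))), con)
  }
  writeLines("//", con)
  invisible(path)
}

#' Read/write FASTA
#'
#' Thin wrappers over Biostrings for plain (uncompressed) FASTA.
#' @param path FASTA path
#' @return named character vector of upper-case sequences
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(toupper(as.character(x)), names(x))
}

#' @param seqs named character vector
#' @rdname read_fasta
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), path)
  invisible(path)
}
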