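#' Write located elements as a BED or TSV track
#'
#' Internal coordinates are 1-based inclusive (GenBank convention). BED output
#' converts to 0-based half-open; TSV keeps 1-based inclusive coordinates and
#' documents its columns in a header line.
#'
#' @param items data.frame with at least `start` and `end` (1-based
#'   inclusive); other columns are carried into the name/extra fields
#' @param path output path
#' @param format "BED" or "TSV"
#' @param chrom chromosome/sequence label for BED output
#' @return path, invisibly
#' @export
write_tracks <- function(items, path, format = c("TSV", "BED"),
                         chrom = "plastome") {
  format <- match.arg(format)
  stopifnot(is.data.frame(items))
  located <- all(c("start", "end") %in% names(items))
  if (format == "BED") {
    stopifnot(located)
  }
  if (nrow(items) > 0L && located) {
    stopifnot(all(items$start >= 1L), all(items$end >= items$start))
  }
  con <- tryCatch(file(path, "w"), error = function(e)
    stop(paste0("cannot write track file: ", path), call. = FALSE))
  on.exit(close(con))
  if (format == "BED") {
    writeLines(sprintf('track name="%s" description="0-based half-open"',
                       chrom), con)
    if (nrow(items) > 0L) {
      name <- if ("name" %in% names(items)) items$name else
        sprintf("item%d", seq_len(nrow(items)))
      writeLines(sprintf("%s\t%d\t%d\t%s", chrom, items$start - 1L,
                         items$end, name), con)
    }
  } else {
    writeLines(paste0("# 1-based inclusive coordinates; columns: ",
                      paste(names(items), collapse = ", ")), con)
    writeLines(paste(names(items), collapse = "\t"), con)
    if (nrow(items) > 0L) {
      write.table(items, con, sep = "\t", quote = FALSE, row.names = FALSE,
                  col.names = FALSE)
    }
  }
  invisible(path)
}

#' Read a BED track back into 1-based inclusive coordinates
#' @param path BED path written by [write_tracks()]
#' @return data.frame: chrom, start, end (1-based inclusive), name
#' @export
read_bed_track <- function(path) {
  lines <- readLines(path)
  lines <- lines[!startsWith(lines, "track") & nzchar(lines)]
  if (length(lines) == 0L) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), name = character()))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  data.frame(chrom = vapply(parts, `[[`, character(1L), 1L),
             start = as.integer(vapply(parts, `[[`, character(1L), 2L)) + 1L,
             end = as.integer(vapply(parts, `[[`, character(1L), 3L)),
             name = vapply(parts, function(x) if (length(x) >= 4L) x[[4L]]
                           else NA_character_, character(1L)))
}
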