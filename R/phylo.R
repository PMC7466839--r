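#' Project reference-anchored pairwise alignments onto a common matrix
#'
#' Builds a pseudo-multiple alignment on reference coordinates from a list
#' of pairwise alignments against one shared reference: each query
#' contributes its base (or "-" for a deletion) at every reference position;
#' insertions relative to the reference are dropped. This is the usual
#' reference-projection used for whole-genome distance estimation between
#' collinear genomes.
#'
#' @param alns list of `pairwise_alignment` objects sharing the same
#'   reference
#' @return named character vector: reference row plus one row per query,
#'   all of reference length
#' @export
project_to_reference <- function(alns) {
  assert_that(length(alns) >= 1L, "need at least one alignment")
  ref_ids <- vapply(alns, `[[`, character(1L), "ref_id")
  assert_that(length(unique(ref_ids)) == 1L,
              "all alignments must share one reference")
  rs <- gsub("-", "", alns[[1L]]$ref_aln, fixed = TRUE)
  rows <- c(setNames(list(rs), ref_ids[1L]),
            setNames(lapply(alns, function(a) {
              rc <- seq_chars(a$ref_aln)
              qc <- seq_chars(a$qry_aln)
              paste(qc[rc != "-"], collapse = "")
            }), vapply(alns, `[[`, character(1L), "qry_id")))
  vapply(rows, identity, character(1L))
}

#' Pairwise p-distance matrix from an aligned matrix
#'
#' d_ij = mismatches / gap-free shared columns (pairwise deletion; N
#' excluded too).
#' @param seqs named character vector of >= 3 equal-length aligned rows
#' @return symmetric numeric matrix with zero diagonal
#' @export
p_distance_matrix <- function(seqs) {
  n <- length(seqs)
  assert_that(n >= 3L, "need >= 3 taxa")
  assert_that(length(unique(nchar(seqs))) == 1L, "rows must be equal length")
  ids <- names(seqs) %||% paste0("t", seq_len(n))
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  valid <- m != "-" & m != "N"
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      ok <- valid[i, ] & valid[j, ]
      lij <- sum(ok)
      d[i, j] <- d[j, i] <- if (lij == 0L) NA_real_ else
        sum(m[i, ok] != m[j, ok]) / lij
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei neighbor joining (standard Q-criterion, via ape) on a
#' symmetric distance matrix; taxa are processed in label order so ties
#' break deterministically; negative branch lengths are clamped to zero and
#' flagged.
#'
#' @param d symmetric matrix with zero diagonal
#' @return an [ape::phylo] tree; attribute `clamped` reports how many branch
#'   lengths were negative before clamping
#' @export
nj_tree <- function(d) {
  assert_that(is.matrix(d) && nrow(d) == ncol(d) && nrow(d) >= 3L,
              "need a square matrix with >= 3 taxa")
  if (max(abs(d - t(d))) > 1e-8) stop("distance matrix is not symmetric",
                                      call. = FALSE)
  ord <- order(rownames(d))
  tr <- ape::nj(d[ord, ord])
  clamped <- sum(tr$edge.length < 0)
  tr$edge.length[tr$edge.length < 0] <- 0
  attr(tr, "clamped") <- clamped
  tr
}

#' Write / read Newick
#'
#' Standard Newick with branch lengths; `read_newick(write_newick(t))`
#' restores the tree (topology, labels and lengths).
#' @param t an [ape::phylo] tree
#' @param path output path
#' @return path (writer) / tree (reader)
#' @export
write_newick <- function(t, path) {
  assert_that(inherits(t, "phylo") && length(t$tip.label) > 0L,
              "not a valid non-empty tree")
  ape::write.tree(t, file = path)
  invisible(path)
}

#' @rdname write_newick
#' @export
read_newick <- function(path) ape::read.tree(path)

#' Does a set of taxa form a clade (exclusive group) in an unrooted tree?
#'
#' TRUE when some edge of the unrooted tree separates exactly `taxa` from
#' all other leaves.
#' @param t an [ape::phylo] tree
#' @param taxa character vector of tip labels
#' @return logical
#' @export
is_monophyletic_unrooted <- function(t, taxa) {
  stopifnot(inherits(t, "phylo"))
  if (!all(taxa %in% t$tip.label)) return(FALSE)
  ape::is.monophyletic(t, taxa, reroot = TRUE)
}

#' Column-resampling bootstrap support for an NJ tree
#'
#' Resamples alignment columns with replacement, rebuilds the NJ tree and
#' reports the proportion of replicates in which each original bipartition
#' recurs. Support values are reported for completeness and are not an
#' accepted inference surface.
#' @param seqs aligned rows as for [p_distance_matrix()]
#' @param replicates bootstrap replicate count
#' @return named numeric vector of support values per internal edge, plus
#'   the tree as attribute
#' @export
nj_bootstrap <- function(seqs, replicates = 100L) {
  m <- do.call(rbind, strsplit(seqs, "", fixed = TRUE))
  rownames(m) <- names(seqs)
  base_tree <- nj_tree(p_distance_matrix(seqs))
  reps <- lapply(seq_len(replicates), function(i) {
    cols <- sample.int(ncol(m), ncol(m), replace = TRUE)
    rows <- apply(m[, cols, drop = FALSE], 1L, paste, collapse = "")
    nj_tree(p_distance_matrix(rows))
  })
  pp <- ape::prop.clades(base_tree, reps, rooted = FALSE)
  pp[is.na(pp)] <- 0
  support <- pp / replicates
  attr(support, "tree") <- base_tree
  support
}
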