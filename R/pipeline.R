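#' Run configuration for the full comparative pipeline
#'
#' @param reference [plastome()] or path (GenBank `.gb`/`.gbk` or FASTA)
#' @param queries list of plastomes or paths
#' @param out_dir output directory (created if needed)
#' @param window co-occurrence window width (bp)
#' @param alpha significance level for the association report
#' @param seed seed for any stochastic stage (bootstraps)
#' @param min_ir_len,tandem_unit_min,tandem_unit_max,tandem_identity,
#'   repeat_min_len,max_hamming detector thresholds
#' @return a `run_config`
#' @export
run_config <- function(reference, queries, out_dir, window = 150L,
                       alpha = 0.01, seed = 1L, min_ir_len = 10000L,
                       tandem_unit_min = 7L, tandem_unit_max = 95L,
                       tandem_identity = 85, repeat_min_len = 21L,
                       max_hamming = 2L) {
  for (x in c(list(reference), queries)) {
    if (is.character(x)) assert_that(file.exists(x), paste0("no such file: ", x))
  }
  structure(list(reference = reference, queries = queries, out_dir = out_dir,
                 window = as.integer(window), alpha = alpha,
                 seed = as.integer(seed), min_ir_len = as.integer(min_ir_len),
                 tandem_unit_min = as.integer(tandem_unit_min),
                 tandem_unit_max = as.integer(tandem_unit_max),
                 tandem_identity = tandem_identity,
                 repeat_min_len = as.integer(repeat_min_len),
                 max_hamming = as.integer(max_hamming)),
            class = "run_config")
}

load_genome <- function(x) {
  if (inherits(x, "plastome")) return(x)
  if (grepl("\\.(gb|gbk|genbank)$", x, ignore.case = TRUE)) {
    return(read_genbank(x))
  }
  seqs <- read_fasta(x)
  plastome(names(seqs)[1L], seqs[[1L]])
}

#' Run the whole comparative analysis
#'
#' Executes, in order: quadripartite partition and junction report on the
#' reference; SSR / tandem / dispersed repeat detection and location
#' classification; collinear alignment and variant calling of every query
#' against the reference (events pooled); 150 bp window table and
#' association report (Spearman + Mann-Whitney); per-locus Pi with hotspot
#' ranking; pairwise NG86 Ka/Ks per gene; codon usage (counts, RSCU,
#' positional composition, amino-acid usage); whole-genome p-distances and
#' the NJ tree. All tables are written under `out_dir` with a JSON manifest
#' echoing the configuration. Any stage failure aborts with the stage name;
#' partial outputs are kept next to a FAILED marker.
#'
#' @param cfg a [run_config()]
#' @return invisibly, a list with every stage result and the manifest
#' @export
run_all <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  unlink(file.path(cfg$out_dir, "FAILED"))
  set.seed(cfg$seed)
  files <- character()
  res <- list()
  stage <- function(name, expr) {
    message(sprintf("[%s] stage: %s", format(Sys.time(), "%H:%M:%S"), name))
    tryCatch(expr, error = function(e) {
      writeLines(c(name, conditionMessage(e)),
                 file.path(cfg$out_dir, "FAILED"))
      stop(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
  }
  out <- function(name) {
    path <- file.path(cfg$out_dir, name)
    files <<- c(files, path)
    path
  }
  tsv <- function(df, name) {
    write_tracks(df, out(name), "TSV")
  }

  ref <- stage("load", load_genome(cfg$reference))
  queries <- stage("load", lapply(cfg$queries, load_genome))
  assert_that(length(queries) >= 1L, "need at least one query genome")

  part <- stage("partition", detect_quadripartite(ref, cfg$min_ir_len))
  stage("partition", {
    jsonlite::write_json(
      list(genome = ref$id, length = nchar(ref$sequence),
           gc_percent = gc_content(ref),
           lsc = part$lsc, irb = part$irb, ssc = part$ssc, ira = part$ira,
           ir_length = part$ir_length, mismatches = part$mismatches),
      out("partition.json"), auto_unbox = TRUE, digits = NA)
  })
  jx <- stage("junctions", junction_distances(ref, part))
  stage("junctions", tsv(jx, "junctions.tsv"))

  ssrs <- stage("ssr", find_ssrs(ref$sequence))
  stage("ssr", tsv(ssrs, "ssr.tsv"))
  tandems <- stage("tandem", find_tandem_repeats(
    ref$sequence, cfg$tandem_unit_min, cfg$tandem_unit_max,
    cfg$tandem_identity))
  stage("tandem", tsv(tandems, "tandem.tsv"))
  stage("tandem", write_tracks(tandems, out("tandem.bed"), "BED",
                               chrom = ref$id))
  disp <- stage("dispersed", find_dispersed_repeats(
    ref$sequence, cfg$repeat_min_len, cfg$max_hamming))
  stage("dispersed", tsv(disp, "dispersed.tsv"))
  cls <- stage("classify", classify_locations(
    rbind(data.frame(start = tandems$start, end = tandems$end),
          if (nrow(disp)) data.frame(start = disp$pos1,
                                     end = disp$pos1 + disp$len - 1L)),
    part, ref))
  stage("classify", tsv(as.data.frame.table(cls$counts,
                                            responseName = "count"),
                        "repeat_context_counts.tsv"))

  alns <- stage("align", lapply(queries, function(q)
    align_collinear(ref, q)))
  events <- stage("variants", do.call(rbind, lapply(alns, call_variants)))
  stage("variants", tsv(events, "variants.tsv"))

  wt <- stage("windows", bin_counts(events, tandems, nchar(ref$sequence),
                                    cfg$window))
  stage("windows", tsv(wt, "windows.tsv"))
  assoc <- stage("cooccur", association_report(wt, cfg$alpha))
  overlap <- stage("cooccur", tandem_overlap_fractions(events, tandems))
  stage("cooccur", jsonlite::write_json(
    list(correlations = assoc$correlations, mann_whitney = assoc$mann_whitney,
         alpha = assoc$alpha, note = assoc$note,
         indel_tandem_overlap = overlap),
    out("association.json"), auto_unbox = TRUE, digits = NA))

  pi_tab <- stage("diversity", diversity_table(c(list(ref), queries), part))
  stage("diversity", tsv(pi_tab, "pi.tsv"))
  hot <- stage("diversity", rank_hotspots(pi_tab))
  stage("diversity", tsv(rbind(hot$genes, hot$intergenic), "hotspots.tsv"))

  kk <- stage("kaks", kaks_table(ref, queries))
  stage("kaks", tsv(kk, "kaks.tsv"))

  ct <- stage("codon", count_codons(ref))
  stage("codon", tsv(rscu(ct), "rscu.tsv"))
  pc <- stage("codon", do.call(rbind, lapply(c(list(ref), queries),
                                             function(g) {
    cbind(genome = g$id, positional_composition(g))
  })))
  stage("codon", tsv(pc, "codon_position_composition.tsv"))
  stage("codon", tsv(amino_acid_usage(ct), "amino_acid_usage.tsv"))

  proj <- stage("phylo", project_to_reference(alns))
  dmat <- stage("phylo", p_distance_matrix(proj))
  stage("phylo", {
    write.table(dmat, out("p_distances.tsv"), sep = "\t", quote = FALSE)
  })
  tree <- stage("phylo", nj_tree(dmat))
  stage("phylo", write_newick(tree, out("nj.nwk")))

  manifest <- list(reference = ref$id,
                   queries = vapply(queries, `[[`, character(1L), "id"),
                   files = basename(files),
                   config = cfg[setdiff(names(cfg),
                                        c("reference", "queries"))])
  jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  res <- list(reference = ref, partition = part, junctions = jx,
              ssrs = ssrs, tandems = tandems, dispersed = disp,
              classification = cls, events = events, windows = wt,
              association = assoc, overlap = overlap, pi = pi_tab,
              hotspots = hot, kaks = kk, codon_table = ct, tree = tree,
              distances = dmat, manifest = manifest)
  invisible(res)
}

# per-locus Pi across genomes: loci matched by name, IR-duplicated genes
# counted once (the IRB copy), single-copy gene and intergenic classes
diversity_table <- function(genomes, part) {
  # queries inherit the region label from the reference by locus name (their
  # own IR junctions may be shifted by indels)
  loci <- lapply(seq_along(genomes), function(i) {
    # IR-duplicated gene names are deduplicated right below (first = IRB
    # copy), so the extractor's duplicate-name warning is expected here
    lt <- suppressWarnings(extract_loci(genomes[[i]],
                                        if (i == 1L) part else NULL))
    lt$locus <- sub("_\\d+$", "", lt$locus)
    lt[!duplicated(paste(lt$class, lt$locus)), , drop = FALSE]
  })
  common <- Reduce(intersect, lapply(loci, function(x)
    paste(x$class, x$locus)))
  rows <- lapply(common, function(key) {
    seqs <- vapply(seq_along(genomes), function(i) {
      x <- loci[[i]]
      x$sequence[paste(x$class, x$locus) == key][1L]
    }, character(1L))
    names(seqs) <- vapply(genomes, `[[`, character(1L), "id")
    meta <- loci[[1L]][paste(loci[[1L]]$class, loci[[1L]]$locus) == key, ][1L, ]
    if (meta$class == "intron") return(NULL)
    if (any(nchar(seqs) == 0L)) return(NULL)
    al <- align_locus(seqs, locus = meta$locus, cls = meta$class,
                      region = meta$region)
    pi <- tryCatch(nucleotide_diversity(al), error = function(e) NULL)
    if (is.null(pi)) return(NULL)
    data.frame(locus = meta$locus, class = meta$class, region = meta$region,
               n = pi$n, sites = pi$sites_used, pi = pi$pi)
  })
  out <- do.call(rbind, Filter(Negate(is.null), rows))
  if (is.null(out)) {
    out <- data.frame(locus = character(), class = character(),
                      region = character(), n = integer(), sites = integer(),
                      pi = numeric())
  }
  out
}

# pairwise NG86 Ka/Ks of every shared CDS gene, each query against the
# reference; genes whose pair fails (frame broken by an indel, internal
# stop) are reported with NA values
kaks_table <- function(ref, queries) {
  ref_cds <- cds_by_name(ref)
  rows <- list()
  for (q in queries) {
    q_cds <- cds_by_name(q)
    for (g in intersect(names(ref_cds), names(q_cds))) {
      r <- tryCatch(kaks_ng86(ref_cds[[g]], q_cds[[g]]),
                    error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        gene = g, pair = paste(ref$id, q$id, sep = ":"),
        ka = r$ka %||% NA_real_, ks = r$ks %||% NA_real_,
        ratio = r$ratio %||% NA_real_)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(gene = character(), pair = character(), ka = numeric(),
                      ks = numeric(), ratio = numeric())
  }
  out
}

# unique CDS sequences by gene name (IR duplicates: first = IRB copy)
cds_by_name <- function(p) {
  cds <- Filter(function(f) f$kind == "CDS", p$features)
  seqs <- lapply(cds, function(f) {
    s <- feature_sequence(p, f)
    substring(s, f$codon_start, nchar(s))
  })
  names(seqs) <- vapply(cds, `[[`, character(1L), "name")
  seqs[!duplicated(names(seqs))]
}
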