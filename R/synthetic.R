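#' Specification for a synthetic plastome study
#'
#' The generator emulates the structure of grass plastomes: a circular
#' ~136 kbp quadripartite genome (LSC ~80 kbp, IR ~21.6 kbp twice, SSC
#' ~12.8 kbp, scaled proportionally for other `L`), ~38.5% GC, protein-coding
#' genes tiled with intergenic gaps (a few duplicated inside the IR), planted
#' SSRs (mostly A/T mononucleotide runs) and imperfect tandem arrays at
#' plastome-like densities (~700 per 136 kbp, unit lengths skewed to 7-10 bp),
#' and derived "species" whose SNP/indel events are drawn per 150 bp window
#' as Poisson with rate lambda * beta^[window overlaps a planted tandem].
#' beta = 1 is the null (no tandem-mutation association); the default beta of
#' 2 mirrors the moderate tandem-indel association seen in real plastomes.
#'
#' @param seed integer seed; every stochastic operation downstream derives
#'   from it
#' @param L genome length (bp)
#' @param lsc,ir,ssc region sizes; defaults scale 80000/21600/12800 at
#'   L = 136000 and must satisfy lsc + 2 ir + ssc = L
#' @param gc genomic GC fraction
#' @param n_genes,gene_codon_range protein-coding gene count and codon-count
#'   range
#' @param n_tandem,tandem_unit_range planted tandem array count and unit
#'   bounds
#' @param n_ssr planted SSR count
#' @param lambda_snp,lambda_indel per-species per-window baseline event rates
#' @param beta tandem-window rate enrichment factor (>= 1)
#' @param indel_mean,indel_cap geometric indel length mean and cap
#' @param p_insertion insertion share among indels
#' @param n_species derived species count
#' @param window window width (bp)
#' @param avoid_tandem_destruction redraw events that would land inside a
#'   planted array
#' @return a `synthetic_spec`
#' @export
synthetic_spec <- function(seed = 1L, L = 136000L,
                           lsc = round(L * 80000 / 136000),
                           ir = round(L * 21600 / 136000),
                           ssc = L - lsc - 2L * ir,
                           gc = 0.385,
                           n_genes = max(4L, round(L / 136000 * 50)),
                           gene_codon_range = c(100L, 400L),
                           n_tandem = max(2L, round(L / 136000 * 700)),
                           tandem_unit_range = c(7L, 95L),
                           n_ssr = max(1L, round(L / 136000 * 25)),
                           lambda_snp = 0.09, lambda_indel = 0.022,
                           beta = 2, indel_mean = 4, indel_cap = 50L,
                           p_insertion = 0.585, n_species = 12L,
                           window = 150L,
                           avoid_tandem_destruction = FALSE) {
  spec <- list(seed = as.integer(seed), L = as.integer(L),
               lsc = as.integer(lsc), ir = as.integer(ir),
               ssc = as.integer(ssc), gc = gc, n_genes = as.integer(n_genes),
               gene_codon_range = as.integer(gene_codon_range),
               n_tandem = as.integer(n_tandem),
               tandem_unit_range = as.integer(tandem_unit_range),
               n_ssr = as.integer(n_ssr), lambda_snp = lambda_snp,
               lambda_indel = lambda_indel, beta = beta,
               indel_mean = indel_mean, indel_cap = as.integer(indel_cap),
               p_insertion = p_insertion, n_species = as.integer(n_species),
               window = as.integer(window),
               avoid_tandem_destruction = isTRUE(avoid_tandem_destruction))
  assert_that(spec$lsc + 2L * spec$ir + spec$ssc == spec$L,
              "region sizes must sum to L")
  assert_that(spec$beta >= 1, "beta must be >= 1")
  assert_that(spec$lambda_snp >= 0 && spec$lambda_indel >= 0,
              "rates must be >= 0")
  structure(spec, class = "synthetic_spec")
}

#' Synthesize a reference plastome with planted structure
#'
#' Draws a random quadripartite genome: LSC and SSC are random sequence with
#' planted genes, SSRs and tandem arrays; the IRB is random sequence with a
#' few planted genes and the IRA is its exact reverse complement (gene
#' annotations mirrored to the minus strand). Repeats are planted in
#' intergenic single-copy space only, with period-breaking flanks so planted
#' coordinates are exact. Fully reproducible from the spec seed.
#'
#' @param spec a [synthetic_spec()]
#' @return list: `plastome` (a [plastome()]), `truth` (partition intervals,
#'   tandem/ssr/gene tables)
#' @export
synthesize_reference <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  set.seed(spec$seed)
  L <- spec$L
  probs <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  ch <- sample(DNA_BASES, L, replace = TRUE, prob = probs)
  irb_start <- spec$lsc + 1L
  irb_end <- spec$lsc + spec$ir
  ssc_start <- irb_end + 1L
  ssc_end <- irb_end + spec$ssc
  ira_start <- ssc_end + 1L

  margin <- max(20L, min(200L, spec$lsc %/% 50L))
  occupied <- logical(L)
  for (b in c(spec$lsc, irb_end, ssc_end)) {
    occupied[max(1L, b - margin):min(L, b + margin)] <- TRUE
  }
  # repeats go into single-copy intergenic space only; the IR pair stays a
  # clean mirror so planted coordinates are exact
  occupied[irb_start:irb_end] <- TRUE
  occupied[ira_start:L] <- TRUE

  # --- genes ---
  sc_len <- spec$lsc + spec$ssc
  n_ir_genes <- if (spec$ir > 3000L) min(3L, spec$n_genes %/% 10L) else 0L
  n_sc <- spec$n_genes - n_ir_genes
  n_lsc_genes <- round(n_sc * spec$lsc / sc_len)
  n_ssc_genes <- n_sc - n_lsc_genes
  genes <- list()
  gene_id <- 0L
  plant_genes <- function(rs, re, ng, ch, genes, gene_id) {
    if (ng <= 0L) return(list(ch = ch, genes = genes, gene_id = gene_id))
    space <- re - rs + 1L - 2L * margin
    lens <- 3L * sample(spec$gene_codon_range[1L]:spec$gene_codon_range[2L],
                        ng, replace = TRUE) + 3L
    while (ng > 0L && sum(lens) + (ng + 1L) * 30L > space) {
      ng <- ng - 1L
      lens <- lens[seq_len(ng)]
    }
    if (ng == 0L) return(list(ch = ch, genes = genes, gene_id = gene_id))
    free <- space - sum(lens) - (ng + 1L) * 30L
    gaps <- 30L + as.vector(stats::rmultinom(1L, free, rep(1, ng + 1L)))
    # codon bases drawn with the positional AT bias of grass plastome CDSs
    # (AT share ~52.7 / 60.3 / 70.0 % at positions 1-3)
    pos_probs <- lapply(c(0.527, 0.603, 0.700), function(at)
      c(at / 2, (1 - at) / 2, (1 - at) / 2, at / 2))
    draw_codons <- function(k) {
      m <- cbind(sample(DNA_BASES, k, TRUE, pos_probs[[1L]]),
                 sample(DNA_BASES, k, TRUE, pos_probs[[2L]]),
                 sample(DNA_BASES, k, TRUE, pos_probs[[3L]]))
      cods <- paste0(m[, 1L], m[, 2L], m[, 3L])
      bad <- cods %in% c("TAA", "TAG", "TGA")
      while (any(bad)) {
        cods[bad] <- paste0(sample(DNA_BASES, sum(bad), TRUE, pos_probs[[1L]]),
                            sample(DNA_BASES, sum(bad), TRUE, pos_probs[[2L]]),
                            sample(DNA_BASES, sum(bad), TRUE, pos_probs[[3L]]))
        bad <- cods %in% c("TAA", "TAG", "TGA")
      }
      cods
    }
    cursor <- rs + margin
    for (gi in seq_len(ng)) {
      cursor <- cursor + gaps[gi]
      len <- lens[gi]
      n_codons <- len %/% 3L - 2L
      body <- draw_codons(n_codons)
      cds <- paste0("ATG", paste(body, collapse = ""),
                    sample(c("TAA", "TAG", "TGA"), 1L))
      strand <- sample(c("+", "-"), 1L)
      written <- if (strand == "-") revcomp(cds) else cds
      ch[cursor:(cursor + len - 1L)] <- seq_chars(written)
      gene_id <- gene_id + 1L
      genes[[length(genes) + 1L]] <- data.frame(
        name = sprintf("g%03d", gene_id), start = cursor,
        end = cursor + len - 1L, strand = strand)
      cursor <- cursor + len
    }
    list(ch = ch, genes = genes, gene_id = gene_id)
  }
  r <- plant_genes(1L, spec$lsc, n_lsc_genes, ch, genes, gene_id)
  r <- plant_genes(ssc_start, ssc_end, n_ssc_genes, r$ch, r$genes, r$gene_id)
  r <- plant_genes(irb_start, irb_end, n_ir_genes, r$ch, r$genes, r$gene_id)
  ch <- r$ch; genes <- r$genes
  gene_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(name = character(), start = integer(), end = integer(),
               strand = character())
  for (i in seq_len(nrow(gene_df))) {
    occupied[max(1L, gene_df$start[i] - 2L):min(L, gene_df$end[i] + 2L)] <- TRUE
  }

  # --- planted repeats (single-copy intergenic space only) ---
  plant_array <- function(ch, occupied, arr, u) {
    len <- nchar(arr)
    for (try in seq_len(60L)) {
      a <- sample.int(ssc_end - len - 2L, 1L) + 1L
      span <- (a - 1L):(a + len)
      if (any(occupied[span])) next
      ch[a:(a + len - 1L)] <- seq_chars(arr)
      # period-breaking flanks keep planted coordinates exact
      ch[a - 1L] <- sample(setdiff(DNA_BASES, ch[a - 1L + u]), 1L)
      ch[a + len] <- sample(setdiff(DNA_BASES, ch[a + len - u]), 1L)
      occupied[span] <- TRUE
      return(list(ch = ch, occupied = occupied, start = a,
                  end = a + len - 1L))
    }
    NULL
  }
  tandems <- list()
  for (t in seq_len(spec$n_tandem)) {
    u <- spec$tandem_unit_range[1L] +
      min(stats::rgeom(1L, 1 / 7),
          spec$tandem_unit_range[2L] - spec$tandem_unit_range[1L])
    unit <- paste(sample(DNA_BASES, u, replace = TRUE, prob = probs),
                  collapse = "")
    if (smallest_period(unit) < u) next
    copies <- sample(2:4, 1L, prob = c(0.55, 0.3, 0.15))
    extra <- if (u > 1L && runif(1L) < 0.4) sample.int(u - 1L, 1L) else 0L
    arr <- substring(strrep(unit, copies + 1L), 1L, copies * u + extra)
    if (nchar(arr) >= 24L && runif(1L) < 0.35) {
      p <- sample.int(nchar(arr), 1L)
      substring(arr, p, p) <- sample(setdiff(DNA_BASES,
                                             substring(arr, p, p)), 1L)
    }
    res <- plant_array(ch, occupied, arr, u)
    if (is.null(res)) next
    ch <- res$ch; occupied <- res$occupied
    tandems[[length(tandems) + 1L]] <- data.frame(
      start = res$start, end = res$end, unit = unit, unit_len = u,
      copies = nchar(arr) / u)
  }
  ssrs <- list()
  for (t in seq_len(spec$n_ssr)) {
    if (runif(1L) < 0.9) {
      motif <- sample(c("A", "T"), 1L)
      copies <- sample(10:14, 1L)
    } else {
      motif <- "AT"
      copies <- sample(6:8, 1L)
    }
    arr <- strrep(motif, copies)
    res <- plant_array(ch, occupied, arr, nchar(motif))
    if (is.null(res)) next
    ch <- res$ch; occupied <- res$occupied
    ssrs[[length(ssrs) + 1L]] <- data.frame(
      start = res$start, end = res$end, motif = motif, copies = copies)
  }

  # --- IRA = exact reverse complement of IRB; mirror its gene annotations ---
  irb_seq <- paste(ch[irb_start:irb_end], collapse = "")
  ch[ira_start:L] <- seq_chars(revcomp(irb_seq))
  # harden the SSC-side junctions: force the first floor(L/1000)+1 inward
  # comparison columns to mismatch so the maximal inverted pair cannot creep
  # past the planted boundary within its mismatch tolerance
  hard <- min(floor(L / 1000) + 1L, max(1L, (spec$ssc - 2L) %/% 2L))
  for (o in 0:(hard - 1L)) {
    if (ch[ssc_start + o] == complement_seq(ch[ssc_end - o])) {
      ch[ssc_end - o] <- sample(setdiff(DNA_BASES,
                                        c(ch[ssc_end - o],
                                          complement_seq(ch[ssc_start + o]))),
                                1L)
    }
  }
  features <- list()
  for (i in seq_len(nrow(gene_df))) {
    g <- gene_df[i, ]
    features[[length(features) + 1L]] <-
      feature(g$name, "CDS", g$strand, cbind(g$start, g$end))
    if (g$start >= irb_start && g$end <= irb_end) {
      s2 <- ira_start + (irb_end - g$end)
      e2 <- ira_start + (irb_end - g$start)
      features[[length(features) + 1L]] <-
        feature(g$name, "CDS", if (g$strand == "+") "-" else "+",
                cbind(s2, e2))
    }
  }
  p <- plastome(sprintf("synth%d", spec$seed), paste(ch, collapse = ""),
                circular = TRUE, features = features)
  truth <- list(
    partition = list(lsc = c(1L, spec$lsc), irb = c(irb_start, irb_end),
                     ssc = c(ssc_start, ssc_end), ira = c(ira_start, L)),
    tandems = if (length(tandems)) do.call(rbind, tandems) else
      data.frame(start = integer(), end = integer(), unit = character(),
                 unit_len = integer(), copies = numeric()),
    ssrs = if (length(ssrs)) do.call(rbind, ssrs) else
      data.frame(start = integer(), end = integer(), motif = character(),
                 copies = integer()),
    genes = gene_df)
  list(plastome = p, truth = truth)
}

#' Derive mutated "species" genomes from a synthetic reference
#'
#' For each species, SNP and indel events are drawn per `window`-bp window as
#' Poisson with rate `lambda * beta^[window overlaps a planted tandem]`;
#' indel lengths are geometric (mean `indel_mean`, capped); insertions get
#' random inserted sequence. Events whose footprints would overlap an
#' already-accepted event of the same species are dropped, so the recorded
#' truth is exactly what is applied to the sequence. With
#' `materialize = FALSE` only the event list is produced (the
#' distributionally identical fast path used for calibration studies).
#'
#' @param ref reference [plastome()] from [synthesize_reference()]
#' @param truth its truth object
#' @param spec the [synthetic_spec()]
#' @param seed RNG seed for the mutation draw (default `spec$seed + 1`)
#' @param materialize build mutated sequences and remapped annotations
#' @return list: `species` (list of plastomes, if materialized), `events`
#'   (data.frame: species, kind, ref_pos, length, alt), `tandem_windows`
#'   (logical per bin)
#' @export
mutate_species <- function(ref, truth, spec, seed = spec$seed + 1L,
                           materialize = TRUE) {
  stopifnot(inherits(ref, "plastome"), inherits(spec, "synthetic_spec"))
  set.seed(seed)
  L <- nchar(ref$sequence)
  w <- spec$window
  nb <- ceiling(L / w)
  tw <- logical(nb)
  if (nrow(truth$tandems)) {
    for (i in seq_len(nrow(truth$tandems))) {
      b1 <- ceiling(truth$tandems$start[i] / w)
      b2 <- ceiling(truth$tandems$end[i] / w)
      tw[b1:b2] <- TRUE
    }
  }
  mult <- ifelse(tw, spec$beta, 1)
  in_tandem <- logical(L)
  if (nrow(truth$tandems)) {
    for (i in seq_len(nrow(truth$tandems))) {
      in_tandem[truth$tandems$start[i]:truth$tandems$end[i]] <- TRUE
    }
  }
  ev_all <- list()
  geom_p <- 1 / spec$indel_mean  # 1 + rgeom: mean = 1 + (1-p)/p = 1/p
  for (sp in seq_len(spec$n_species)) {
    n_snp <- rpois(nb, spec$lambda_snp * mult)
    n_ind <- rpois(nb, spec$lambda_indel * mult)
    rows <- list()
    mk_pos <- function(bin, count) {
      (bin - 1L) * w + sample.int(min(w, L - (bin - 1L) * w), count,
                                  replace = FALSE)
    }
    for (b in which(n_snp + n_ind > 0L)) {
      total <- n_snp[b] + n_ind[b]
      avail <- min(w, L - (b - 1L) * w)
      total <- min(total, avail)
      pos <- mk_pos(b, total)
      kinds <- c(rep("SNP", min(n_snp[b], total)),
                 rep("indel", max(0L, total - n_snp[b])))
      for (qi in seq_len(total)) {
        p0 <- pos[qi]
        if (spec$avoid_tandem_destruction && in_tandem[p0]) {
          for (try in seq_len(20L)) {
            cand <- (b - 1L) * w + sample.int(avail, 1L)
            if (!in_tandem[cand]) { p0 <- cand; break }
          }
          if (in_tandem[p0]) next
        }
        if (kinds[qi] == "SNP") {
          rb <- substring(ref$sequence, p0, p0)
          if (rb == "N") next
          rows[[length(rows) + 1L]] <- data.frame(
            species = sp, kind = "SNP", ref_pos = p0, length = 1L,
            alt = sample(setdiff(DNA_BASES, rb), 1L))
        } else {
          len <- min(1L + rgeom(1L, geom_p), spec$indel_cap)
          if (runif(1L) < spec$p_insertion) {
            rows[[length(rows) + 1L]] <- data.frame(
              species = sp, kind = "insertion", ref_pos = p0, length = len,
              alt = paste(sample(DNA_BASES, len, replace = TRUE),
                          collapse = ""))
          } else {
            len <- min(len, L - p0)  # stay on the genome
            if (len < 1L) next
            rows[[length(rows) + 1L]] <- data.frame(
              species = sp, kind = "deletion", ref_pos = p0, length = len,
              alt = "")
          }
        }
      }
    }
    if (length(rows) == 0L) next
    ev <- do.call(rbind, rows)
    ev <- ev[order(ev$ref_pos), , drop = FALSE]
    # drop events whose reference footprint overlaps an accepted one
    foot_end <- ifelse(ev$kind == "deletion", ev$ref_pos + ev$length - 1L,
                       ev$ref_pos)
    keep <- logical(nrow(ev))
    last_end <- -1L
    for (i in seq_len(nrow(ev))) {
      if (ev$ref_pos[i] > last_end) {
        keep[i] <- TRUE
        last_end <- foot_end[i]
      }
    }
    ev_all[[sp]] <- ev[keep, , drop = FALSE]
  }
  events <- if (length(ev_all)) do.call(rbind, ev_all) else
    data.frame(species = integer(), kind = character(), ref_pos = integer(),
               length = integer(), alt = character())
  rownames(events) <- NULL
  out <- list(events = events, tandem_windows = tw)
  if (materialize) {
    out$species <- lapply(seq_len(spec$n_species), function(sp) {
      apply_events(ref, events[events$species == sp, , drop = FALSE],
                   sprintf("%s_sp%02d", ref$id, sp))
    })
  }
  out
}

# apply a non-overlapping event set to a plastome; annotations remapped
apply_events <- function(ref, ev, new_id) {
  s <- ref$sequence
  if (nrow(ev)) {
    ev <- ev[order(-ev$ref_pos), , drop = FALSE]
    for (i in seq_len(nrow(ev))) {
      p0 <- ev$ref_pos[i]
      if (ev$kind[i] == "SNP") {
        substring(s, p0, p0) <- ev$alt[i]
      } else if (ev$kind[i] == "insertion") {
        s <- paste0(substring(s, 1L, p0), ev$alt[i],
                    substring(s, p0 + 1L, nchar(s)))
      } else {
        s <- paste0(substring(s, 1L, p0 - 1L),
                    substring(s, p0 + ev$length[i], nchar(s)))
      }
    }
  }
  ins <- ev[ev$kind == "insertion", , drop = FALSE]
  del <- ev[ev$kind == "deletion", , drop = FALSE]
  map_pos <- function(x) {
    shift_ins <- vapply(x, function(xx) sum(ins$length[ins$ref_pos < xx]),
                        numeric(1L))
    shift_del <- vapply(x, function(xx)
      sum(pmin(pmax(xx - del$ref_pos + 1L, 0L), del$length)), numeric(1L))
    as.integer(x + shift_ins - shift_del)
  }
  feats <- lapply(ref$features, function(f) {
    parts <- cbind(map_pos(f$parts[, 1L]), map_pos(f$parts[, 2L]))
    parts[, 1L] <- pmax(parts[, 1L], 1L)
    if (any(parts[, 2L] < parts[, 1L])) return(NULL)
    feature(f$name, f$kind, f$strand, parts, f$trans_spliced, f$codon_start)
  })
  plastome(new_id, s, ref$circular, Filter(Negate(is.null), feats))
}

#' Write the synthetic fixture suite to disk
#'
#' For each seed, emits the reference as FASTA and GenBank, the mutated
#' species as multi-FASTA, and the planted truth as JSON, for a small test
#' matrix (null beta = 1, moderate beta = 2, strong beta = 5 at L = 30000,
#' plus a tiny 2 kbp genome for oracle-scale tests).
#'
#' @param out_dir writable output directory
#' @param seeds integer vector of seeds
#' @return data.frame manifest of the files written
#' @export
make_fixture_suite <- function(out_dir, seeds = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list()
  emit <- function(path, role, seed) {
    manifest[[length(manifest) + 1L]] <<- data.frame(file = path, role = role,
                                                     seed = seed)
  }
  for (seed in seeds) {
    for (beta in c(1, 2, 5)) {
      spec <- synthetic_spec(seed = seed, L = 30000L, beta = beta,
                             n_species = 6L)
      syn <- synthesize_reference(spec)
      mut <- mutate_species(syn$plastome, syn$truth, spec)
      tag <- sprintf("seed%d_beta%g", seed, beta)
      fa <- file.path(out_dir, paste0(tag, "_ref.fasta"))
      write_fasta(setNames(syn$plastome$sequence, syn$plastome$id), fa)
      emit(fa, "reference fasta", seed)
      gb <- file.path(out_dir, paste0(tag, "_ref.gb"))
      write_genbank(syn$plastome, gb)
      emit(gb, "reference genbank", seed)
      sp <- file.path(out_dir, paste0(tag, "_species.fasta"))
      write_fasta(vapply(mut$species, `[[`, character(1L), "sequence") |>
                    setNames(vapply(mut$species, `[[`, character(1L), "id")),
                  sp)
      emit(sp, "species fasta", seed)
      tj <- file.path(out_dir, paste0(tag, "_truth.json"))
      jsonlite::write_json(list(partition = syn$truth$partition,
                                tandems = syn$truth$tandems,
                                ssrs = syn$truth$ssrs,
                                genes = syn$truth$genes,
                                events = mut$events), tj, digits = NA)
      emit(tj, "truth json", seed)
    }
    tiny <- synthesize_reference(synthetic_spec(seed = seed, L = 2000L,
                                                n_genes = 2L, n_tandem = 4L,
                                                n_ssr = 2L, n_species = 2L))
    tf <- file.path(out_dir, sprintf("seed%d_tiny_ref.fasta", seed))
    write_fasta(setNames(tiny$plastome$sequence, tiny$plastome$id), tf)
    emit(tf, "tiny reference fasta", seed)
  }
  out <- do.call(rbind, manifest)
  rownames(out) <- NULL
  out
}
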