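test_that("the generator is byte-identical under a fixed seed", {
  spec <- synthetic_spec(seed = 71, L = 12000, n_species = 2, n_genes = 4)
  s1 <- synthesize_reference(spec)
  s2 <- synthesize_reference(spec)
  expect_identical(s1$plastome$sequence, s2$plastome$sequence)
  expect_identical(s1$truth, s2$truth)
  m1 <- mutate_species(s1$plastome, s1$truth, spec)
  m2 <- mutate_species(s2$plastome, s2$truth, spec)
  expect_identical(m1$events, m2$events)
  expect_identical(m1$species[[1]]$sequence, m2$species[[1]]$sequence)
})

test_that("planted partitions are recovered exactly across seeds", {
  for (s in 1:10) {
    spec <- synthetic_spec(seed = 700 + s, L = 20000, n_species = 2,
                           n_genes = 4)
    syn <- synthesize_reference(spec)
    part <- detect_quadripartite(syn$plastome, min_ir_len = 1500)
    tp <- syn$truth$partition
    expect_identical(unname(part$irb), as.integer(tp$irb))
    expect_identical(unname(part$ssc), as.integer(tp$ssc))
    expect_identical(unname(part$ira), as.integer(tp$ira))
    # coverage and IR symmetry invariants
    total <- sum(vapply(c("lsc", "irb", "ssc", "ira"), function(r)
      part[[r]][2] - part[[r]][1] + 1, numeric(1)))
    expect_equal(total, nchar(syn$plastome$sequence))
    expect_lte(part$mismatches / part$ir_length, 0.001)
  }
})

test_that("planted tandem arrays are recovered at >= 95% with identity >= 90", {
  hits_cover <- function(truth, hits) {
    vapply(seq_len(nrow(truth)), function(i) {
      ov <- pmin(hits$end, truth$end[i]) - pmax(hits$start, truth$start[i]) + 1
      any(ov >= 0.8 * (truth$end[i] - truth$start[i] + 1))
    }, logical(1))
  }
  recalls <- vapply(1:8, function(s) {
    spec <- synthetic_spec(seed = 7000 + s, L = 20000, n_species = 2)
    syn <- synthesize_reference(spec)
    truth <- syn$truth$tandems
    truth <- truth[truth$unit_len >= 7, , drop = FALSE]
    hits <- find_tandem_repeats(syn$plastome$sequence, min_identity = 90)
    mean(hits_cover(truth, hits))
  }, numeric(1))
  expect_gte(mean(recalls), 0.95)
})

test_that("zero mutation rates reproduce the reference exactly", {
  spec <- synthetic_spec(seed = 72, L = 10000, n_species = 2, n_genes = 3,
                         lambda_snp = 0, lambda_indel = 0)
  syn <- synthesize_reference(spec)
  mut <- mutate_species(syn$plastome, syn$truth, spec)
  expect_equal(nrow(mut$events), 0L)
  for (sp in mut$species) {
    expect_identical(sp$sequence, syn$plastome$sequence)
    aln <- align_collinear(syn$plastome, sp)
    expect_equal(nrow(call_variants(aln)), 0L)
  }
})

test_that("at beta = 1 tandem windows carry no excess mutations", {
  spec <- synthetic_spec(seed = 73, L = 30000, beta = 1)
  syn <- synthesize_reference(spec)
  diffs <- vapply(1:40, function(r) {
    mut <- mutate_species(syn$plastome, syn$truth, spec, seed = 9000 + r,
                          materialize = FALSE)
    ev <- mut$events
    names(ev)[names(ev) == "species"] <- "qry_id"
    wt <- bin_counts(ev, syn$truth$tandems, spec$L)
    tw <- mut$tandem_windows
    mean(wt$indel[tw] + wt$snp[tw]) - mean(wt$indel[!tw] + wt$snp[!tw])
  }, numeric(1))
  pooled_rate <- (spec$lambda_snp + spec$lambda_indel) * spec$n_species
  se <- sqrt(2 * pooled_rate / 100) / sqrt(40)  # ~ se of the mean difference
  expect_lt(abs(mean(diffs)), 2 * se * 5)  # wide but diagnostic bound
})

test_that("avoid_tandem_destruction keeps events out of planted arrays", {
  spec <- synthetic_spec(seed = 74, L = 20000, beta = 5,
                         avoid_tandem_destruction = TRUE)
  syn <- synthesize_reference(spec)
  mut <- mutate_species(syn$plastome, syn$truth, spec, materialize = FALSE)
  td <- syn$truth$tandems
  inside <- vapply(mut$events$ref_pos, function(p)
    any(p >= td$start & p <= td$end), logical(1))
  expect_equal(sum(inside), 0L)
})

test_that("the fixture suite regenerates identically and parses back", {
  d1 <- tempfile("fix1"); d2 <- tempfile("fix2")
  m1 <- make_fixture_suite(d1, seeds = 5L)
  m2 <- make_fixture_suite(d2, seeds = 5L)
  expect_equal(basename(m1$file), basename(m2$file))
  expect_gte(nrow(m1), 13L)  # 3 beta levels x 4 files + tiny reference
  for (i in seq_len(nrow(m1))) {
    expect_identical(readLines(m1$file[i]), readLines(m2$file[i]))
  }
  gb <- grep("_ref\\.gb$", m1$file, value = TRUE)[1]
  p <- read_genbank(gb)
  fa <- read_fasta(grep("beta1_ref\\.fasta$", m1$file, value = TRUE)[1])
  expect_identical(p$sequence, unname(fa[1]))
  expect_gt(length(p$features), 0L)
})

test_that("a tiny fixture runs through the whole pipeline quickly", {
  spec <- synthetic_spec(seed = 75, L = 2000, n_genes = 2, n_tandem = 4,
                         n_ssr = 2, n_species = 3,
                         gene_codon_range = c(40L, 80L),
                         lambda_snp = 0.3, lambda_indel = 0.05)
  syn <- synthesize_reference(spec)
  mut <- mutate_species(syn$plastome, syn$truth, spec)
  out <- tempfile("tinyrun")
  cfg <- run_config(syn$plastome, mut$species, out, min_ir_len = 250L)
  res <- suppressMessages(run_all(cfg))
  expect_true(file.exists(file.path(out, "manifest.json")))
  expect_equal(nrow(res$association$correlations), 3L)
  expect_false(file.exists(file.path(out, "FAILED")))
})
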