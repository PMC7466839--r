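test_that("identical sequences align with no gaps and call no variants", {
  set.seed(11)
  s <- rand_dna(3000)
  aln <- align_collinear(s, s)
  expect_false(grepl("-", aln$ref_aln, fixed = TRUE))
  expect_equal(aln$ref_aln, aln$qry_aln)
  expect_equal(nrow(call_variants(aln)), 0L)
})

test_that("planted SNPs and a 5 bp deletion are recovered exactly, at the
           optimum of the full affine DP", {
  set.seed(12)
  ref <- rand_dna(2000)
  qry <- ref
  snp_pos <- c(300L, 900L, 1500L)
  for (p in snp_pos) {
    substring(qry, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substring(ref, p, p))[1]
  }
  qry <- paste0(substring(qry, 1, 1199), substring(qry, 1205))  # 5 bp deletion
  aln <- align_collinear(ref, qry)
  expect_equal(gsub("-", "", aln$ref_aln), ref)
  expect_equal(gsub("-", "", aln$qry_aln), qry)
  ev <- call_variants(aln)
  expect_equal(sum(ev$kind == "SNP"), 3L)
  expect_setequal(ev$ref_pos[ev$kind == "SNP"], snp_pos)
  del <- ev[ev$kind == "deletion", ]
  expect_equal(nrow(del), 1L)
  expect_equal(del$length, 5L)
  # left-normalized anchor computed independently
  a <- 1200L; b <- 1204L
  while (a > 1 && substring(ref, a - 1, a - 1) == substring(ref, b, b)) {
    a <- a - 1L; b <- b - 1L
  }
  expect_equal(del$ref_pos, a)
  # alignment score equals the full Needleman-Wunsch/Gotoh optimum
  expect_equal(score_alignment(aln$ref_aln, aln$qry_aln),
               oracle_align_score(ref, qry))
})

test_that("a large reversed segment triggers the non-collinear error", {
  set.seed(13)
  ref <- rand_dna(3000)
  mid <- substring(ref, 1001, 2200)
  qry <- paste0(substring(ref, 1, 1000), revcomp(mid), substring(ref, 2201))
  expect_error(align_collinear(ref, qry, max_gap_span = 200L),
               "non-collinear")
})

test_that("variant classification follows the contiguity rule", {
  mk_aln <- function(r, q) {
    structure(list(ref_id = "r", qry_id = "q", ref_aln = r, qry_aln = q,
                   n_anchors = 0L), class = "pairwise_alignment")
  }
  # isolated mismatch at column 3 -> SNP at ref_pos 3
  ev <- call_variants(mk_aln("ACGTACGT", "ACTTACGT"))
  expect_equal(ev$kind, "SNP")
  expect_equal(ev$ref_pos, 3L)
  # a 3-column gap run in the query -> one deletion, not three
  ev <- call_variants(mk_aln("ACGTACGT", "ACGT---T"))
  expect_equal(ev$kind, "deletion")
  expect_equal(ev$length, 3L)
  # >= 2 contiguous mismatch columns -> one substitution block
  ev <- call_variants(mk_aln("ACGTACGT", "ACTAACGT"))
  expect_equal(ev$kind, "substitution_block")
  expect_equal(ev$length, 2L)
  expect_equal(ev$ref_pos, 3L)
  # insertion anchored at the 5' reference base, left-normalized
  ev <- call_variants(mk_aln("ACG--TAC", "ACGGGTAC"))
  expect_equal(ev$kind, "insertion")
  expect_equal(ev$length, 2L)
  expect_equal(ev$ref_pos, 2L)  # GG slides left over the G at ref pos 3
})

test_that("event lengths conserve total gap columns (synthetic round-trip)", {
  spec <- synthetic_spec(seed = 21, L = 8000, n_species = 2, n_genes = 4,
                         gene_codon_range = c(60L, 120L))
  syn <- synthesize_reference(spec)
  mut <- mutate_species(syn$plastome, syn$truth, spec)
  for (sp in mut$species) {
    aln <- align_collinear(syn$plastome, sp)
    ev <- call_variants(aln)
    qc <- strsplit(aln$qry_aln, "")[[1]]
    rc <- strsplit(aln$ref_aln, "")[[1]]
    expect_equal(sum(ev$length[ev$kind == "deletion"]), sum(qc == "-"))
    expect_equal(sum(ev$length[ev$kind == "insertion"]), sum(rc == "-"))
  }
})

test_that("planted events are recovered exactly when well separated", {
  spec <- synthetic_spec(seed = 22, L = 12000, n_species = 3,
                         lambda_snp = 0.02, lambda_indel = 0.008,
                         n_genes = 4)
  syn <- synthesize_reference(spec)
  mut <- mutate_species(syn$plastome, syn$truth, spec)
  for (i in seq_along(mut$species)) {
    truth_i <- mut$events[mut$events$species == i, ]
    # spacing condition: only check species whose events are >= 50 bp apart
    if (nrow(truth_i) > 1 && min(diff(sort(truth_i$ref_pos))) < 50) next
    ev <- call_variants(align_collinear(syn$plastome, mut$species[[i]]))
    expect_equal(nrow(ev), nrow(truth_i))
    expect_setequal(ev$ref_pos[ev$kind == "SNP"],
                    truth_i$ref_pos[truth_i$kind == "SNP"])
    expect_equal(sort(ev$length[ev$kind == "insertion"]),
                 sort(truth_i$length[truth_i$kind == "insertion"]))
    expect_equal(sort(ev$length[ev$kind == "deletion"]),
                 sort(truth_i$length[truth_i$kind == "deletion"]))
  }
})

test_that("tandem overlap fractions follow interval containment", {
  events <- data.frame(qry_id = "q", kind = c("insertion", "insertion",
                                              "deletion"),
                       ref_pos = c(100L, 500L, 120L), length = c(2L, 3L, 4L),
                       ref_allele = "", qry_allele = "")
  tandems <- data.frame(start = 90L, end = 130L)
  fr <- tandem_overlap_fractions(events, tandems)
  expect_equal(fr$insertion_fraction, 0.5)
  expect_equal(fr$deletion_fraction, 1)
  expect_equal(fr$n_insertions, 2L)
  # no tandems -> zero fractions with counts
  fr0 <- tandem_overlap_fractions(events, tandems[0, , drop = FALSE])
  expect_equal(fr0$insertion_fraction, 0)
  expect_equal(fr0$n_insertions, 2L)
  # random fixture vs a direct containment scan
  set.seed(23)
  ev <- data.frame(qry_id = "q", kind = sample(c("insertion", "deletion"),
                                               50, TRUE),
                   ref_pos = sample(1000L, 50), length = 1L,
                   ref_allele = "", qry_allele = "")
  td <- data.frame(start = sort(sample(900L, 8)))
  td$end <- td$start + sample(10:40, 8, TRUE)
  fr <- tandem_overlap_fractions(ev, td, flank = 5L)
  inside <- vapply(ev$ref_pos, function(p)
    any(p >= td$start - 5 & p <= td$end + 5), logical(1))
  ins <- ev$kind == "insertion"
  expect_equal(fr$insertion_fraction, mean(inside[ins]))
  expect_equal(fr$deletion_fraction, mean(inside[!ins]))
})
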