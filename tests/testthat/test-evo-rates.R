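test_that("align_locus: identity, one clean gap block, order invariance", {
  set.seed(41)
  base <- rand_dna(300)
  al0 <- align_locus(c(a = base, b = base, c = base))
  expect_true(all(nchar(al0$aln) == 300))
  expect_false(any(grepl("-", al0$aln, fixed = TRUE)))
  # one planted 3 bp deletion -> one 3-column gap block
  del <- paste0(substring(base, 1, 149), substring(base, 153))
  al1 <- align_locus(c(a = base, b = del))
  expect_equal(length(unique(nchar(al1$aln))), 1L)
  expect_equal(sum(strsplit(al1$aln[["b"]], "")[[1]] == "-"), 3L)
  r <- rle(strsplit(al1$aln[["b"]], "")[[1]] == "-")
  expect_equal(sum(r$values), 1L)  # a single gap run
  # downstream Pi is invariant to input order
  mut <- base
  substring(mut, 37, 37) <- setdiff(c("A", "C", "G", "T"),
                                    substring(base, 37, 37))[1]
  p1 <- nucleotide_diversity(align_locus(c(a = base, b = del, c = mut)))
  p2 <- nucleotide_diversity(align_locus(c(c = mut, a = base, b = del)))
  expect_equal(p1$pi, p2$pi)
})

test_that("Pi follows the pairwise-deletion definition", {
  expect_equal(nucleotide_diversity(c(a = "ACGT", b = "ACGT"))$pi, 0)
  s1 <- strrep("A", 100)
  s2 <- paste0(strrep("A", 98), "CC")
  expect_equal(nucleotide_diversity(c(a = s1, b = s2))$pi, 0.02)
  # three-row toy with gaps, hand-computed:
  # pairs: (a,b): L=4, d=1; (a,c): L=4, d=2; (b,c): L=3, d=1
  a <- "ACGTA"
  b <- "ACCT-"
  c_ <- "AG-TC"
  want <- (1 / 4 + 2 / 4 + 1 / 3) * 2 / (3 * 2)
  got <- nucleotide_diversity(c(a = a, b = b, c = c_))
  expect_equal(got$pi, want)
  expect_equal(got$pi, oracle_pi(c(a, b, c_)))
  expect_error(nucleotide_diversity(c(a = "A-", b = "-A")), "gap-free")
})

test_that("hotspot ranking is descending with deterministic ties", {
  res <- data.frame(locus = c("g1", "g2", "g3", "i1", "i2"),
                    class = c("gene", "gene", "gene", "intergenic",
                              "intergenic"),
                    pi = c(0.01, 0.05, 0.05, 0.002, 0.2))
  h <- rank_hotspots(res, top = 2)
  expect_equal(h$genes$locus, c("g2", "g3"))  # tie broken by name
  expect_equal(h$genes$rank, 1:2)
  expect_equal(h$intergenic$locus[1], "i2")
  expect_equal(nrow(h$intergenic), 2L)
})

test_that("NG86: identity, single-codon cases, and the enumeration oracle", {
  r0 <- kaks_ng86("ATGAAA", "ATGAAA")
  expect_equal(r0$ka, 0)
  expect_equal(r0$ks, 0)
  expect_true(is.na(r0$ratio))
  # Phe TTT -> TTC: synonymous single difference
  r1 <- kaks_ng86("TTT", "TTC")
  o1 <- oracle_ng86("TTT", "TTC")
  expect_equal(r1$pn, 0)
  expect_gt(r1$ps, 0)
  expect_equal(r1$s_sites, o1$s_sites)
  expect_equal(r1$n_sites, o1$n_sites)
  expect_equal(r1$sd, o1$sd)
  expect_equal(r1$pn, o1$pn)
  expect_equal(r1$ps, o1$ps)
  # site counts of every codon match the seqinr-translated oracle
  codons <- setdiff(plastocomp:::all_codons(), c("TAA", "TAG", "TGA"))
  for (cd in codons) {
    expect_equal(plastocomp:::syn_sites(cd), oracle_syn_sites(cd),
                 tolerance = 1e-12)
  }
})

test_that("NG86 pathway averaging matches exhaustive enumeration on pairs", {
  set.seed(42)
  codons <- setdiff(plastocomp:::all_codons(), c("TAA", "TAG", "TGA"))
  pairs <- cbind(sample(codons, 60, TRUE), sample(codons, 60, TRUE))
  for (q in seq_len(nrow(pairs))) {
    got <- plastocomp:::codon_pair_diffs(pairs[q, 1], pairs[q, 2])
    want <- oracle_pair_diffs(pairs[q, 1], pairs[q, 2])
    expect_equal(got[["sd"]], want[["sd"]], tolerance = 1e-12)
    expect_equal(got[["nd"]], want[["nd"]], tolerance = 1e-12)
  }
})

test_that("synonymous-only 30-codon pair: Ka = 0, Ks equals the oracle", {
  set.seed(43)
  syn_subs <- list(c("TTT", "TTC"), c("CTA", "CTG"), c("GGA", "GGT"),
                   c("CCA", "CCG"), c("ACT", "ACC"))
  a <- character(30); b <- character(30)
  for (i in 1:30) {
    if (i %% 5 == 0) {
      pr <- syn_subs[[sample(5, 1)]]
      a[i] <- pr[1]; b[i] <- pr[2]
    } else {
      a[i] <- b[i] <- sample(setdiff(plastocomp:::all_codons(),
                                     c("TAA", "TAG", "TGA")), 1)
    }
  }
  A <- paste(a, collapse = ""); B <- paste(b, collapse = "")
  r <- kaks_ng86(A, B)
  o <- oracle_ng86(A, B)
  expect_equal(r$ka, 0)
  expect_equal(r$ks, o$ks, tolerance = 1e-12)
  expect_equal(r$n_sites + r$s_sites, 3 * r$codons)
  # symmetry
  r2 <- kaks_ng86(B, A)
  expect_equal(r$ka, r2$ka)
  expect_equal(r$ks, r2$ks)
})

test_that("NG86 guards: internal stop, length mismatch, JC small-p limit", {
  expect_error(kaks_ng86("ATGTAAAAG", "ATGAAAAAG"), "codon 2")
  expect_error(kaks_ng86("ATGAAA", "ATGAAAAAG"), "mismatch")
  # JC correction reduces to p as p -> 0
  p <- 1e-6
  jc <- -0.75 * log(1 - 4 * p / 3)
  expect_lt(abs(jc - p), 1e-9)
})
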