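partition_length_of <- function(part) {
  sum(vapply(c("lsc", "irb", "ssc", "ira"),
             function(r) part[[r]][2] - part[[r]][1] + 1, numeric(1)))
}

rand_dna_fixed <- function(n) {
  set.seed(7)
  rand_dna(n)
}

make_gb <- function(lines, seq) {
  path <- tempfile(fileext = ".gb")
  n <- nchar(seq)
  body <- c(sprintf("LOCUS       TOY%06d %d bp    DNA     circular PLN", n, n),
            "FEATURES             Location/Qualifiers",
            sprintf("     source          1..%d", n),
            lines,
            "ORIGIN")
  starts <- seq(1L, n, by = 60L)
  for (s in starts) {
    body <- c(body, sprintf("%9d %s", s,
                            tolower(substring(seq, s, min(s + 59L, n)))))
  }
  writeLines(c(body, "//"), path)
  path
}

test_that("read_genbank captures compound CDS locations and the sequence", {
  set.seed(42)
  seq <- rand_dna(300)
  path <- make_gb(c("     CDS             join(11..40,61..99)",
                    '                     /gene="toyA"'), seq)
  p <- read_genbank(path)
  expect_s3_class(p, "plastome")
  expect_equal(p$sequence, toupper(seq))
  expect_true(p$circular)
  cds <- Filter(function(f) f$kind == "CDS", p$features)
  expect_length(cds, 1L)
  expect_equal(nrow(cds[[1]]$parts), 2L)
  expect_equal(unname(cds[[1]]$parts[, "start"]), c(11L, 61L))
  expect_equal(cds[[1]]$name, "toyA")
})

test_that("trans-spliced order() locations set the trans_spliced flag", {
  set.seed(43)
  seq <- rand_dna(400)
  path <- make_gb(c("     CDS             order(21..50,201..260,301..330)",
                    '                     /gene="rps12"'), seq)
  p <- read_genbank(path)
  cds <- Filter(function(f) f$kind == "CDS", p$features)[[1]]
  expect_true(cds$trans_spliced)
  expect_equal(nrow(cds$parts), 3L)
})

test_that("a feature interval beyond the sequence is a validation error", {
  set.seed(44)
  seq <- rand_dna(200)
  path <- make_gb(c("     CDS             150..260",
                    '                     /gene="bad"'), seq)
  expect_error(read_genbank(path), "bad")
})

test_that("a record without ORIGIN is a parse error", {
  path <- tempfile(fileext = ".gb")
  writeLines(c("LOCUS       X 10 bp", "FEATURES", "//"), path)
  expect_error(read_genbank(path), "ORIGIN")
})

test_that("write_genbank round-trips through read_genbank", {
  set.seed(45)
  p <- plastome("rt1", rand_dna(500), features = list(
    feature("gA", "CDS", "+", cbind(c(31L, 101L), c(90L, 160L))),
    feature("tB", "tRNA", "-", cbind(301L, 372L)),
    feature("gC", "CDS", "-", cbind(401L, 460L), codon_start = 2L)))
  path <- tempfile(fileext = ".gb")
  write_genbank(p, path)
  q <- read_genbank(path)
  expect_equal(q$sequence, p$sequence)
  expect_equal(length(q$features), length(p$features))
  expect_equal(q$features[[1]]$parts, p$features[[1]]$parts)
  expect_equal(q$features[[2]]$strand, "-")
  expect_equal(q$features[[3]]$codon_start, 2L)
})

test_that("gc_content follows its closed form and rejects all-N input", {
  expect_equal(gc_content(plastome("a", "ATGC")), 50)
  expect_equal(gc_content(plastome("b", "AAAA")), 0)
  expect_equal(gc_content(plastome("c", "ATGCN")), 50) # N out of denominator
  expect_error(gc_content(plastome("d", "NNNN")), "all N")
})

test_that("detect_quadripartite errors when no inverted pair exists", {
  set.seed(46)
  p <- plastome("noir", rand_dna(2000))
  expect_error(detect_quadripartite(p, min_ir_len = 300), "no-IR")
})

test_that("planted IR recovery matches the brute-force inverted-repeat oracle", {
  for (s in 1:25) {
    set.seed(100 + s)
    irb <- rand_dna(300)
    g <- paste0(rand_dna(1000), irb, rand_dna(200), revcomp(irb))
    p <- plastome(sprintf("ir%d", s), g)
    part <- detect_quadripartite(p, min_ir_len = 250)
    o <- oracle_max_inverted(g, 250)
    expect_equal(unname(part$irb[1]), o$s1)
    expect_equal(unname(part$ira[1]), o$s2)
    expect_equal(part$ir_length, o$len)
    expect_equal(part$mismatches, 0L)
    # partition covers the sequence
    expect_equal(partition_length_of(part), nchar(g))
  }
})

test_that("extract_loci orients genes, names intergenic gaps, finds introns", {
  seq <- paste0(strrep("N", 10), "ATGAAATGA", strrep("C", 25), "GGGTTTCCC",
                strrep("A", 5))
  seq <- chartr("N", "T", seq)
  p <- plastome("loci", seq, features = list(
    feature("geneA", "CDS", "+", cbind(11L, 19L)),
    feature("geneB", "tRNA", "-", cbind(45L, 53L))))
  part <- structure(list(lsc = c(1L, 40L), irb = c(41L, 48L),
                         ssc = c(49L, 50L), ira = c(51L, 58L),
                         ir_length = 8L, mismatches = 0L),
                    class = "region_partition")
  loci <- extract_loci(p, part)
  expect_equal(loci$sequence[loci$locus == "geneA"], "ATGAAATGA")
  expect_equal(loci$sequence[loci$locus == "geneB"],
               revcomp(substring(seq, 45, 53)))
  ig <- loci[loci$class == "intergenic", ]
  expect_equal(ig$locus, "geneA-geneB")
  expect_equal(ig$end - ig$start + 1L, 25L)
  # intron from a two-part feature
  p2 <- plastome("loci2", rand_dna_fixed(60), features = list(
    feature("geneC", "CDS", "+", cbind(c(5L, 31L), c(16L, 45L)))))
  loci2 <- extract_loci(p2, NULL)
  expect_true("geneC.intron1" %in% loci2$locus)
  expect_equal(loci2$start[loci2$class == "intron"], 17L)
  expect_equal(loci2$end[loci2$class == "intron"], 30L)
})

test_that("junction distances: boundary contact is 0, straddles report flanks", {
  set.seed(48)
  irb <- rand_dna(300)
  g <- paste0(rand_dna(1000), irb, rand_dna(200), revcomp(irb))
  feats <- list(
    feature("endsAtJ", "gene", "+", cbind(950L, 1000L)),     # ends at LSC/IRB
    feature("straddler", "gene", "+", cbind(1293L, 1320L)))  # crosses IRB/SSC
  p <- plastome("jx", g, features = feats)
  part <- detect_quadripartite(p, min_ir_len = 250)
  jr <- junction_distances(p, part)
  r0 <- jr[jr$gene == "endsAtJ" & jr$junction == "LSC/IRB", ]
  expect_equal(r0$distance[1], 0)
  expect_equal(r0$side[1], "inside-SC")
  rs <- jr[jr$gene == "straddler" & jr$side == "straddling", ]
  expect_equal(nrow(rs), 1L)
  expect_equal(rs$overhang_left + rs$overhang_right, 1320 - 1293 + 1)
  expect_equal(rs$overhang_left, 1300 - 1293 + 1)
})

test_that("BED export is 0-based half-open and round-trips", {
  items <- data.frame(start = c(1L, 151L), end = c(150L, 700L),
                      name = c("a", "b"))
  path <- tempfile(fileext = ".bed")
  write_tracks(items, path, "BED", chrom = "chr")
  lines <- readLines(path)
  expect_equal(lines[2], "chr\t0\t150\ta")
  back <- read_bed_track(path)
  expect_equal(back$start, items$start)
  expect_equal(back$end, items$end)
  # round-trip is byte-identical
  path2 <- tempfile(fileext = ".bed")
  write_tracks(back[, c("start", "end", "name")], path2, "BED", chrom = "chr")
  expect_identical(readLines(path), readLines(path2))
  # empty input -> header-only file
  path3 <- tempfile(fileext = ".bed")
  write_tracks(items[0, ], path3, "BED", chrom = "chr")
  expect_length(readLines(path3), 1L)
})
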