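# plant an array into a background with period-breaking flanks so the
# planted coordinates are exactly recoverable
plant <- function(bg, arr, at, u) {
  ch <- chars(bg)
  len <- nchar(arr)
  ch[at:(at + len - 1L)] <- chars(arr)
  alt <- function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1L)
  if (at > 1L) ch[at - 1L] <- alt(ch[at - 1L + u])
  if (at + len <= length(ch)) ch[at + len] <- alt(ch[at + len - u])
  paste(ch, collapse = "")
}

test_that("SSR copy-number minima are hard thresholds", {
  set.seed(1)
  bg <- rand_dna(120)
  s9 <- plant(bg, strrep("A", 9), 40, 1L)
  expect_equal(nrow(find_ssrs(s9)), 0L)
  s10 <- plant(bg, strrep("A", 10), 40, 1L)
  h <- find_ssrs(s10)
  expect_equal(nrow(h), 1L)
  expect_equal(h$motif, "A")
  expect_equal(h$copies, 10)
  expect_equal(h$ssr_class, "p1")
  expect_equal(h$start, 40L)
})

test_that("two SSRs 30 bp apart: simple when unjoined, composite by default", {
  set.seed(2)
  bg <- rand_dna(80)
  s <- plant(bg, strrep("AT", 6), 5, 2L)
  s <- plant(s, strrep("T", 11), 47, 1L)
  simple <- find_ssrs(s, join_dist = -1L)
  expect_equal(nrow(simple), 2L)
  expect_equal(simple$motif, c("AT", "T"))
  expect_equal(simple$start, c(5L, 47L))
  expect_equal(simple$end, c(16L, 57L))
  o <- oracle_simple_ssrs(s)
  expect_equal(simple[, c("motif", "start", "end", "copies")],
               o[, c("motif", "start", "end", "copies")],
               ignore_attr = TRUE)
  joined <- find_ssrs(s)  # spacer 30 <= 100 -> composite
  expect_equal(joined$ssr_class, "composite")
  expect_match(joined$components, "AT:5-16;T:47-57")
})

test_that("SSR detector equals the loop oracle on planted strings", {
  for (s in 1:30) {
    set.seed(300 + s)
    bg <- rand_dna(300)
    x <- plant(bg, strrep(c("A", "T", "C")[1 + s %% 3], 10 + s %% 4), 30, 1L)
    x <- plant(x, strrep("AT", 6 + s %% 3), 150, 2L)
    if (s %% 2 == 0) x <- plant(x, strrep("AAG", 5), 240, 3L)
    got <- find_ssrs(x, join_dist = -1L)
    want <- oracle_simple_ssrs(x)
    expect_equal(got[, c("motif", "start", "end", "copies", "ssr_class")],
                 want, ignore_attr = TRUE)
  }
})

test_that("perfect fractional-copy tandem array is found exactly", {
  h <- find_tandem_repeats("ACGTACGTACGTACG", unit_min = 2, unit_max = 8)
  expect_equal(nrow(h), 1L)
  expect_equal(h$unit, "ACGT")
  expect_equal(h$copies, 3.75)
  expect_equal(h$identity, 100)
  expect_equal(c(h$start, h$end), c(1L, 15L))
})

test_that("an oracle-certified repeat-free string yields no tandem hits", {
  set.seed(3)
  repeat {
    x <- rand_dna(500)
    if (nrow(oracle_tandems(x, 7, 20)) == 0L) break
  }
  expect_equal(nrow(find_tandem_repeats(x, 7, 20)), 0L)
})

test_that("one substitution in a 3x10-mer array: copies 3, identity 29/30", {
  u <- "ACGTTGCAAG"
  arr <- strrep(u, 3)
  substring(arr, 15, 15) <- "C"  # A -> C in the middle copy
  # flanks break the period for >= 3 positions on each side, so the array
  # cannot creep into the background
  x <- paste0("TTTTT", arr, "CAAAA")
  h <- find_tandem_repeats(x, unit_min = 7, unit_max = 15)
  h <- h[h$start == 6L, ]
  expect_equal(nrow(h), 1L)
  expect_equal(h$copies, 3)
  expect_equal(h$identity, round(100 * 29 / 30, 4))
  expect_equal(h$unit, u)
})

test_that("tandem detector equals the brute-force oracle on planted strings", {
  for (s in 1:40) {
    set.seed(400 + s)
    u_len <- sample(3:10, 1)
    unit <- rand_dna(u_len)
    copies <- sample(2:4, 1)
    arr <- strrep(unit, copies)
    if (nchar(arr) >= 12 && s %% 2 == 0) {
      p <- sample(nchar(arr), 1)
      substring(arr, p, p) <- sample(c("A", "C", "G", "T"), 1)
    }
    x <- plant(rand_dna(120), arr, sample(20:60, 1), u_len)
    got <- find_tandem_repeats(x, unit_min = 3, unit_max = 12)
    want <- oracle_tandems(x, 3, 12)
    want$identity <- round(want$identity, 4)
    expect_equal(got, want, tolerance = 1e-6, ignore_attr = TRUE)
  }
})

test_that("raising the tandem identity threshold never adds hits", {
  set.seed(5)
  x <- plant(rand_dna(200), strrep("ACGTTGC", 4), 50, 7L)
  lo <- find_tandem_repeats(x, 3, 20, min_identity = 80)
  hi <- find_tandem_repeats(x, 3, 20, min_identity = 95)
  expect_lte(nrow(hi), nrow(lo))
})

test_that("planted exact and palindromic 21-mers are classified correctly", {
  set.seed(6)
  word <- rand_dna(21)
  repeat {  # background certified free of >= 21 bp repeat structure
    bg <- rand_dna(260)
    if (nrow(oracle_dispersed(bg, 21, 2)) == 0L) break
  }
  x <- paste0(substring(bg, 1, 9), word, substring(bg, 31, 199), word,
              substring(bg, 221, 260))
  h <- find_dispersed_repeats(x, 21, 2)
  # a forward pair covering the planted copies (maximal windows may extend
  # a little into the background within the Hamming budget)
  fw <- h[h$kind == "forward", ]
  expect_gte(nrow(fw), 1L)
  expect_true(any(fw$pos1 <= 10 & fw$pos1 + fw$len - 1 >= 30 &
                    fw$pos2 <= 200 & fw$pos2 + fw$len - 1 >= 220))
  expect_equal(h, oracle_dispersed(x, 21, 2), ignore_attr = TRUE)
  x2 <- paste0(substring(bg, 1, 9), word, substring(bg, 31, 199),
               revcomp(word), substring(bg, 221, 260))
  h2 <- find_dispersed_repeats(x2, 21, 2)
  expect_true(any(h2$kind == "palindromic" & h2$len >= 21))
  expect_equal(h2, oracle_dispersed(x2, 21, 2), ignore_attr = TRUE)
})

test_that("a 20 bp exact duplicate stays below the length threshold", {
  set.seed(7)
  word <- rand_dna(20)
  repeat {
    bg <- rand_dna(200)
    if (nrow(oracle_dispersed(bg, 20, 0)) == 0L) break
  }
  x <- paste0(substring(bg, 1, 20), word, substring(bg, 41, 160), word,
              substring(bg, 181, 200))
  expect_equal(nrow(find_dispersed_repeats(x, 21, 2)),
               nrow(oracle_dispersed(x, 21, 2)))
  got20 <- find_dispersed_repeats(x, 20, 2)
  expect_true(any(got20$len >= 20))
})

test_that("dispersed detection is reverse-complement equivariant", {
  set.seed(8)
  word <- rand_dna(25)
  x <- paste0(rand_dna(30), word, rand_dna(80), word, rand_dna(20),
              revcomp(word), rand_dna(15))
  n <- nchar(x)
  h1 <- find_dispersed_repeats(x, 21, 2)
  h2 <- find_dispersed_repeats(revcomp(x), 21, 2)
  expect_equal(nrow(h1), nrow(h2))
  expect_equal(sort(table(h1$kind)), sort(table(h2$kind)))
  # forward pair coordinates reflect
  f1 <- h1[h1$kind == "forward", ]
  f2 <- h2[h2$kind == "forward", ]
  refl1 <- sort(n - (f1$pos2 + f1$len - 1) + 1)
  expect_equal(refl1, sort(f2$pos1))
})

test_that("classify_locations assigns by midpoint and conserves totals", {
  set.seed(9)
  irb <- rand_dna(300)
  g <- paste0(rand_dna(1000), irb, rand_dna(200), revcomp(irb))
  p <- plastome("cl", g, features = list(
    feature("gA", "CDS", "+", cbind(101L, 400L))))
  part <- detect_quadripartite(p, min_ir_len = 250)
  hits <- data.frame(start = c(150L, 500L, 990L, 1100L),
                     end = c(170L, 520L, 1008L, 1120L))
  cl <- classify_locations(hits, part, p)
  expect_equal(sum(cl$counts), nrow(hits))
  expect_equal(cl$assignments$context[1], "CDS")
  expect_equal(cl$assignments$region[1], "LSC")
  # hit straddling LSC/IRB with midpoint in LSC stays LSC and is flagged
  expect_equal(cl$assignments$region[3], "LSC")
  expect_true(cl$assignments$straddles_junction[3])
  expect_equal(cl$assignments$region[4], "IR")
})
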