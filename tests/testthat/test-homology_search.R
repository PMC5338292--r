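test_that("Karlin-Altschul bookkeeping", {
  p <- search_params()
  # S = 0: S' = -ln(0.41)/ln 2
  expect_equal(raw_to_bitscore(0, p), -log(0.41) / log(2),
               tolerance = 1e-12)
  expect_equal(raw_to_bitscore(0, p), 1.2863, tolerance = 1e-4)
  # S' = 40, m = n = 1e4: E = 1e8 * 2^-40
  expect_equal(bitscore_to_evalue(40, 1e4, 1e4), 1e8 * 2^-40,
               tolerance = 1e-12)
  expect_equal(bitscore_to_evalue(40, 1e4, 1e4), 9.09e-5,
               tolerance = 1e-3)
  # monotone in S; evalue linear in m
  expect_true(all(diff(raw_to_bitscore(0:50, p)) > 0))
  expect_equal(bitscore_to_evalue(30, 2e4, 1e4),
               2 * bitscore_to_evalue(30, 1e4, 1e4))
})

test_that("self-alignment reports one full-length 100% hit", {
  set.seed(42)
  s <- rnd_seq(1000)
  h <- find_hits(s, s, search_params())
  expect_equal(nrow(h), 1L)
  expect_equal(h$pident, 100)
  expect_equal(c(h$qstart, h$qend, h$sstart, h$send), c(1, 1000, 1, 1000))
})

test_that("a planted exact repeat is found at its coordinates", {
  set.seed(7)
  bg1 <- rnd_seq(10000); bg2 <- rnd_seq(10000); r <- rnd_seq(300)
  q <- paste0(substr(bg1, 1, 4000), r, substr(bg1, 4301, 10000))
  s <- paste0(substr(bg2, 1, 7000), r, substr(bg2, 7301, 10000))
  h <- find_hits(q, s, search_params())
  expect_equal(nrow(h), 1L)
  # oracle: the planted coordinates (local alignment may extend a few
  # bases into chance matches at the edges)
  expect_gte(reciprocal_overlap(h$qstart, h$qend, 4001, 4300), 0.97)
  expect_gte(reciprocal_overlap(min(h$sstart, h$send),
                                max(h$sstart, h$send), 7001, 7300), 0.97)

  # same repeat reverse-complemented: minus-strand hit
  s2 <- paste0(substr(bg2, 1, 7000),
               orgHGT:::revcomp(r), substr(bg2, 7301, 10000))
  h2 <- find_hits(q, s2, search_params())
  expect_equal(nrow(h2), 1L)
  expect_gt(h2$sstart, h2$send)
})

test_that("strand symmetry: searching the revcomp mirrors coordinates", {
  set.seed(19)
  bg1 <- rnd_seq(6000); bg2 <- rnd_seq(6000); r <- rnd_seq(400)
  q <- paste0(substr(bg1, 1, 2000), r, substr(bg1, 2401, 6000))
  s <- paste0(substr(bg2, 1, 3000), r, substr(bg2, 3401, 6000))
  h <- find_hits(q, s, search_params())
  hr <- find_hits(q, orgHGT:::revcomp(s), search_params())
  expect_equal(nrow(h), nrow(hr))
  L <- nchar(s)
  expect_setequal(L - hr$sstart + 1L, h$sstart)
  expect_setequal(L - hr$send + 1L, h$send)
  expect_equal(sort(h$bitscore), sort(hr$bitscore))
})

test_that("planted-homology recovery across lengths and divergences", {
  set.seed(101)
  n_trials <- 100L
  ok <- 0L
  for (i in seq_len(n_trials)) {
    L <- sample(200:2000, 1)
    d <- runif(1, 0, 0.15)
    bg1 <- rnd_seq(10000); bg2 <- rnd_seq(10000); r <- rnd_seq(L)
    qs <- sample(1000:7000, 1); ss <- sample(1000:7000, 1)
    q <- paste0(substr(bg1, 1, qs), r, substr(bg1, qs + 1, 10000))
    s <- paste0(substr(bg2, 1, ss), mutate_seq(r, d),
                substr(bg2, ss + 1, 10000))
    h <- find_hits(q, s, search_params())
    if (nrow(h) &&
        max(reciprocal_overlap(h$qstart, h$qend, qs + 1, qs + L)) >= 0.9)
      ok <- ok + 1L
  }
  expect_gte(ok / n_trials, 0.95)
})

test_that("no reported hit exceeds the E-value ceiling", {
  set.seed(5)
  q <- rnd_seq(5000); s <- rnd_seq(5000)
  ins <- rnd_seq(250)
  q2 <- paste0(substr(q, 1, 2000), ins, substr(q, 2001, 5000))
  s2 <- paste0(substr(s, 1, 900), mutate_seq(ins, 0.1),
               substr(s, 901, 5000))
  for (w in c(7L, 11L, 20L)) {
    h <- find_hits(q2, s2, search_params(word_size = w))
    expect_true(all(h$evalue <= 1e-10))
    expect_true(all(h$pident >= 0 & h$pident <= 100))
  }
})

test_that("word size larger than a sequence warns and returns nothing", {
  expect_warning(h <- find_hits("ACGTACGTAC", rnd_seq(100),
                                search_params(word_size = 20L)),
                 "word_size")
  expect_equal(nrow(h), 0L)
})

test_that("reported identity matches an independent recount", {
  # plant a repeat with known divergence; recount identity from the
  # per-base comparison of the planted copies restricted to the
  # reported interval
  set.seed(23)
  r <- rnd_seq(600)
  r2 <- mutate_seq(r, 0.05)
  q <- paste0(rnd_seq(2000), r, rnd_seq(2000))
  s <- paste0(rnd_seq(3000), r2, rnd_seq(1000))
  h <- find_hits(q, s, search_params())
  expect_equal(nrow(h), 1L)
  # no indels were introduced, so the alignment is gapless over the
  # planted interval and identity equals the planted base agreement
  a <- strsplit(substr(q, h$qstart, h$qend), "")[[1]]
  b <- strsplit(substr(s, min(h$sstart, h$send),
                       max(h$sstart, h$send)), "")[[1]]
  expect_equal(h$gapopen, 0L)
  expect_equal(h$pident, 100 * mean(a == b), tolerance = 0.011)
})
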