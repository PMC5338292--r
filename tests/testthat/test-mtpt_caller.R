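test_that("hit filter applies strict >200 bp and >70% boundaries", {
  h <- rbind(make_hit(1000, 1199),           # span 200 -> removed
             make_hit(2000, 2200),           # span 201 -> kept
             make_hit(3000, 3500, pident = 70.0),  # removed
             make_hit(4000, 4500, pident = 70.1))  # kept
  f <- filter_hits(h)
  expect_equal(f$qstart, c(2000, 4000))
  expect_equal(nrow(filter_hits(h[0, ])), 0L)
})

test_that("ancient-homology exclusion drops 1 bp overlaps, keeps adjacency", {
  feats <- data.frame(name = c("rrn18", "cox1"), start = c(5000L, 9000L),
                      end = c(6200L, 9900L), strand = "+", kind = "gene")
  h <- rbind(make_hit(4000, 5000),   # 1 bp overlap with rrn18 -> dropped
             make_hit(3000, 4999),   # adjacent -> kept
             make_hit(9100, 9500))   # cox1 not blacklisted -> kept
  out <- exclude_ancient(h, feats)
  expect_equal(out$qstart, c(3000, 9100))
  # configurable blacklist
  out2 <- exclude_ancient(h, feats, blacklist = c("rrn18", "cox1"))
  expect_equal(out2$qstart, 3000)
  # absent blacklist gene is a logged no-op
  expect_message(out3 <- exclude_ancient(h, feats,
                                         blacklist = c("rrn16")),
                 "absent")
  expect_equal(nrow(out3), 3L)
})

test_that("merging follows the gap < 100 bp rule at its boundaries", {
  m <- merge_mtpts(rbind(make_hit(1000, 1300), make_hit(1390, 1700)))
  expect_equal(nrow(m), 1L)            # gap 89 -> one call
  expect_equal(c(m$start, m$end), c(1000, 1700))

  m <- merge_mtpts(rbind(make_hit(1000, 1300), make_hit(1400, 1700)))
  expect_equal(nrow(m), 1L)            # gap 99 -> merged

  m <- merge_mtpts(rbind(make_hit(1000, 1300), make_hit(1401, 1700)))
  expect_equal(nrow(m), 2L)            # gap 100 -> two calls
  expect_equal(m$length, c(301L, 300L))
})

test_that("merging is order-invariant, idempotent and matches the oracle", {
  set.seed(31)
  for (i in 1:200) {
    n <- sample(2:12, 1)
    starts <- sample(1:20000, n)
    ends <- starts + sample(201:2000, n, replace = TRUE)
    h <- do.call(rbind, lapply(seq_len(n), function(j)
      make_hit(starts[j], ends[j])))
    m <- merge_mtpts(h)
    orc <- merge_oracle(starts, ends)
    expect_equal(m$start, orc$s)
    expect_equal(m$end, orc$e)
    # order invariance
    m2 <- merge_mtpts(h[sample(n), ])
    expect_equal(m2$start, m$start)
    expect_equal(m2$end, m$end)
    # output gaps all >= 100
    if (nrow(m) > 1)
      expect_true(all(m$start[-1] - m$end[-nrow(m)] - 1L >= 100L))
    # envelope contains all supporting hits
    expect_true(all(vapply(seq_len(nrow(m)), function(k) {
      hh <- m$hits[[k]]
      all(hh$qstart >= m$start[k] & hh$qend <= m$end[k])
    }, logical(1))))
  }
})

test_that("gene content is read off the plastid subject intervals", {
  sf <- data.frame(seqid = "s", name = c("psbA", "rbcL"),
                   start = c(100L, 2000L), end = c(1100L, 3300L),
                   strand = "+", kind = "gene")
  h <- make_hit(5000, 5900, sstart = 900, send = 1800)
  m <- merge_mtpts(h, subject_features = sf)
  expect_equal(m$gene_content[[1]], "psbA")
})

test_that("per-genome statistics", {
  empty <- merge_mtpts(make_hit(1, 1)[0, ])
  st <- genome_stats(empty, 10000)
  expect_equal(st$n_mtpts, 0L)
  expect_equal(st$pct_mtdna, 0)

  one <- merge_mtpts(make_hit(2000, 3037))  # 1038 bp in 10 kb = 10.38%
  st <- genome_stats(one, 10000)
  expect_equal(st$pct_mtdna, 10.38)

  overlapping <- rbind(merge_mtpts(make_hit(100, 500)),
                       merge_mtpts(make_hit(400, 900)))
  expect_error(genome_stats(overlapping, 10000))
})

test_that("spearman matches the rank-then-Pearson oracle", {
  # deterministic cases
  s <- spearman_test(1:10, (1:10)^3)
  expect_equal(s$rho, 1)
  expect_lt(s$p_value, 1e-10)

  s <- spearman_test(c(1, 2, 3, 4, 5), c(2, 1, 4, 3, 5))
  expect_equal(s$rho, cor(rank(c(1, 2, 3, 4, 5)),
                          rank(c(2, 1, 4, 3, 5))))

  expect_true(spearman_test(1:5, rep(7, 5))$undefined)

  # oracle sweep with ties
  set.seed(13)
  for (i in 1:200) {
    n <- sample(4:30, 1)
    x <- sample(1:8, n, replace = TRUE)
    y <- sample(1:8, n, replace = TRUE)
    if (var(rank(x)) == 0 || var(rank(y)) == 0) next
    expect_equal(spearman_test(x, y)$rho, cor(rank(x), rank(y)),
                 tolerance = 1e-12)
  }
})

test_that("exact permutation p-value equals the brute-force enumeration", {
  set.seed(17)
  x <- c(3, 1, 4, 1, 5)
  y <- c(9, 2, 6, 5, 3)
  s <- spearman_test(x, y, exact = TRUE)
  perms <- orgHGT:::.permutations(5)
  rhos <- apply(perms, 1, function(p) cor(rank(x), rank(y)[p]))
  expect_equal(s$p_value, mean(abs(rhos) >= abs(s$rho) - 1e-12))
  expect_error(spearman_test(1:12, 12:1, exact = TRUE), "n <= 10")
})
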