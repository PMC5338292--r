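small_cfg <- function(...) {
  defaults <- list(n_species = 5L, mt_length = 45000L,
                   pt_length = 12000L, n_native_mtpt = 2L,
                   n_mt2mt_events = 1L, n_pt2mt_events = 1L)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

test_that("the species tree is seeded, scaled and ultrametric", {
  cfg <- sim_config(seed = 5, n_species = 4)
  t1 <- simulate_species_tree(cfg)
  t2 <- simulate_species_tree(cfg)
  expect_identical(ape::write.tree(t1), ape::write.tree(t2))
  expect_true(all(t1$edge.length > 0))
  depths <- ape::node.depth.edgelength(t1)[1:4]
  expect_true(all(abs(depths - cfg$tree_height) < 1e-9))  # ultrametric
  expect_equal(max(depths), cfg$tree_height)
})

test_that("identical configs give bit-identical corpora", {
  cfg <- small_cfg(seed = 8)
  c1 <- simulate_corpus(cfg)
  c2 <- simulate_corpus(cfg)
  expect_identical(lapply(c1$genomes, function(g) g$mt$sequence),
                   lapply(c2$genomes, function(g) g$mt$sequence))
  expect_identical(c1$truth, c2$truth)
})

test_that("zero tree height leaves all species identical to the root", {
  cfg <- small_cfg(seed = 4, tree_height = 0,
                   n_native_mtpt = 0L, n_mt2mt_events = 0L,
                   n_pt2mt_events = 0L)
  corpus <- simulate_corpus(cfg)
  seqs <- vapply(corpus$genomes, function(g) g$mt$sequence, character(1))
  expect_equal(length(unique(seqs)), 1L)
  expect_equal(nrow(corpus$truth), 0L)
})

test_that("branch substitution counts match the analytic expectation", {
  set.seed(21)
  cfg <- sim_config(pt_intergenic_rate = 1, indel_rate = 0)
  seq <- strsplit(rnd_seq(10000), "")[[1]]
  feats <- orgHGT:::empty_features()
  out <- orgHGT:::.mutate_branch(seq, feats, 0.1, cfg, "pt")
  # expected 1000 mutation events; with HKY back-substitution the
  # observed difference count is slightly below the event count
  n_events <- 10000 * 0.1
  sigma <- sqrt(n_events)
  diffs <- sum(out$seq != seq)
  expect_lt(abs(diffs - n_events), 4 * sigma + 0.05 * n_events)
  expect_gt(diffs, 0)
})

test_that("conserved loci remain cross-compartment detectable at full height", {
  cfg <- small_cfg(seed = 6, n_native_mtpt = 0L, n_mt2mt_events = 0L,
                   n_pt2mt_events = 0L)
  corpus <- simulate_corpus(cfg)
  g <- corpus$genomes[[1]]
  h <- find_hits(g$mt, g$pt, search_params())
  atp1 <- g$mt$features[g$mt$features$name == "atp1", ]
  expect_true(any(interval_overlap(h$qstart, h$qend,
                                   atp1$start, atp1$end) > 500))
})

test_that("implanted intervals trace back to their sources", {
  cfg <- small_cfg(seed = 9)
  corpus <- simulate_corpus(cfg)
  tr <- corpus$truth
  expect_gt(nrow(tr), 0L)
  for (i in seq_len(nrow(tr))) {
    ins <- substr(corpus$genomes[[tr$recipient[i]]]$mt$sequence,
                  tr$mt_start[i], tr$mt_end[i])
    src <- substr(corpus$genomes[[tr$donor[i]]]$pt$sequence,
                  tr$src_start[i], tr$src_end[i])
    expect_equal(nchar(ins), nchar(src))
    ident <- mean(strsplit(ins, "")[[1]] == strsplit(src, "")[[1]])
    # one or two rounds of divergence_at_transfer, allow 3 sigma
    n_rounds <- if (tr$type[i] == "mt2mt_hgt") 2 else 1
    d <- n_rounds * cfg$divergence_at_transfer
    expect_gt(ident, 1 - d - 3 * sqrt(d / nchar(ins)) - 0.02)
  }
})

test_that("mt2mt tracts surround the MTPT with donor sequence", {
  cfg <- small_cfg(seed = 10)
  corpus <- simulate_corpus(cfg)
  ev <- corpus$truth[corpus$truth$type == "mt2mt_hgt", ][1, ]
  expect_false(is.na(ev$tract_start))
  # both 1 kb windows flanking the MTPT lie inside the tract
  expect_lte(ev$tract_start, ev$mt_start - cfg$mt_tract_padding)
  expect_gte(ev$tract_end, ev$mt_end + cfg$mt_tract_padding)
  # the flank window sequence matches donor mitochondrial sequence
  rec <- corpus$genomes[[ev$recipient]]$mt
  don <- corpus$genomes[[ev$donor]]$mt
  flank <- substr(rec$sequence, ev$mt_start - 1000L, ev$mt_start - 1L)
  h <- find_hits(flank, don, search_params(word_size = 11L))
  expect_gt(nrow(h), 0L)
  expect_gt(max(h$qend - h$qstart + 1), 800)

  # pt2mt flanks carry no donor mitochondrial sequence
  ev2 <- corpus$truth[corpus$truth$type == "pt2mt_hgt", ][1, ]
  rec2 <- corpus$genomes[[ev2$recipient]]$mt
  don2 <- corpus$genomes[[ev2$donor]]$mt
  flank2 <- substr(rec2$sequence, ev2$mt_start - 1000L, ev2$mt_start - 1L)
  h2 <- find_hits(flank2, don2, search_params(word_size = 11L))
  expect_equal(nrow(h2), 0L)
})

test_that("zero event counts leave genomes unchanged with an empty log", {
  cfg <- small_cfg(seed = 12, n_native_mtpt = 0L, n_mt2mt_events = 0L,
                   n_pt2mt_events = 0L)
  tree <- simulate_species_tree(cfg)
  sim <- evolve_genomes(tree, cfg)
  imp <- implant_events(sim, tree, cfg)
  expect_identical(lapply(imp$genomes, function(g) g$mt$sequence),
                   lapply(sim$genomes, function(g) g$mt$sequence))
  expect_equal(nrow(imp$truth), 0L)
})

test_that("recovery scoring implements the 50% reciprocal-overlap rule", {
  truth <- data.frame(event_id = 1:2, type = c("native_igt", "pt2mt_hgt"),
                      donor = c("a", "b"), recipient = c("a", "a"),
                      mt_start = c(1000L, 5000L), mt_end = c(1999L, 5999L),
                      src_start = NA, src_end = NA,
                      tract_start = NA, tract_end = NA)
  perfect <- data.frame(mt_id = "a_mt", start = c(1000L, 5000L),
                        end = c(1999L, 5999L))
  s <- score_recovery(truth, perfect)
  expect_equal(s$recall, 1)
  expect_equal(s$precision, 1)

  s0 <- score_recovery(truth, perfect[0, ])
  expect_equal(s0$recall, 0)
  expect_true(is.na(s0$precision))

  # shifted by > 50%: counted as both FP and FN
  shifted <- data.frame(mt_id = "a_mt", start = c(1600L, 5700L),
                        end = c(2599L, 6699L))
  s2 <- score_recovery(truth, shifted)
  expect_equal(s2$recall, 0)
  expect_equal(s2$precision, 0)
})
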