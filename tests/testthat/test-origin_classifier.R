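solanales <- c("asterids", "lamiids", "Solanales")

test_that("best-hit screen separates related from unrelated lineages", {
  # recipient Solanales, best hit Rosales -> putatively foreign
  expect_true(screen_best_hit(c("rosids", "Rosales", "Cannabaceae"),
                              solanales))
  # best hit in the same order -> native screen-out
  expect_false(screen_best_hit(c("asterids", "lamiids", "Solanales",
                                 "Solanaceae"), solanales))
  # best hit to the same species' own plastome -> native
  expect_false(screen_best_hit(solanales, solanales))
  expect_warning(out <- screen_best_hit(character(0), solanales),
                 "missing lineage")
  expect_true(is.na(out))
})

test_that("alignment of identical sequences is gap-free", {
  set.seed(3)
  s <- rnd_seq(400)
  panel <- structure(list(
    focal_id = "f",
    members = data.frame(id = c("f", "a", "b"), seq = s,
                         lineage = NA, compartment = "pt")),
    class = "homolog_panel")
  panel <- build_alignment(panel)
  expect_false(any(panel$alignment == "-"))
  expect_equal(ncol(panel$alignment), 400L)
})

test_that("a single deletion shows as one gap run, as pairwise NW says", {
  set.seed(4)
  s <- rnd_seq(500)
  del <- paste0(substr(s, 1, 200), substr(s, 211, 500))
  panel <- structure(list(
    focal_id = "f",
    members = data.frame(id = c("f", "d", "c"),
                         seq = c(s, del, mutate_seq(s, 0.02)),
                         lineage = NA, compartment = "pt")),
    class = "homolog_panel")
  panel <- build_alignment(panel)
  expect_gte(ncol(panel$alignment), 500L)  # >= longest member
  runs <- rle(panel$alignment["d", ] == "-")
  expect_equal(sum(runs$values), 1L)
  expect_equal(sum(runs$lengths[runs$values]), 10L)
  # oracle: global pairwise alignment of the two sequences shows one
  # indel of width 10 (a gap in the subject is an "insertion" in
  # Biostrings' pattern-relative naming)
  pa <- Biostrings::pairwiseAlignment(s, del, type = "global")
  ind <- Biostrings::nindel(pa)@insertion
  expect_equal(unname(ind[1, "Length"]), 1)
  expect_equal(unname(ind[1, "WidthSum"]), 10)
  expect_error(build_alignment(structure(list(members = data.frame(
    id = "x", seq = "ACGT")), class = "homolog_panel")), "at least 2")
})

test_that("tree inference recovers a quartet and calibrates supports", {
  # simulate a clean alignment on ((A,B),(C,D)) with a long internal
  # edge: AB|CD must be recovered with very high support
  set.seed(9)
  anc <- rnd_seq(300)
  left <- mutate_seq(anc, 0.15); right <- mutate_seq(anc, 0.15)
  aln <- rbind(A = strsplit(mutate_seq(left, 0.02), "")[[1]],
               B = strsplit(mutate_seq(left, 0.02), "")[[1]],
               C = strsplit(mutate_seq(right, 0.02), "")[[1]],
               D = strsplit(mutate_seq(right, 0.02), "")[[1]])
  tr <- infer_tree(aln, n_bootstrap = 200, seed = 1)
  # oracle: enumerate the three quartet topologies via the four-point
  # condition on raw distances
  dm <- as.matrix(ape::dist.dna(ape::as.DNAbin(tolower(aln)),
                                model = "raw"))
  sums <- c(AB_CD = dm["A", "B"] + dm["C", "D"],
            AC_BD = dm["A", "C"] + dm["B", "D"],
            AD_BC = dm["A", "D"] + dm["B", "C"])
  expect_equal(names(which.min(sums)), "AB_CD")
  expect_true(ape::is.monophyletic(ape::root(tr, "C"), c("A", "B")))
  sup <- suppressWarnings(as.integer(tr$node.label))
  expect_gte(max(sup, na.rm = TRUE), 95L)
})

test_that("supports are invariant to row order and hit 100 without variance", {
  set.seed(10)
  anc <- rnd_seq(200)
  aln <- do.call(rbind, lapply(1:5, function(i)
    strsplit(mutate_seq(anc, 0.1), "")[[1]]))
  rownames(aln) <- letters[1:5]
  t1 <- infer_tree(aln, n_bootstrap = 50, seed = 7)
  t2 <- infer_tree(aln[sample(5), ], n_bootstrap = 50, seed = 7)
  expect_equal(ape::write.tree(t1), ape::write.tree(t2))

  # duplicated-column alignment: every replicate yields the same tree
  base <- aln[, rep(1:50, 4)]
  t3 <- infer_tree(base, n_bootstrap = 30, seed = 3)
  sup <- suppressWarnings(as.integer(t3$node.label))
  expect_true(all(sup[!is.na(sup)] == 100L))
})

test_that("placement classifies foreign, native and unresolved cases", {
  tax <- list("cann_mtpt|mtpt" = c("rosids", "Rosales", "Cannabaceae"),
              "cann_pt|pt" = c("rosids", "Rosales", "Cannabaceae"),
              "sol1|pt" = c("asterids", "lamiids", "Solanales"),
              "sol2|pt" = c("asterids", "lamiids", "Solanales"),
              "ros|pt" = c("rosids", "Fagales", "Fagaceae"))
  comps <- c("cann_mtpt|mtpt" = "mtpt", "cann_pt|pt" = "pt",
             "sol1|pt" = "pt", "sol2|pt" = "pt", "ros|pt" = "pt",
             focal = "focal")

  # focal sister to a Cannabaceae MTPT tip with support 100 -> foreign
  tr <- ape::read.tree(text = paste0(
    "(((focal:0.02,cann_mtpt|mtpt:0.02)100:0.1,cann_pt|pt:0.05)100:0.2,",
    "(sol1|pt:0.05,sol2|pt:0.05)100:0.2,ros|pt:0.3);"))
  pl <- classify_placement(tr, "focal", solanales, tax,
                           compartments = comps)
  expect_equal(pl$verdict, "foreign")
  expect_equal(pl$support, 100L)
  expect_equal(pl$donor_lineage, c("rosids", "Rosales", "Cannabaceae"))
  expect_true(pl$donor_sister_flag)

  # focal nested in its own order's plastome clade -> native
  tr2 <- ape::read.tree(text = paste0(
    "(((focal:0.02,sol1|pt:0.02)100:0.1,sol2|pt:0.05)100:0.2,",
    "(cann_pt|pt:0.05,cann_mtpt|mtpt:0.05)100:0.2,ros|pt:0.3);"))
  pl2 <- classify_placement(tr2, "focal", solanales, tax,
                            compartments = comps)
  expect_equal(pl2$verdict, "native")
  expect_false(pl2$donor_sister_flag)

  # incongruent placement at support 65 -> unresolved, never foreign
  tr3 <- ape::read.tree(text = paste0(
    "(((focal:0.02,cann_mtpt|mtpt:0.02)65:0.1,cann_pt|pt:0.05)65:0.2,",
    "(sol1|pt:0.05,sol2|pt:0.05)65:0.2,ros|pt:0.3);"))
  pl3 <- classify_placement(tr3, "focal", solanales, tax,
                            compartments = comps)
  expect_equal(pl3$verdict, "unresolved")
})

test_that("fuzzed trees never yield foreign at support <= 70", {
  set.seed(77)
  ranks <- list(c("A", "B", "C"), c("A", "B", "D"), c("E", "F", "G"),
                c("H", "I", "J"), c("K", "L", "M"))
  for (i in 1:100) {
    n <- sample(5:10, 1)
    tr <- ape::rtree(n)
    tr$tip.label <- c("focal", paste0("t", seq_len(n - 1)))
    tr$node.label <- as.character(sample(0:70, tr$Nnode, replace = TRUE))
    tax <- setNames(sample(ranks, n - 1, replace = TRUE),
                    paste0("t", seq_len(n - 1)))
    pl <- classify_placement(tr, "focal", c("A", "B", "C"), tax)
    expect_false(pl$verdict == "foreign")
  }
})
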