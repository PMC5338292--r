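test_that("FASTA reading normalizes case, U and ambiguity codes", {
  f <- withr::local_tempfile(fileext = ".fa")
  writeLines(c(">x", "acgt"), f)
  recs <- read_fasta(f)
  expect_length(recs, 1L)
  expect_equal(recs$x$sequence, "ACGT")

  writeLines(c(">r", "ACGuRYT"), f)
  expect_warning(recs <- read_fasta(f), "collapsed to N")
  expect_equal(recs$r$sequence, "ACGTNNT")

  writeLines(c(">a", "ACGT", ">a", "GGGG"), f)
  expect_error(read_fasta(f), "duplicate")

  writeLines(character(0), f)
  expect_error(read_fasta(f))
})

test_that("FASTA round-trips losslessly", {
  set.seed(1)
  f <- withr::local_tempfile(fileext = ".fa")
  recs <- list(genome_record("g1", rnd_seq(533), "mt"),
               genome_record("g2", rnd_seq(70), "pt"))
  write_fasta(recs, f)
  back <- read_fasta(f)
  expect_equal(back$g1$sequence, recs[[1]]$sequence)
  expect_equal(back$g2$sequence, recs[[2]]$sequence)
})

test_that("hit tables parse the outfmt-6 dialect", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste("q", "s", "98.0", "340", "6", "1", "29093", "29432",
                   "100", "439", "1e-100", "500", sep = "\t"), f)
  h <- read_hit_table(f)
  expect_equal(h$qstart, 29093L)
  expect_equal(h$qend, 29432L)
  expect_equal(h$length, 340L)
  expect_equal(h$qend - h$qstart + 1L, 340L)

  # minus-strand subject preserved, not rejected
  writeLines(paste("q", "s", "90", "401", "0", "0", "1", "401",
                   "500", "100", "1e-50", "300", sep = "\t"), f)
  h <- read_hit_table(f)
  expect_gt(h$sstart, h$send)

  # wrong column count names the offending line
  writeLines(c(paste(rep("1", 12), collapse = "\t"),
               paste(rep("1", 11), collapse = "\t")), f)
  expect_error(read_hit_table(f), "line 2")
})

test_that("hit tables round-trip", {
  f <- withr::local_tempfile(fileext = ".tsv")
  h <- rbind(make_hit(100, 500), make_hit(1000, 1300, 900, 600))
  write_hit_table(h, f)
  back <- read_hit_table(f)
  expect_equal(back$qstart, h$qstart)
  expect_equal(back$sstart, h$sstart)
  expect_equal(back$send, h$send)
})

test_that("taxonomy parsing and lineage comparison", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("NC_026515\tasterids; lamiids; Solanales",
               "X1\tasterids; lamiids; Gentianales",
               "X2\tSantalales"), f)
  tax <- read_taxonomy(f)
  expect_equal(tax$NC_026515, c("asterids", "lamiids", "Solanales"))
  expect_equal(lineage_shared_prefix(tax$NC_026515, tax$X1), 2L)
  expect_length(tax$X2, 1L)  # single-rank lineage is valid
  expect_false(lineage_related(tax$NC_026515, tax$X2))

  writeLines(c("ok\ta; b", "bad\t"), f)
  expect_error(read_taxonomy(f), "bad")
})

test_that("newick round-trips topology, lengths and supports", {
  f <- withr::local_tempfile(fileext = ".nwk")
  writeLines("((A:1,B:1)95:0.5,C:1);", f)
  tr <- read_newick(f)
  expect_s3_class(tr, "phylo")
  expect_true("95" %in% tr$node.label)
  f2 <- withr::local_tempfile(fileext = ".nwk")
  write_newick(tr, f2)
  tr2 <- read_newick(f2)
  expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                         ape::unroot(tr2))), 0)
  expect_equal(tr2$edge.length, tr$edge.length, tolerance = 1e-6)
  expect_true("95" %in% tr2$node.label)

  # unrooted 3-leaf tree accepted
  writeLines("(A:1,B:1,C:2);", f)
  expect_s3_class(read_newick(f), "phylo")

  writeLines("((A:1,B:1;", f)
  expect_error(suppressWarnings(read_newick(f)))
})

test_that("GFF3 reading keeps the consumed columns", {
  f <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\tsrc\tgene\t10\t99\t.\t+\t.\tID=g1;Name=atp1",
               "chr1\tsrc\tmtpt_annotation\t200\t300\t.\t+\t.\tID=m1",
               "chr1\tsrc\tregion\t1\t500\t.\t-\t.\tName=r1"), f)
  g <- read_gff3(f)
  expect_equal(g$name, c("atp1", "m1", "r1"))
  expect_equal(g$kind, c("gene", "mtpt_annotation", "other"))
  expect_equal(g$start, c(10L, 200L, 1L))
  f2 <- withr::local_tempfile(fileext = ".gff3")
  write_gff3(g, f2)
  g2 <- read_gff3(f2)
  expect_equal(g2$name, g$name)
  expect_equal(g2$kind, g$kind)
})

test_that("the packaged foreign-MTPT table loads with expected shape", {
  df <- read_table1()
  expect_equal(nrow(df), 46L)
  expect_true(all(c("recipient_species", "donor_lineage", "flank5_code",
                    "flank3_code", "host_parasite_flag") %in% names(df)))
  # flank verdicts are only ever yes with codes 4, 5 or 6
  codes <- c(df$flank5_code, df$flank3_code)
  codes <- codes[!is.na(codes)]
  yes_codes <- unique(sub("yes", "", codes[startsWith(codes, "yes")]))
  expect_true(all(yes_codes %in% c("4", "5", "6")))
  no_codes <- unique(sub("no", "", codes[startsWith(codes, "no")]))
  expect_true(all(no_codes %in% c("1", "2", "3", "5")))
})
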