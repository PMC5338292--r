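#' Simulation configuration for synthetic organellar corpora
#'
#' The generator emulates a sample of plant species related by a Yule
#' species tree, each carrying a circular mitochondrial and plastid
#' genome.  Both genomes descend from common root sequences; three
#' conserved loci (atp1, rrn18, rrn26) are planted as homolog pairs
#' shared between the compartments to exercise the ancient-homology
#' exclusion.  Mitochondrial intergenic sequence evolves fast (so only
#' close relatives share recognizable intergenic homology, as in real
#' plant chondromes), plastid sequence slowly (so plastid homolog
#' panels span the whole tree, as in real plastomes).
#'
#' Transfer events implanted on top of the evolved genomes:
#' `native_igt` copies a plastid segment of the same species into its
#' mitochondrion; `mt2mt_hgt` first performs that IGT in a donor
#' species and then copies the donor MTPT together with
#' `mt_tract_padding` bp of surrounding donor mitochondrial sequence
#' into a distantly related recipient; `pt2mt_hgt` copies a donor
#' plastid segment directly with no mitochondrial padding.  Event
#' counts are corpus totals; donors are drawn from the opposite major
#' clade of the tree (order-level-or-deeper donors).
#'
#' @param seed integer; fully determines the corpus.
#' @param n_species number of species (>= 4).
#' @param tree_height expected root-to-tip substitutions/site at rate 1.
#' @param mt_length,pt_length genome lengths in bp.
#' @param n_native_mtpt,n_mt2mt_events,n_pt2mt_events corpus-wide event
#'   counts.
#' @param mtpt_length_range bp interval for transferred plastid segments.
#' @param mt_tract_padding bp of donor mitochondrial sequence
#'   co-transferred on each side of the MTPT in mt-to-mt events.
#' @param divergence_at_transfer substitutions/site between the donor
#'   copy and the transferred copy.
#' @param indel_rate indel events relative to the substitution rate.
#' @param kappa HKY transition/transversion rate ratio.
#' @param conserved_rate,mt_intergenic_rate,pt_intergenic_rate relative
#'   site-rate multipliers.
#' @param gene_buffer minimal distance (bp) between an insertion point
#'   and any gene feature, so 1 kb flank windows stay gene-free.
#' @param insert_spacing minimal distance (bp) between insertion points.
#' @param ultrametric make the species tree ultrametric.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_species = 20L, tree_height = 0.2,
                       mt_length = 60000L, pt_length = 15000L,
                       n_native_mtpt = 20L, n_mt2mt_events = 30L,
                       n_pt2mt_events = 30L,
                       mtpt_length_range = c(400L, 1500L),
                       mt_tract_padding = 1500L,
                       divergence_at_transfer = 0.05,
                       indel_rate = 0.02, kappa = 2,
                       conserved_rate = 0.15, mt_intergenic_rate = 6,
                       pt_intergenic_rate = 0.8,
                       gene_buffer = 1100L, insert_spacing = 1500L,
                       ultrametric = TRUE) {
  stopifnot(n_species >= 4L, mt_length > 0L, pt_length > 0L,
            n_native_mtpt >= 0L, n_mt2mt_events >= 0L,
            n_pt2mt_events >= 0L, seed == as.integer(seed))
  structure(as.list(environment()), class = "sim_config")
}

#' Simulate the species tree
#'
#' Yule (pure-birth) topology with branch lengths rescaled so the
#' deepest root-to-tip path equals `tree_height`; rejection-sampled so
#' both root subtrees hold at least a quarter of the species (the
#' corpus needs two well-represented major clades to serve as donor and
#' recipient pools).  Tips are labelled `sp01`, `sp02`, ...
#'
#' @param config a [sim_config()].
#' @return rooted `phylo`, ultrametric unless `config$ultrametric` is
#'   FALSE.
#' @export
simulate_species_tree <- function(config) {
  set.seed(config$seed)
  n <- config$n_species
  min_side <- max(2L, floor(n / 4))
  for (i in 1:200) {
    tr <- ape::rphylo(n, birth = 1, death = 0)
    root_kids <- tr$edge[tr$edge[, 1] == n + 1L, 2]
    sizes <- vapply(root_kids, function(k)
      if (k <= n) 1L else
        length(phangorn::Descendants(tr, k, "tips")[[1]]), integer(1))
    if (min(sizes) >= min_side) break
  }
  if (!config$ultrametric) {
    tr$edge.length <- rexp(nrow(tr$edge), rate = 1)
  }
  depth <- max(ape::node.depth.edgelength(tr)[seq_len(n)])
  tr$edge.length <- if (depth > 0 && config$tree_height > 0)
    tr$edge.length * config$tree_height / depth
  else rep(0, nrow(tr$edge))
  tr$tip.label <- sprintf("sp%02d", seq_len(n))
  tr
}

#' Derive Table-1 style lineages from the species tree
#'
#' Taxonomic ranks are divergence-time bands, as in real
#' classifications: the major clade is the root split, the subclade and
#' order group tips whose most recent common ancestor is younger than a
#' fraction of the tree height (0.7 and 0.35 by default).  Two species
#' are order-level related (rank depth 3) exactly when their divergence
#' time is below the order cut — which is also roughly the horizon at
#' which fast-evolving mitochondrial intergenic homology fades, so
#' flank hits land overwhelmingly within the correct rank group.
#' Lineages look like `clade22; sub3; ord7; sp04`.
#'
#' For non-ultrametric trees the cuts fall back to mean root-to-tip
#' depth.
#'
#' @param tree rooted `phylo` from [simulate_species_tree()].
#' @param sub_frac,ord_frac height fractions for the subclade and order
#'   cuts.
#' @return named list species -> rank vector.
#' @export
build_taxonomy <- function(tree, sub_frac = 0.7, ord_frac = 0.35) {
  n <- length(tree$tip.label)
  depths <- ape::node.depth.edgelength(tree)
  height <- mean(depths[seq_len(n)])
  # time before present of each node
  age <- max(depths[seq_len(n)]) - depths
  root_kids <- tree$edge[tree$edge[, 1] == n + 1L, 2]
  clade_of <- integer(n)
  for (k in seq_along(root_kids)) {
    tips <- if (root_kids[k] <= n) root_kids[k] else
      phangorn::Descendants(tree, root_kids[k], "tips")[[1]]
    clade_of[tips] <- k
  }
  # group tips whose MRCA is younger than the cut: climb from each tip
  # to the oldest ancestor still below the cut
  group_at <- function(cut) {
    vapply(seq_len(n), function(i) {
      nd <- i
      repeat {
        par <- tree$edge[tree$edge[, 2] == nd, 1]
        if (!length(par) || age[par] > cut) break
        nd <- par
      }
      nd
    }, integer(1))
  }
  sub_of <- match(group_at(sub_frac * height),
                  unique(group_at(sub_frac * height)))
  ord_of <- match(group_at(ord_frac * height),
                  unique(group_at(ord_frac * height)))
  out <- list()
  for (i in seq_len(n))
    out[[tree$tip.label[i]]] <- c(paste0("clade", clade_of[i]),
                                  paste0("sub", sub_of[i]),
                                  paste0("ord", ord_of[i]),
                                  tree$tip.label[i])
  out
}

# conserved-locus and gene layout of the root genomes
.root_layout <- function(cfg) {
  mt_genes <- c(atp1 = 900L, rrn18 = 1200L, rrn26 = 1800L,
                cox1 = 900L, nad5 = 1200L)
  pt_genes <- c(atp1 = 900L, rrn18 = 1200L, rrn26 = 1800L,
                psbA = 1000L, rbcL = 1300L, matK = 1500L)
  stopifnot(sum(mt_genes) < cfg$mt_length, sum(pt_genes) < cfg$pt_length)
  list(mt = mt_genes, pt = pt_genes)
}

.random_chars <- function(n) sample(c("A", "C", "G", "T"), n, replace = TRUE)

# assemble a root genome: genes (some with shared sequences) separated
# by random intergenic spacers
.build_root <- function(total_len, gene_lens, shared_seqs) {
  spacer <- (total_len - sum(gene_lens)) %/% (length(gene_lens) + 1L)
  chunks <- list(); feats <- list(); pos <- 0L
  add <- function(chars) {
    chunks[[length(chunks) + 1L]] <<- chars
    pos <<- pos + length(chars)
  }
  add(.random_chars(spacer))
  for (g in names(gene_lens)) {
    s <- if (g %in% names(shared_seqs)) shared_seqs[[g]]
    else .random_chars(gene_lens[[g]])
    feats[[g]] <- data.frame(name = g, start = pos + 1L,
                             end = pos + length(s), strand = "+",
                             kind = "gene", stringsAsFactors = FALSE)
    add(s)
    add(.random_chars(spacer))
  }
  pad <- total_len - pos
  if (pad > 0L) add(.random_chars(pad))
  list(seq = unlist(chunks), features = do.call(rbind, feats))
}

# one branch of sequence evolution: HKY-like substitutions (event-based,
# so the expected substitution count on a branch of length t is
# t * sum(site rates)) plus geometric-length indels confined to
# intergenic sequence
.mutate_branch <- function(seq, features, t, cfg, compartment) {
  L <- length(seq)
  inter_rate <- if (compartment == "mt") cfg$mt_intergenic_rate
  else cfg$pt_intergenic_rate
  rates <- rep(inter_rate, L)
  for (i in seq_len(nrow(features)))
    if (features$kind[i] == "gene")
      rates[features$start[i]:features$end[i]] <- cfg$conserved_rate
  n_sub <- rpois(1L, t * sum(rates))
  if (n_sub > 0L) {
    pos <- sample.int(L, n_sub, replace = TRUE, prob = rates)
    seq[pos] <- .hky_targets(seq[pos], cfg$kappa)
  }
  n_ind <- rpois(1L, cfg$indel_rate * t * sum(rates))
  for (j in seq_len(n_ind)) {
    len <- rgeom(1L, 0.5) + 1L
    ins <- runif(1) < 0.5
    p <- 0L
    for (try in 1:20) {
      cand <- sample.int(length(seq) - len - 1L, 1L)
      clash <- any(interval_overlap(cand, cand + len,
                                    features$start - 2L,
                                    features$end + 2L) >= 1L)
      if (!clash) { p <- cand; break }
    }
    if (p == 0L) next
    if (ins) {
      seq <- append(seq, .random_chars(len), after = p)
      shift <- features$start > p
      features$start[shift] <- features$start[shift] + len
      features$end[shift] <- features$end[shift] + len
    } else {
      seq <- seq[-(p:(p + len - 1L))]
      shift <- features$start > p
      features$start[shift] <- features$start[shift] - len
      features$end[shift] <- features$end[shift] - len
    }
  }
  list(seq = seq, features = features)
}

# HKY target bases: transition with weight kappa, each transversion 1
.hky_targets <- function(current, kappa) {
  ti <- c(A = "G", G = "A", C = "T", T = "C")
  tv1 <- c(A = "C", G = "C", C = "A", T = "A")
  tv2 <- c(A = "T", G = "T", C = "G", T = "G")
  u <- runif(length(current)) * (kappa + 2)
  ifelse(u < kappa, ti[current],
         ifelse(u < kappa + 1, tv1[current], tv2[current]))
}

#' Evolve root genomes along the species tree
#'
#' Root mt/pt sequences are drawn uniformly over {A,C,G,T} around
#' planted gene features; the conserved loci atp1/rrn18/rrn26 are
#' planted with identical sequence in both compartments.  Each branch
#' applies HKY-like substitutions (conserved genes at
#' `conserved_rate`, intergenic at the compartment multiplier) and
#' geometric-length indels that avoid gene features, with annotations
#' lifted through every indel.
#'
#' @param tree from [simulate_species_tree()].
#' @param config a [sim_config()].
#' @return list: `genomes` (per species: list `mt`, `pt` of
#'   `genome_record`), `taxonomy` (ids and species -> rank vectors).
#' @export
evolve_genomes <- function(tree, config) {
  set.seed(config$seed + 1L)
  layout <- .root_layout(config)
  shared <- lapply(layout$mt[c("atp1", "rrn18", "rrn26")], .random_chars)
  root_mt <- .build_root(config$mt_length, layout$mt, shared)
  root_pt <- .build_root(config$pt_length, layout$pt, shared)
  n <- length(tree$tip.label)
  tree <- ape::reorder.phylo(tree, "cladewise")
  states <- vector("list", n + tree$Nnode)
  states[[n + 1L]] <- list(mt = root_mt, pt = root_pt)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]; child <- tree$edge[e, 2]
    t <- tree$edge.length[e]
    ps <- states[[par]]
    states[[child]] <- list(
      mt = .mutate_branch(ps$mt$seq, ps$mt$features, t, config, "mt"),
      pt = .mutate_branch(ps$pt$seq, ps$pt$features, t, config, "pt"))
  }
  spp_tax <- build_taxonomy(tree)
  genomes <- list(); taxonomy <- list()
  for (i in seq_len(n)) {
    sp <- tree$tip.label[i]
    st <- states[[i]]
    mt <- genome_record(paste0(sp, "_mt"), paste(st$mt$seq, collapse = ""),
                        "mt", st$mt$features, spp_tax[[sp]])
    pt <- genome_record(paste0(sp, "_pt"), paste(st$pt$seq, collapse = ""),
                        "pt", st$pt$features, spp_tax[[sp]])
    genomes[[sp]] <- list(mt = mt, pt = pt)
    taxonomy[[sp]] <- spp_tax[[sp]]
    taxonomy[[mt$id]] <- spp_tax[[sp]]
    taxonomy[[pt$id]] <- spp_tax[[sp]]
  }
  list(genomes = genomes, taxonomy = taxonomy)
}

# circular substring: a/b may run outside [1, L]
substr_circ <- function(s, a, b) {
  L <- nchar(s)
  idx <- ((seq(a, b) - 1L) %% L) + 1L
  paste(strsplit(s, "")[[1]][idx], collapse = "")
}

# substitutions-only divergence applied to a transferred copy
.diverge_copy <- function(s, d, kappa) {
  v <- strsplit(s, "")[[1]]
  n <- rpois(1L, d * length(v))
  if (n > 0L) {
    pos <- sample.int(length(v), n, replace = TRUE)
    ok <- v[pos] %in% c("A", "C", "G", "T")
    v[pos[ok]] <- .hky_targets(v[pos[ok]], kappa)
  }
  paste(v, collapse = "")
}

# a plastid source interval of the requested length avoiding the
# ancient-homology loci
.pick_source <- function(pt, len, blacklist = c("atp1", "rrn18", "rrn26")) {
  L <- nchar(pt$sequence)
  if (len > L) stop("requested insert longer than source genome")
  bl <- pt$features[pt$features$name %in% blacklist, , drop = FALSE]
  for (try in 1:200) {
    a <- sample.int(L - len, 1L)
    if (!any(interval_overlap(a, a + len - 1L, bl$start, bl$end) >= 1L))
      return(c(a, a + len - 1L))
  }
  stop("could not place a source interval avoiding the conserved loci")
}

# k insertion points on an mt genome: outside gene features +- buffer,
# outside existing MTPT annotations +- mtpt_pad, pairwise >= spacing
# apart.  mtpt_pad defaults to spacing; phase B passes tract padding +
# flank width so no 1 kb flank window can reach co-transferred tract
# material belonging to an earlier event.
.pick_insert_positions <- function(mt, k, buffer, spacing,
                                   mtpt_pad = spacing) {
  if (k == 0L) return(integer(0))
  L <- nchar(mt$sequence)
  ok <- rep(TRUE, L)
  f <- mt$features
  for (i in seq_len(nrow(f))) {
    pad <- if (f$kind[i] == "mtpt_annotation") mtpt_pad else buffer
    a <- max(1L, f$start[i] - pad); b <- min(L, f$end[i] + pad)
    ok[a:b] <- FALSE
  }
  # circular genomes: only a token margin at the linear representation ends
  ok[c(seq_len(100L), seq(L - 100L, L))] <- FALSE
  pos <- integer(0)
  cand <- which(ok)
  for (j in seq_len(k)) {
    if (!length(cand)) stop("no room to place insertion ", j, " of ", k)
    p <- cand[sample.int(length(cand), 1L)]
    pos <- c(pos, p)
    cand <- cand[abs(cand - p) > spacing]
  }
  sort(pos)
}

# insert blocks (pos, seq, mtpt interval relative to block) into an mt
# genome; returns the updated record, the final absolute intervals, and
# a coordinate-shift function for previously recorded intervals
.insert_blocks <- function(mt, blocks) {
  if (!length(blocks))
    return(list(mt = mt, intervals = NULL,
                shift = function(x) x))
  pos <- vapply(blocks, `[[`, integer(1), "pos")
  o <- order(pos)
  blocks <- blocks[o]; pos <- pos[o]
  lens <- vapply(blocks, function(b) nchar(b$seq), integer(1))
  cum <- cumsum(c(0L, lens))[seq_along(lens)]
  starts <- pos + 1L + cum
  seq_parts <- character(2L * length(blocks) + 1L)
  prev <- 1L
  for (i in seq_along(blocks)) {
    seq_parts[2L * i - 1L] <- substr(mt$sequence, prev, pos[i])
    seq_parts[2L * i] <- blocks[[i]]$seq
    prev <- pos[i] + 1L
  }
  seq_parts[2L * length(blocks) + 1L] <-
    substr(mt$sequence, prev, nchar(mt$sequence))
  new_seq <- paste(seq_parts, collapse = "")
  shift <- function(x) x + vapply(x, function(xx)
    sum(lens[pos < xx]), numeric(1))
  f <- mt$features
  f$start <- as.integer(shift(f$start)); f$end <- as.integer(shift(f$end))
  intervals <- data.frame(
    block_start = starts,
    block_end = starts + lens - 1L,
    mtpt_start = starts + vapply(blocks, function(b)
      b$mtpt_rel[1], integer(1)) - 1L,
    mtpt_end = starts + vapply(blocks, function(b)
      b$mtpt_rel[2], integer(1)) - 1L,
    event_id = vapply(blocks, function(b) b$event_id, integer(1)))
  newf <- data.frame(name = sprintf("mtpt_ev%03d", intervals$event_id),
                     start = intervals$mtpt_start,
                     end = intervals$mtpt_end, strand = "+",
                     kind = "mtpt_annotation", stringsAsFactors = FALSE)
  f <- rbind(f, newf)
  mt2 <- genome_record(mt$id, new_seq, mt$compartment, f, mt$lineage,
                       mt$circular)
  list(mt = mt2, intervals = intervals, shift = shift)
}

#' Implant IGT and HGT events into evolved genomes
#'
#' See [sim_config()] for the three event models.  Donor species are
#' always drawn from the opposite major clade of the recipient, so
#' donors are unrelated at every rank.  Every implanted interval is
#' recorded in the truth log.
#'
#' @param sim output of [evolve_genomes()].
#' @param tree the species tree.
#' @param config a [sim_config()].
#' @return list: `genomes` (updated), `taxonomy`, `truth` (data.frame:
#'   event_id, type, donor, recipient, mt_start, mt_end, src_start,
#'   src_end, tract_start, tract_end).
#' @export
implant_events <- function(sim, tree, config) {
  set.seed(config$seed + 2L)
  genomes <- sim$genomes
  n <- length(tree$tip.label)
  root_kids <- tree$edge[tree$edge[, 1] == n + 1L, 2]
  side_tips <- lapply(root_kids, function(k)
    if (k <= n) tree$tip.label[k] else
      tree$tip.label[phangorn::Descendants(tree, k, "tips")[[1]]])
  sideA <- side_tips[[1]]; sideB <- side_tips[[2]]
  species <- tree$tip.label
  recycle <- function(pool, k) {
    if (k == 0L) return(character(0))
    out <- character(0)
    while (length(out) < k) out <- c(out, sample(pool))
    out[seq_len(k)]
  }
  rlen <- function(k) {
    if (k == 0L) return(integer(0))
    as.integer(round(runif(k, config$mtpt_length_range[1],
                           config$mtpt_length_range[2])))
  }
  block <- function(type, rec, don) {
    if (!length(rec)) return(NULL)
    data.frame(type = type, recipient = rec, donor = don,
               stringsAsFactors = FALSE)
  }
  events <- rbind(
    block("native_igt", recycle(species, config$n_native_mtpt),
          NA_character_),
    block("mt2mt_hgt", recycle(sideA, config$n_mt2mt_events),
          recycle(sideB, config$n_mt2mt_events)),
    block("pt2mt_hgt", recycle(sideB, config$n_pt2mt_events),
          recycle(sideA, config$n_pt2mt_events)))
  if (is.null(events)) events <- data.frame()
  if (!nrow(events))
    return(list(genomes = genomes, taxonomy = sim$taxonomy,
                truth = data.frame()))
  events$donor[events$type == "native_igt"] <-
    events$recipient[events$type == "native_igt"]
  events$event_id <- seq_len(nrow(events))
  events$len <- rlen(nrow(events))
  events$src_start <- NA_integer_; events$src_end <- NA_integer_
  for (i in seq_len(nrow(events))) {
    src <- .pick_source(genomes[[events$donor[i]]]$pt, events$len[i])
    events$src_start[i] <- src[1]; events$src_end[i] <- src[2]
  }
  truth <- data.frame(event_id = events$event_id, type = events$type,
                      donor = events$donor, recipient = events$recipient,
                      mt_start = NA_integer_, mt_end = NA_integer_,
                      src_start = events$src_start,
                      src_end = events$src_end,
                      tract_start = NA_integer_, tract_end = NA_integer_,
                      stringsAsFactors = FALSE)
  donor_mtpt <- list()  # event_id -> donor-genome MTPT interval (phase A)

  # phase A: native IGT + the donor-side IGT of every mt2mt event
  phaseA <- events[events$type %in% c("native_igt", "mt2mt_hgt"), ]
  for (sp in unique(c(phaseA$recipient[phaseA$type == "native_igt"],
                      phaseA$donor[phaseA$type == "mt2mt_hgt"]))) {
    rows <- which((phaseA$type == "native_igt" & phaseA$recipient == sp) |
                    (phaseA$type == "mt2mt_hgt" & phaseA$donor == sp))
    if (!length(rows)) next
    is_donor <- any(phaseA$type[rows] == "mt2mt_hgt")
    buffer <- if (is_donor) config$mt_tract_padding + 600L
    else config$gene_buffer
    # donor-side spacing keeps the co-transferred tracts of different
    # events disjoint in donor coordinates
    spacing <- if (is_donor)
      max(config$insert_spacing, 2L * config$mt_tract_padding + 1000L)
    else config$insert_spacing
    pos <- .pick_insert_positions(genomes[[sp]]$mt, length(rows),
                                  buffer, spacing)
    blocks <- lapply(seq_along(rows), function(j) {
      ev <- phaseA[rows[j], ]
      src_seq <- substr(genomes[[ev$donor]]$pt$sequence,
                        ev$src_start, ev$src_end)
      list(pos = pos[j],
           seq = .diverge_copy(src_seq, config$divergence_at_transfer,
                               config$kappa),
           mtpt_rel = c(1L, nchar(src_seq)),
           event_id = ev$event_id)
    })
    res <- .insert_blocks(genomes[[sp]]$mt, blocks)
    genomes[[sp]]$mt <- res$mt
    for (j in seq_len(nrow(res$intervals))) {
      eid <- res$intervals$event_id[j]
      if (events$type[eid] == "native_igt") {
        truth$mt_start[eid] <- res$intervals$mtpt_start[j]
        truth$mt_end[eid] <- res$intervals$mtpt_end[j]
      } else {
        donor_mtpt[[as.character(eid)]] <-
          c(res$intervals$mtpt_start[j], res$intervals$mtpt_end[j])
      }
    }
  }
  # the donor-side IGT copy of each mt2mt event is itself a detectable
  # native MTPT of the donor: log it so recovery scoring expects it
  if (length(donor_mtpt)) {
    extra <- do.call(rbind, lapply(names(donor_mtpt), function(eid) {
      ev <- events[as.integer(eid), ]
      data.frame(event_id = max(events$event_id) + as.integer(eid),
                 type = "native_igt", donor = ev$donor,
                 recipient = ev$donor,
                 mt_start = donor_mtpt[[eid]][1],
                 mt_end = donor_mtpt[[eid]][2],
                 src_start = ev$src_start, src_end = ev$src_end,
                 tract_start = NA_integer_, tract_end = NA_integer_,
                 stringsAsFactors = FALSE)
    }))
    truth <- rbind(truth, extra)
  }

  # phase B: HGT insertions into recipients
  phaseB <- events[events$type %in% c("mt2mt_hgt", "pt2mt_hgt"), ]
  for (sp in unique(phaseB$recipient)) {
    rows <- which(phaseB$recipient == sp)
    pos <- .pick_insert_positions(genomes[[sp]]$mt, length(rows),
                                  config$gene_buffer,
                                  config$insert_spacing,
                                  mtpt_pad = config$mt_tract_padding +
                                    1000L)
    blocks <- lapply(seq_along(rows), function(j) {
      ev <- phaseB[rows[j], ]
      if (ev$type == "mt2mt_hgt") {
        dm <- donor_mtpt[[as.character(ev$event_id)]]
        pad <- config$mt_tract_padding
        tract <- substr_circ(genomes[[ev$donor]]$mt$sequence,
                             dm[1] - pad, dm[2] + pad)
        list(pos = pos[j],
             seq = .diverge_copy(tract, config$divergence_at_transfer,
                                 config$kappa),
             mtpt_rel = c(pad + 1L, pad + (dm[2] - dm[1] + 1L)),
             event_id = ev$event_id)
      } else {
        src_seq <- substr(genomes[[ev$donor]]$pt$sequence,
                          ev$src_start, ev$src_end)
        list(pos = pos[j],
             seq = .diverge_copy(src_seq, config$divergence_at_transfer,
                                 config$kappa),
             mtpt_rel = c(1L, nchar(src_seq)),
             event_id = ev$event_id)
      }
    })
    res <- .insert_blocks(genomes[[sp]]$mt, blocks)
    genomes[[sp]]$mt <- res$mt
    # phase A intervals on this genome shift under the new insertions
    old <- which(truth$recipient == sp & !is.na(truth$mt_start))
    truth$mt_start[old] <- as.integer(res$shift(truth$mt_start[old]))
    truth$mt_end[old] <- as.integer(res$shift(truth$mt_end[old]))
    for (j in seq_len(nrow(res$intervals))) {
      eid <- res$intervals$event_id[j]
      truth$mt_start[eid] <- res$intervals$mtpt_start[j]
      truth$mt_end[eid] <- res$intervals$mtpt_end[j]
      if (events$type[eid] == "mt2mt_hgt") {
        truth$tract_start[eid] <- res$intervals$block_start[j]
        truth$tract_end[eid] <- res$intervals$block_end[j]
      }
    }
  }
  list(genomes = genomes, taxonomy = sim$taxonomy, truth = truth)
}

#' Simulate a complete corpus
#'
#' Convenience wrapper: tree, genome evolution, event implantation.
#'
#' @param config a [sim_config()].
#' @return list: `tree`, `genomes`, `taxonomy`, `truth`, `config`.
#' @export
simulate_corpus <- function(config = sim_config()) {
  tree <- simulate_species_tree(config)
  sim <- evolve_genomes(tree, config)
  imp <- implant_events(sim, tree, config)
  list(tree = tree, genomes = imp$genomes, taxonomy = imp$taxonomy,
       truth = imp$truth, config = config)
}

#' Score pipeline calls against the simulation truth log
#'
#' A call matches a truth event when both lie on the same genome and
#' their intervals overlap reciprocally by at least 50%.
#'
#' @param truth truth data.frame from [implant_events()].
#' @param calls data.frame with `mt_id`, `start`, `end` and optionally
#'   `verdict` (native/foreign/unresolved), `donor_lineage` and
#'   `mt2mt_supported` columns.
#' @param taxonomy named list for donor-lineage accuracy.
#' @return list: `recall`, `precision`, `matches` (per-event call index
#'   or NA), and when the optional columns are present
#'   `foreign_recall`, `foreign_precision`, `donor_accuracy`,
#'   `mt2mt_flag_rates` (named by truth type).
#' @export
score_recovery <- function(truth, calls, taxonomy = NULL) {
  truth$mt_id <- paste0(truth$recipient, "_mt")
  match_of <- rep(NA_integer_, nrow(truth))
  for (i in seq_len(nrow(truth))) {
    if (is.na(truth$mt_start[i])) next
    cand <- which(calls$mt_id == truth$mt_id[i])
    if (!length(cand)) next
    ro <- reciprocal_overlap(truth$mt_start[i], truth$mt_end[i],
                             calls$start[cand], calls$end[cand])
    if (max(ro) >= 0.5) match_of[i] <- cand[which.max(ro)]
  }
  matched_calls <- unique(match_of[!is.na(match_of)])
  out <- list(recall = mean(!is.na(match_of)),
              precision = if (nrow(calls)) length(matched_calls) /
                nrow(calls) else NA_real_,
              matches = match_of)
  if ("verdict" %in% names(calls)) {
    is_foreign_truth <- truth$type %in% c("mt2mt_hgt", "pt2mt_hgt")
    verdicts <- ifelse(is.na(match_of), NA,
                       calls$verdict[match_of])
    out$foreign_recall <- mean(verdicts[is_foreign_truth] == "foreign",
                               na.rm = FALSE)
    called_foreign <- which(calls$verdict == "foreign")
    truly_foreign <- match_of[is_foreign_truth]
    out$foreign_precision <- if (length(called_foreign))
      mean(called_foreign %in% truly_foreign) else NA_real_
    if ("donor_lineage" %in% names(calls) && !is.null(taxonomy)) {
      ok <- which(is_foreign_truth & !is.na(match_of) &
                    verdicts == "foreign")
      if (length(ok)) {
        acc <- vapply(ok, function(i) {
          assigned <- parse_lineage(calls$donor_lineage[match_of[i]])
          true_lin <- taxonomy[[truth$donor[i]]]
          length(assigned) > 0 &&
            lineage_related(assigned, true_lin, 1L)
        }, logical(1))
        out$donor_accuracy <- mean(acc)
      } else out$donor_accuracy <- NA_real_
    }
  }
  if ("mt2mt_supported" %in% names(calls)) {
    out$mt2mt_flag_rates <- vapply(
      c(native_igt = "native_igt", mt2mt_hgt = "mt2mt_hgt",
        pt2mt_hgt = "pt2mt_hgt"),
      function(ty) {
        ii <- which(truth$type == ty & !is.na(match_of))
        if (!length(ii)) return(NA_real_)
        mean(isTRUE_v(calls$mt2mt_supported[match_of[ii]]))
      }, numeric(1))
  }
  out
}
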