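#' Screen an MTPT as putatively foreign from its best hit
#'
#' An MTPT whose most similar plastid genome belongs to a lineage
#' unrelated to the recipient at the configured rank depth (default:
#' order level) is flagged putatively foreign and passed on to the
#' phylogenetic classifier; everything else is screened out as native.
#'
#' @param best_lineage lineage ranks of the best-hit subject genome.
#' @param recipient_lineage lineage ranks of the recipient.
#' @param unrelated_depth rank depth used by [lineage_related()].
#' @return TRUE when putatively foreign.
#' @export
screen_best_hit <- function(best_lineage, recipient_lineage,
                            unrelated_depth = 3L) {
  if (!length(best_lineage) || !length(recipient_lineage)) {
    warning("missing lineage; screening result ambiguous")
    return(NA)
  }
  !lineage_related(best_lineage, recipient_lineage, unrelated_depth)
}

#' Build a homolog panel for one focal sequence
#'
#' Searches the focal sequence against every genome of the panel
#' (excluding, by id, the genome the focal sequence came from) and
#' extracts the best-hit region of each genome that responds.  Regions
#' extracted from plastid genomes get compartment `"pt"`; regions from
#' mitochondrial genomes are plastid-like sequence residing in a
#' mitochondrial genome and get compartment `"mtpt"` — the tips whose
#' sisterhood to the focal sequence raises the donor-sister (omega)
#' flag.
#'
#' @param focal_seq nucleotide string (the MTPT or flank).
#' @param focal_id tip label for the focal sequence.
#' @param genomes list of `genome_record` (pt and/or mt).
#' @param taxonomy named list id -> lineage ranks.
#' @param exclude_ids genome ids to skip (typically the recipient mt).
#' @param params [search_params()]; word 11 balances sensitivity across
#'   deep panels against noise.
#' @param min_cover drop responding genomes whose extracted region
#'   covers less than this fraction of the focal length: fragmentary
#'   homologs contribute more distance noise than signal to the panel
#'   tree.
#' @return list of class `homolog_panel`: `focal_id`, `members`
#'   (data.frame id, seq, lineage, compartment), `alignment` (NULL until
#'   [build_alignment()]).
#' @export
build_panel <- function(focal_seq, focal_id, genomes, taxonomy,
                        exclude_ids = character(0),
                        params = search_params(word_size = 11L),
                        min_cover = 0.4) {
  members <- list()
  for (g in genomes) {
    if (g$id %in% exclude_ids) next
    h <- find_hits(focal_seq, g, params)
    if (!nrow(h)) next
    best <- h[which.max(h$bitscore), ]
    minus <- best$sstart > best$send
    # union envelope of all hits on the best hit's strand that lie close
    # to it on the subject: fragments of one homologous locus
    same <- (h$sstart > h$send) == minus
    slo <- pmin(h$sstart, h$send); shi <- pmax(h$sstart, h$send)
    blo <- min(best$sstart, best$send); bhi <- max(best$sstart, best$send)
    near <- same & slo < bhi + 2L * nchar(focal_seq) &
      shi > blo - 2L * nchar(focal_seq)
    lo <- min(slo[near]); hi <- max(shi[near])
    if (hi - lo + 1L < min_cover * nchar(focal_seq)) next
    seq <- substr(g$sequence, lo, hi)
    if (minus) seq <- revcomp(seq)
    comp <- if (g$compartment == "pt") "pt" else "mtpt"
    members[[length(members) + 1L]] <- data.frame(
      id = paste0(g$id, "|", comp), seq = seq,
      lineage = format_lineage(taxonomy[[g$id]] %||% character(0)),
      compartment = comp, stringsAsFactors = FALSE)
  }
  members <- do.call(rbind, c(list(data.frame(
    id = focal_id, seq = focal_seq, lineage = NA_character_,
    compartment = "focal", stringsAsFactors = FALSE)), members))
  structure(list(focal_id = focal_id, members = members, alignment = NULL),
            class = "homolog_panel")
}

#' Align a homolog panel
#'
#' Multiple alignment of the panel members.  The heavy lifting is done
#' by the MAFFT program (FFT-NS-2, deterministic for a fixed input
#' order); the panel rows are passed in their stored order.
#'
#' @param panel a `homolog_panel`.
#' @return the panel with `$alignment` set: a character matrix over
#'   {A,C,G,T,N,-} with one named row per member.
#' @export
build_alignment <- function(panel) {
  m <- panel$members
  if (nrow(m) < 2L) stop("need at least 2 sequences to align")
  if (Sys.which("mafft") == "")
    stop("mafft not found on PATH; it is required for build_alignment()")
  fin <- tempfile(fileext = ".fa"); fout <- tempfile(fileext = ".fa")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_fasta(setNames(m$seq, m$id), fin)
  status <- system2("mafft", c("--retree", "2", "--maxiterate", "0",
                               "--quiet", shQuote(fin)),
                    stdout = fout, stderr = FALSE)
  if (status != 0L) stop("mafft failed with status ", status)
  aln <- Biostrings::readBStringSet(fout)
  mat <- do.call(rbind, lapply(as.character(aln), function(s)
    strsplit(chartr("u", "t", s), "")[[1]]))
  mat <- toupper(mat)
  mat[!(mat %in% c("A", "C", "G", "T", "-"))] <- "N"
  rownames(mat) <- names(aln)
  # restore input order (mafft preserves it, but be explicit)
  panel$alignment <- mat[m$id, , drop = FALSE]
  panel
}

#' Infer a tree with bootstrap supports from an alignment
#'
#' Neighbor-joining on TN93 maximum-likelihood pairwise distances with a
#' seeded nonparametric bootstrap (column resampling with replacement);
#' the support of each internal edge is the percentage of replicates
#' containing the same bipartition.  Rows are sorted into canonical
#' (alphabetical) tip order before anything is drawn, so supports do not
#' depend on the input row order.
#'
#' @param alignment character matrix (rows = tips) or a `homolog_panel`
#'   with `$alignment` set.
#' @param n_bootstrap bootstrap replicates.
#' @param seed RNG seed for the resampling.
#' @return an unrooted `phylo` tree; `node.label` holds integer percent
#'   supports.
#' @export
infer_tree <- function(alignment, n_bootstrap = 1000L, seed = 1L) {
  if (inherits(alignment, "homolog_panel")) alignment <- alignment$alignment
  stopifnot(is.matrix(alignment), nrow(alignment) >= 4L)
  alignment <- alignment[order(rownames(alignment)), , drop = FALSE]
  all_gap <- colSums(alignment != "-") == 0L
  if (any(all_gap)) {
    warning(sum(all_gap), " all-gap column(s) dropped")
    alignment <- alignment[, !all_gap, drop = FALSE]
  }
  dna <- ape::as.DNAbin(tolower(alignment))
  est <- function(x) {
    d <- ape::dist.dna(x, model = "TN93", pairwise.deletion = TRUE)
    # guard against saturated or empty pairs in resampled replicates
    bad <- !is.finite(d)
    if (any(bad)) d[bad] <- max(d[!bad], 1) * 2
    ape::nj(d)
  }
  tr <- est(dna)
  set.seed(seed)
  counts <- ape::boot.phylo(tr, dna, est, B = n_bootstrap,
                            quiet = TRUE, rooted = FALSE)
  tr$node.label <- as.character(as.integer(round(100 * counts /
                                                   n_bootstrap)))
  tr
}

# support lookup table: tip-set key -> integer support, from an unrooted
# tree whose node.label holds supports
.bipart_supports <- function(tree) {
  ntip <- length(tree$tip.label)
  desc <- phangorn::Descendants(tree, (ntip + 1L):(ntip + tree$Nnode),
                                type = "tips")
  keys <- vapply(desc, function(tt)
    paste(sort(tree$tip.label[tt]), collapse = "|"), character(1))
  sup <- suppressWarnings(as.integer(tree$node.label))
  setNames(sup, keys)
}

.clade_support <- function(tips, all_tips, lookup) {
  key <- paste(sort(tips), collapse = "|")
  comp <- paste(sort(setdiff(all_tips, tips)), collapse = "|")
  if (!is.na(lookup[key])) return(unname(lookup[key]))
  if (!is.na(lookup[comp])) return(unname(lookup[comp]))
  NA_integer_
}

# longest common prefix of a list of rank vectors
.shared_prefix <- function(lineages) {
  Reduce(function(a, b) {
    n <- lineage_shared_prefix(a, b)
    if (n == 0L) character(0) else a[seq_len(n)]
  }, lineages)
}

#' Classify the phylogenetic placement of a focal sequence
#'
#' Implements the incongruence criterion: the focal sequence is foreign
#' when it falls, with bootstrap support above the threshold, inside a
#' clade of sequences from a lineage unrelated to the recipient.
#' Concretely, the tree is midpoint rooted, the smallest
#' focal-containing clade is sought whose bipartition support exceeds
#' `bs_threshold` and whose non-focal members share a lineage prefix;
#' that prefix is the donor lineage.  If it is related to the recipient
#' at `unrelated_depth` the verdict is native, otherwise foreign.  With
#' no such supported clade the verdict is unresolved — never foreign at
#' support <= threshold.
#'
#' The donor-sister flag is raised when the focal tip's immediate sister
#' set consists exclusively of MTPT-compartment tips of the donor
#' lineage: the signature that the plastid sequence travelled inside the
#' donor's mitochondrial genome.
#'
#' @param tree unrooted `phylo` with percent supports in `node.label`.
#' @param focal_tip tip label of the focal sequence.
#' @param recipient_lineage rank vector of the recipient.
#' @param taxonomy named list tip label -> rank vector (focal excluded).
#' @param bs_threshold foreign calls require support strictly above this.
#' @param unrelated_depth rank depth for [lineage_related()].
#' @param compartments optional named character vector tip ->
#'   `"pt"`/`"mtpt"` used for the donor-sister flag.
#' @return list of class `phylo_placement`: `verdict`
#'   (native/foreign/unresolved), `support`, `donor_lineage` (rank
#'   vector or NULL), `sister_group`, `donor_sister_flag`, `tree`,
#'   `focal_tip`.
#' @export
classify_placement <- function(tree, focal_tip, recipient_lineage, taxonomy,
                               bs_threshold = 70L, unrelated_depth = 3L,
                               compartments = NULL) {
  stopifnot(focal_tip %in% tree$tip.label)
  lookup <- .bipart_supports(tree)
  rooted <- phangorn::midpoint(tree)
  ntip <- length(rooted$tip.label)
  all_tips <- rooted$tip.label
  desc <- phangorn::Descendants(rooted, (ntip + 1L):(ntip + rooted$Nnode),
                                type = "tips")
  cand <- list()
  for (i in seq_along(desc)) {
    tips <- all_tips[desc[[i]]]
    if (!(focal_tip %in% tips) || length(tips) < 2L ||
        length(tips) >= length(all_tips)) next
    others <- setdiff(tips, focal_tip)
    # donor identity is certified by the plastome tips of the clade:
    # an MTPT tip carries its host's lineage, which may itself be
    # foreign to the plastid sequence it contains (the donor-sister
    # situation), so mtpt tips do not veto clade coherence when
    # plastome tips are present
    if (!is.null(compartments) &&
        any(compartments[others] == "pt", na.rm = TRUE))
      others <- others[compartments[others] == "pt"]
    lins <- lapply(others, function(tp) taxonomy[[tp]])
    if (any(vapply(lins, is.null, logical(1)))) next
    pref <- .shared_prefix(lins)
    if (!length(pref)) next
    sup <- .clade_support(tips, all_tips, lookup)
    if (is.na(sup) || sup <= bs_threshold) next
    cand[[length(cand) + 1L]] <- list(tips = tips, pref = pref, sup = sup)
  }
  # focal's immediate sister set in the rooted tree
  edge <- rooted$edge
  focal_num <- match(focal_tip, all_tips)
  parent <- edge[edge[, 2] == focal_num, 1]
  sib_nodes <- setdiff(edge[edge[, 1] == parent, 2], focal_num)
  sister <- all_tips[unlist(lapply(sib_nodes, function(nd)
    if (nd <= ntip) nd else desc[[nd - ntip]]))]
  res <- list(verdict = "unresolved", support = NA_integer_,
              donor_lineage = NULL, sister_group = sister,
              donor_sister_flag = FALSE, tree = tree,
              focal_tip = focal_tip)
  if (length(cand)) {
    best <- cand[[which.min(vapply(cand, function(cc) length(cc$tips),
                                   integer(1)))]]
    if (lineage_related(best$pref, recipient_lineage, unrelated_depth)) {
      res$verdict <- "native"
      res$support <- best$sup
    } else {
      res$verdict <- "foreign"
      res$support <- best$sup
      res$donor_lineage <- best$pref
      if (!is.null(compartments) && length(sister)) {
        comp_ok <- all(compartments[sister] == "mtpt", na.rm = FALSE)
        lin_ok <- all(vapply(sister, function(tp) {
          lin <- taxonomy[[tp]]
          !is.null(lin) && lineage_related(lin, best$pref,
                                           min(unrelated_depth,
                                               length(best$pref)))
        }, logical(1)))
        res$donor_sister_flag <- isTRUE(comp_ok) && lin_ok
      }
    }
  }
  stopifnot(!(res$verdict == "foreign" && res$support <= bs_threshold))
  res
}

#' Full origin classification of one MTPT call
#'
#' Chains the best-hit screen, panel construction, alignment, tree
#' inference and placement classification.  Calls whose best hit is
#' lineage-related to the recipient are returned as native without a
#' tree (the screen of the detection procedure); putatively foreign
#' calls are confirmed or rejected phylogenetically.
#'
#' @param call one row of a [call_mtpts()] data.frame.
#' @param mt recipient `genome_record`.
#' @param genomes list of all panel genomes (pt panel, plus mt genomes
#'   whose MTPT copies should be offered as tips).
#' @param taxonomy named list id -> rank vector.
#' @param n_bootstrap,seed passed to [infer_tree()].
#' @param bs_threshold,unrelated_depth placement thresholds.
#' @param panel_params search settings for panel extraction.
#' @param tree optional externally computed newick tree (`phylo`) used
#'   instead of the internal distance tree.
#' @return a `phylo_placement` list (verdict `"native"` may carry no
#'   tree when decided by the screen).
#' @export
classify_origin <- function(call, mt, genomes, taxonomy,
                            n_bootstrap = 1000L, seed = 1L,
                            bs_threshold = 70L, unrelated_depth = 3L,
                            panel_params = search_params(word_size = 11L),
                            tree = NULL) {
  best_lin <- taxonomy[[call$best_subject]]
  scr <- screen_best_hit(best_lin, mt$lineage, unrelated_depth)
  if (isFALSE(scr)) {
    return(list(verdict = "native", support = NA_integer_,
                donor_lineage = NULL, sister_group = character(0),
                donor_sister_flag = FALSE, tree = NULL,
                focal_tip = NA_character_, screened = TRUE))
  }
  focal_seq <- substr(mt$sequence, call$start, call$end)
  focal_tip <- paste0(call$mt_id, "|focal")
  panel <- build_panel(focal_seq, focal_tip, genomes, taxonomy,
                       exclude_ids = mt$id, params = panel_params)
  if (nrow(panel$members) < 4L) {
    return(list(verdict = "unresolved", support = NA_integer_,
                donor_lineage = NULL, sister_group = character(0),
                donor_sister_flag = FALSE, tree = NULL,
                focal_tip = focal_tip, screened = FALSE))
  }
  if (is.null(tree)) {
    panel <- build_alignment(panel)
    tree <- infer_tree(panel, n_bootstrap = n_bootstrap, seed = seed)
  }
  tax <- setNames(lapply(panel$members$lineage, parse_lineage),
                  panel$members$id)
  tax[[focal_tip]] <- NULL
  comps <- setNames(panel$members$compartment, panel$members$id)
  out <- classify_placement(tree, focal_tip, mt$lineage, tax,
                            bs_threshold, unrelated_depth, comps)
  out$screened <- FALSE
  out
}
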