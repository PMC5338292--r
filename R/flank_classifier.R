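#' Extract the 1 kb flanking windows of an MTPT call
#'
#' Windows are `[start-width, start-1]` and `[end+1, end+width]`.  On
#' circular genomes (the organellar default) the windows wrap around
#' the origin; in linear mode they are truncated at the sequence ends
#' and a flank that truncates to nothing becomes NA evidence.
#'
#' @param call list/row with `start` and `end` (1-based inclusive).
#' @param genome `genome_record`.
#' @param width flank width in bp.
#' @param circular override the genome's circularity flag.
#' @return list with `five_prime` and `three_prime`, each either NA or
#'   a list `(seq, start, end)`; wrapped windows keep their unwrapped
#'   coordinates (start may be < 1, end may exceed the length).
#' @export
extract_flanks <- function(call, genome, width = 1000L,
                           circular = NULL) {
  circular <- circular %||% genome$circular
  L <- nchar(genome$sequence)
  win <- function(a, b) {
    if (circular) {
      idx <- ((seq(a, b) - 1L) %% L) + 1L
      seq <- paste(strsplit(genome$sequence, "")[[1]][idx], collapse = "")
      return(list(seq = seq, start = a, end = b))
    }
    a2 <- max(1L, a); b2 <- min(L, b)
    if (a2 > b2) return(NA)
    list(seq = substr(genome$sequence, a2, b2), start = a2, end = b2)
  }
  five <- if (call$start - 1L >= 1L || circular)
    win(call$start - width, call$start - 1L) else NA
  three <- if (call$end + 1L <= L || circular)
    win(call$end + 1L, call$end + width) else NA
  if (!circular && call$start == 1L) five <- NA
  if (!circular && call$end == L) three <- NA
  list(five_prime = five, three_prime = three)
}

#' Categorize one flank from its homology hits
#'
#' The six-way evidence code: 1 no hit; 2 all hits related to the
#' recipient lineage (putative native flank); 3 hits only to lineages
#' unrelated to both donor and recipient (inconclusive); 4 all hits
#' related to the donor lineage; 5 hits to diverse lineages — settled
#' by a phylogeny of the flank; 6 external evidence (never computed,
#' carried as an input annotation).  A flank supports the mt-to-mt
#' hypothesis iff its category is 4, or 5 with phylogenetic support,
#' or 6.
#'
#' @param flank_hits outfmt-6 hits of the flank against the
#'   mitochondrial panel (recipient excluded).
#' @param taxonomy named list id -> rank vector for the subjects.
#' @param donor_lineage,recipient_lineage rank vectors.
#' @param unrelated_depth rank depth for [lineage_related()].
#' @return list: `category` (integer 1-5), `related` (per-hit factor
#'   "recipient"/"donor"/"other"), plus `supports_mt2mt` for categories
#'   decided without phylogeny (NA for category 5).
#' @export
categorize_flank <- function(flank_hits, taxonomy, donor_lineage,
                             recipient_lineage, unrelated_depth = 3L) {
  if (is.null(flank_hits) || !nrow(flank_hits))
    return(list(category = 1L, related = character(0),
                supports_mt2mt = FALSE))
  rel <- vapply(flank_hits$sseqid, function(id) {
    lin <- taxonomy[[id]]
    if (is.null(lin)) return("other")
    if (lineage_related(lin, donor_lineage, unrelated_depth)) return("donor")
    if (lineage_related(lin, recipient_lineage, unrelated_depth))
      return("recipient")
    "other"
  }, character(1))
  category <- if (all(rel == "recipient")) 2L
  else if (all(rel == "donor")) 4L
  else if (!any(rel %in% c("donor", "recipient"))) 3L
  else 5L
  supports <- switch(as.character(category),
                     "2" = FALSE, "3" = FALSE, "4" = TRUE, NA)
  list(category = category, related = unname(rel),
       supports_mt2mt = supports)
}

#' Classify one flank of a foreign MTPT
#'
#' Searches the flank against the mitochondrial panel, applies
#' [categorize_flank()], and for category 5 (diverse lineages) runs the
#' placement classifier on a panel built from the flank's own hits:
#' phylogenetic support requires a foreign verdict, a donor-matching
#' lineage and support above the threshold.  When the diverse panel is
#' too small for a tree (< 4 tips) the verdict falls back to the
#' lineage of the highest-bitscore hit.
#'
#' @param flank one element of [extract_flanks()] (or NA).
#' @param side `"five_prime"` or `"three_prime"`.
#' @param mt_panel list of mitochondrial `genome_record`s.
#' @param taxonomy named list id -> rank vector.
#' @param donor_lineage,recipient_lineage rank vectors.
#' @param recipient_id recipient genome id (excluded from the search).
#' @param params flank search settings (word 11 by default).
#' @param unrelated_depth rank depth.
#' @param n_bootstrap,seed tree settings for category-5 phylogenies.
#' @param bs_threshold support needed for category-5 phylo support.
#' @return one-row data.frame (`flank_evidence`): side, window
#'   coordinates, category, `phylo_support`, `supports_mt2mt`.
#' @export
classify_flank <- function(flank, side, mt_panel, taxonomy, donor_lineage,
                           recipient_lineage, recipient_id,
                           params = search_params(word_size = 11L),
                           unrelated_depth = 3L, n_bootstrap = 200L,
                           seed = 1L, bs_threshold = 70L) {
  ev <- data.frame(side = side, win_start = NA_integer_,
                   win_end = NA_integer_, category = NA_integer_,
                   phylo_support = NA, supports_mt2mt = FALSE)
  if (!is.list(flank)) return(ev)  # NA flank: not testable
  ev$win_start <- flank$start; ev$win_end <- flank$end
  panel_recs <- mt_panel[vapply(mt_panel, function(g)
    g$id != recipient_id, logical(1))]
  hits <- search_panel(genome_record("flankq", flank$seq, "mt"),
                       panel_recs, params, exclude_self = FALSE)
  cat5 <- categorize_flank(hits, taxonomy, donor_lineage,
                           recipient_lineage, unrelated_depth)
  ev$category <- cat5$category
  if (cat5$category != 5L) {
    ev$supports_mt2mt <- isTRUE(cat5$supports_mt2mt)
    return(ev)
  }
  # diverse lineages: phylogeny of the flank against its hit regions
  subject_ids <- unique(hits$sseqid)
  panel <- build_panel(flank$seq, "flank|focal",
                       panel_recs[vapply(panel_recs, function(g)
                         g$id %in% subject_ids, logical(1))],
                       taxonomy, params = params)
  if (nrow(panel$members) >= 4L) {
    panel <- build_alignment(panel)
    tree <- infer_tree(panel, n_bootstrap = n_bootstrap, seed = seed)
    tax <- setNames(lapply(panel$members$lineage, parse_lineage),
                    panel$members$id)
    tax[["flank|focal"]] <- NULL
    pl <- classify_placement(tree, "flank|focal", recipient_lineage, tax,
                             bs_threshold, unrelated_depth)
    ok <- pl$verdict == "foreign" &&
      !is.null(pl$donor_lineage) &&
      lineage_related(pl$donor_lineage, donor_lineage,
                      min(unrelated_depth, length(pl$donor_lineage))) &&
      pl$support > bs_threshold
    ev$phylo_support <- ok
  } else {
    best <- hits[which.max(hits$bitscore), ]
    lin <- taxonomy[[best$sseqid]]
    ev$phylo_support <- !is.null(lin) &&
      lineage_related(lin, donor_lineage, unrelated_depth)
  }
  ev$supports_mt2mt <- isTRUE(ev$phylo_support)
  ev
}

#' Flank evidence for one foreign MTPT record
#'
#' @param call one row of a foreign call table (needs `start`, `end`,
#'   `mt_id` and a donor lineage).
#' @param donor_lineage rank vector assigned by the origin classifier.
#' @param mt recipient `genome_record`.
#' @param mt_panel list of mitochondrial `genome_record`s.
#' @param taxonomy named list id -> rank vector.
#' @param width flank width (1 kb).
#' @param ... passed to [classify_flank()].
#' @return one-row data.frame: the call columns plus `flank5_*`,
#'   `flank3_*` evidence and `mt2mt_supported`.
#' @export
classify_flanks_record <- function(call, donor_lineage, mt, mt_panel,
                                   taxonomy, width = 1000L, ...) {
  fl <- extract_flanks(call, mt, width)
  e5 <- classify_flank(fl$five_prime, "five_prime", mt_panel, taxonomy,
                       donor_lineage, mt$lineage, mt$id, ...)
  e3 <- classify_flank(fl$three_prime, "three_prime", mt_panel, taxonomy,
                       donor_lineage, mt$lineage, mt$id, ...)
  data.frame(mt_id = call$mt_id, start = call$start, end = call$end,
             donor_lineage = format_lineage(donor_lineage),
             flank5_category = e5$category, flank5_supports = e5$supports_mt2mt,
             flank3_category = e3$category, flank3_supports = e3$supports_mt2mt,
             mt2mt_supported = e5$supports_mt2mt || e3$supports_mt2mt)
}

#' Summarize a foreign-MTPT corpus
#'
#' Accepts either computed records (with logical `flank5_supports` /
#' `flank3_supports` columns) or the packaged published table (with
#' `flank5_code` / `flank3_code` tokens such as `"yes4"`, `"no3"`,
#' `NA`), and counts the records with mt-to-mt flank support and those
#' involving a host-parasite relationship.
#'
#' @param records data.frame of foreign MTPT records.
#' @return list: `n_total`, `n_mt2mt`, `pct_mt2mt`, `n_host_parasite`,
#'   `pct_host_parasite`, `per_species` (named counts), plus the
#'   display-rounded `pct_*_rounded` values.
#' @export
summarize_corpus <- function(records) {
  n <- nrow(records)
  if (!n)
    return(list(n_total = 0L, n_mt2mt = 0L, pct_mt2mt = NA_real_,
                n_host_parasite = 0L, pct_host_parasite = NA_real_,
                per_species = integer(0), pct_mt2mt_rounded = NA_real_,
                pct_host_parasite_rounded = NA_real_))
  if ("flank5_code" %in% names(records)) {
    sup5 <- !is.na(records$flank5_code) &
      startsWith(records$flank5_code, "yes")
    sup3 <- !is.na(records$flank3_code) &
      startsWith(records$flank3_code, "yes")
  } else {
    sup5 <- isTRUE_v(records$flank5_supports)
    sup3 <- isTRUE_v(records$flank3_supports)
  }
  mt2mt <- sup5 | sup3
  hp <- if ("host_parasite_flag" %in% names(records))
    records$host_parasite_flag else rep(FALSE, n)
  species <- if ("recipient_species" %in% names(records))
    records$recipient_species else records$mt_id
  list(n_total = n,
       n_mt2mt = sum(mt2mt),
       pct_mt2mt = 100 * sum(mt2mt) / n,
       n_host_parasite = sum(hp, na.rm = TRUE),
       pct_host_parasite = 100 * sum(hp, na.rm = TRUE) / n,
       per_species = table(species),
       pct_mt2mt_rounded = round(100 * sum(mt2mt) / n),
       pct_host_parasite_rounded = round(100 * sum(hp, na.rm = TRUE) / n))
}

isTRUE_v <- function(x) !is.na(x) & x
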