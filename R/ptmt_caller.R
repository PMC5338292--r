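#' Detect mitochondrion-derived sequences in a plastid genome
#'
#' Reverse-direction detector: the plastid genome is searched against a
#' mitochondrial panel with a sensitive word size (7).  Hits whose
#' mitochondrial subject interval overlaps a region annotated as
#' plastid-derived (an MTPT annotation) or an ancient-homology locus
#' (atp1, rrn18, rrn26) are excluded.  Surviving plastid regions are
#' cross-checked against the other plastid genomes of the panel; a
#' region is reported only when its best mitochondrial bitscore is
#' strictly higher than its best plastid bitscore.
#'
#' @param pt plastid `genome_record` to scan.
#' @param mt_panel list of annotated mitochondrial `genome_record`s.
#' @param pt_panel list of plastid `genome_record`s (self is skipped).
#' @param params [search_params()]; the published settings use word
#'   size 7 with E-value 1e-10.
#' @param blacklist ancient-homology locus names.
#' @param min_len minimal reported region length in bp (word size 7
#'   yields tiny hits; 30 bp is this package's reporting floor).
#' @param max_gap merge gap for building regions from hits.
#' @return data.frame of candidate regions: `pt_id,start,end,length,
#'   best_mt_subject,best_mt_bitscore,best_pt_bitscore,excluded_reason,
#'   reported`.  Reported calls always have `excluded_reason == "none"`
#'   and `best_mt_bitscore > best_pt_bitscore`.
#' @export
call_ptmts <- function(pt, mt_panel, pt_panel = list(),
                       params = search_params(word_size = 7L),
                       blacklist = c("atp1", "rrn18", "rrn26"),
                       min_len = 30L, max_gap = 99L) {
  empty <- data.frame(pt_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      best_mt_subject = character(0),
                      best_mt_bitscore = numeric(0),
                      best_pt_bitscore = numeric(0),
                      excluded_reason = character(0),
                      reported = logical(0))
  if (!length(mt_panel)) return(empty)
  feats <- setNames(lapply(mt_panel, function(g) g$features),
                    vapply(mt_panel, function(g) g$id, character(1)))
  hits <- search_panel(pt, mt_panel, params, exclude_self = FALSE)
  if (!nrow(hits)) return(empty)
  reason <- vapply(seq_len(nrow(hits)), function(i) {
    ft <- feats[[hits$sseqid[i]]]
    if (is.null(ft) || !nrow(ft)) return("none")
    slo <- min(hits$sstart[i], hits$send[i])
    shi <- max(hits$sstart[i], hits$send[i])
    ov <- interval_overlap(slo, shi, ft$start, ft$end) >= 1L
    if (any(ov & ft$kind == "mtpt_annotation")) return("mtpt-annotated")
    if (any(ov & ft$name %in% blacklist)) return("ancient-homology")
    "none"
  }, character(1))
  build_regions <- function(hh, why) {
    if (!nrow(hh)) return(NULL)
    o <- order(hh$qstart, hh$qend)
    hh <- hh[o, , drop = FALSE]
    grp <- cumsum(c(TRUE, hh$qstart[-1] - cummax(hh$qend)[-nrow(hh)] -
                      1L > max_gap))
    do.call(rbind, lapply(split(seq_len(nrow(hh)), grp), function(ii) {
      g <- hh[ii, , drop = FALSE]
      b <- which.max(g$bitscore)
      data.frame(pt_id = pt$id, start = min(g$qstart), end = max(g$qend),
                 length = max(g$qend) - min(g$qstart) + 1L,
                 best_mt_subject = g$sseqid[b],
                 best_mt_bitscore = max(g$bitscore),
                 best_pt_bitscore = 0,
                 excluded_reason = why, reported = FALSE)
    }))
  }
  ok_regions <- build_regions(hits[reason == "none", , drop = FALSE], "none")
  ex <- hits[reason != "none", , drop = FALSE]
  ex_why <- reason[reason != "none"]
  ex_regions <- NULL
  if (nrow(ex))
    ex_regions <- do.call(rbind, lapply(unique(ex_why), function(why)
      build_regions(ex[ex_why == why, , drop = FALSE], why)))
  out <- rbind(ok_regions, ex_regions)
  if (is.null(out)) return(empty)
  # drop ok-regions that overlap an excluded region (no reported call may
  # overlap any excluded region)
  if (!is.null(ok_regions) && !is.null(ex_regions)) {
    keep <- vapply(seq_len(nrow(out)), function(i) {
      if (out$excluded_reason[i] != "none") return(TRUE)
      !any(interval_overlap(out$start[i], out$end[i],
                            ex_regions$start, ex_regions$end) >= 1L)
    }, logical(1))
    out <- out[keep, , drop = FALSE]
  }
  # plastid cross-check for surviving regions
  for (i in which(out$excluded_reason == "none")) {
    if (out$length[i] < min_len) next
    region <- genome_record(paste0(pt$id, "_region"),
                            substr(pt$sequence, out$start[i], out$end[i]),
                            "pt")
    best_pt <- 0
    for (g in pt_panel) {
      if (g$id == pt$id) next
      h <- find_hits(region, g, params)
      if (nrow(h)) best_pt <- max(best_pt, max(h$bitscore))
    }
    out$best_pt_bitscore[i] <- best_pt
    out$reported[i] <- out$best_mt_bitscore[i] > best_pt
  }
  out$reported <- out$reported & out$length >= min_len &
    out$excluded_reason == "none"
  rownames(out) <- NULL
  out
}
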