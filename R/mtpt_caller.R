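#' Filter raw mt-vs-pt hits before MTPT merging
#'
#' Keeps hits whose query (mitochondrial) span exceeds 200 bp and whose
#' percent identity exceeds 70 — both strict inequalities.
#'
#' @param hits outfmt-6 data.frame (one mitochondrial query).
#' @param min_len minimal query span in bp (span >= min_len is kept;
#'   default 201 encodes the strict "> 200 bp" rule).
#' @param min_identity identity floor, strict (`pident > min_identity`).
#' @return filtered hits.
#' @export
filter_hits <- function(hits, min_len = 201L, min_identity = 70.0) {
  if (!nrow(hits)) return(hits)
  span <- hits$qend - hits$qstart + 1L
  hits[span >= min_len & hits$pident > min_identity, , drop = FALSE]
}

#' Drop hits overlapping ancient-homology loci
#'
#' Plastid-mitochondrial similarity at atp1, rrn18 and rrn26 predates
#' land plants and must not be called as transfer; any hit whose query
#' interval overlaps such an annotated locus by at least 1 bp is
#' removed.  The locus list is configurable to add further known
#' ancient-transfer regions.
#'
#' @param hits outfmt-6 data.frame on one mt query.
#' @param mt_features feature data.frame of the mt genome (columns
#'   `name,start,end`).
#' @param blacklist locus names to exclude.
#' @return hits minus those overlapping a blacklisted locus.
#' @export
exclude_ancient <- function(hits, mt_features,
                            blacklist = c("atp1", "rrn18", "rrn26")) {
  if (!nrow(hits)) return(hits)
  bl <- mt_features[mt_features$name %in% blacklist, , drop = FALSE]
  missing <- setdiff(blacklist, mt_features$name)
  if (length(missing))
    message("blacklist loci absent from annotation: ",
            paste(missing, collapse = ", "))
  if (!nrow(bl)) return(hits)
  drop <- vapply(seq_len(nrow(hits)), function(i) {
    any(interval_overlap(hits$qstart[i], hits$qend[i],
                         bl$start, bl$end) >= 1L)
  }, logical(1))
  hits[!drop, , drop = FALSE]
}

#' Merge filtered hits into MTPT calls
#'
#' Hits on one mitochondrial genome whose query intervals are separated
#' by gaps of less than 100 bp (gap = next start - previous end - 1) are
#' unioned transitively into a single call; the call interval is the
#' union envelope.  Merging considers the mitochondrial coordinate only;
#' the plastid-side intervals of all supporting hits are retained for
#' inspection.
#'
#' @param hits filtered outfmt-6 data.frame, all with the same `qseqid`.
#' @param max_gap largest mergeable gap in bp (99 encodes "< 100 bp").
#' @param subject_features optional data.frame of plastid gene features
#'   (columns `seqid,name,start,end,kind`) used to annotate the plastid
#'   gene content of each call.
#' @return data.frame of calls: `mt_id,start,end,length,n_hits`, plus
#'   list-columns `hits` (supporting rows) and `gene_content`.
#' @export
merge_mtpts <- function(hits, max_gap = 99L, subject_features = NULL) {
  if (!nrow(hits))
    return(data.frame(mt_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0),
                      n_hits = integer(0)))
  stopifnot(length(unique(hits$qseqid)) == 1L)
  o <- order(hits$qstart, hits$qend)
  hits <- hits[o, , drop = FALSE]
  grp <- cumsum(c(TRUE, hits$qstart[-1] - cummax(hits$qend)[-nrow(hits)] -
                    1L > max_gap))
  calls <- do.call(rbind, lapply(split(seq_len(nrow(hits)), grp), function(ii) {
    hh <- hits[ii, , drop = FALSE]
    genes <- character(0)
    if (!is.null(subject_features) && nrow(subject_features)) {
      for (j in seq_len(nrow(hh))) {
        sf <- subject_features[subject_features$seqid == hh$sseqid[j] &
                                 subject_features$kind == "gene", ,
                               drop = FALSE]
        if (!nrow(sf)) next
        slo <- min(hh$sstart[j], hh$send[j]); shi <- max(hh$sstart[j], hh$send[j])
        genes <- c(genes, sf$name[interval_overlap(slo, shi,
                                                   sf$start, sf$end) >= 1L])
      }
    }
    data.frame(mt_id = hh$qseqid[1], start = min(hh$qstart),
               end = max(hh$qend),
               length = max(hh$qend) - min(hh$qstart) + 1L,
               n_hits = nrow(hh),
               hits = I(list(hh)),
               gene_content = I(list(sort(unique(genes)))))
  }))
  rownames(calls) <- NULL
  calls
}

# lineage of the best supporting hit of one call: highest bitscore, ties
# broken by lowest evalue then lexicographic subject id
best_hit_subject <- function(call_hits) {
  o <- order(-call_hits$bitscore, call_hits$evalue, call_hits$sseqid)
  call_hits$sseqid[o[1]]
}

#' Call MTPTs in one mitochondrial genome against a plastid panel
#'
#' Runs the full detection chain: panel search (or user-supplied hits),
#' the >200 bp / >70% identity filter, the ancient-homology exclusion,
#' and gap-tolerant merging.  When a taxonomy is supplied, each call is
#' annotated with the lineage of its best-hit plastid genome and
#' screened as `native` or `putatively_foreign` (see
#' [screen_best_hit()]).
#'
#' @param mt `genome_record` (compartment mt).
#' @param pt_panel list of plastid `genome_record`s.
#' @param params [search_params()]; the mt-vs-pt preset uses word 20.
#' @param hits optional pre-computed outfmt-6 table (skips the search).
#' @param taxonomy named list id -> lineage ranks.
#' @param blacklist ancient-homology loci.
#' @param min_len,min_identity,max_gap detection thresholds.
#' @param unrelated_depth rank depth for the native/foreign screen.
#' @return call data.frame (see [merge_mtpts()]) with extra columns
#'   `best_subject`, `best_lineage` (semicolon string) and `status`.
#' @export
call_mtpts <- function(mt, pt_panel, params = search_params(),
                       hits = NULL, taxonomy = NULL,
                       blacklist = c("atp1", "rrn18", "rrn26"),
                       min_len = 201L, min_identity = 70.0, max_gap = 99L,
                       unrelated_depth = 3L) {
  if (is.null(hits)) {
    # hits overlapping blacklisted loci are dropped post hoc anyway
    # (exclude_ancient); masking them in the query skips aligning the
    # ancient homologies in every panel genome with the same outcome
    masked <- mt
    bl <- mt$features[mt$features$name %in% blacklist, , drop = FALSE]
    if (nrow(bl)) {
      v <- strsplit(mt$sequence, "")[[1]]
      for (i in seq_len(nrow(bl))) v[bl$start[i]:bl$end[i]] <- "N"
      masked$sequence <- paste(v, collapse = "")
    }
    hits <- search_panel(masked, pt_panel, params, exclude_self = FALSE)
  }
  hits <- filter_hits(hits, min_len, min_identity)
  hits <- exclude_ancient(hits, mt$features, blacklist)
  # mirror of the reverse-direction rule: a plastid region annotated as
  # mitochondrion-derived (a PTMT) must not nominate an MTPT
  if (nrow(hits)) {
    pt_by_id <- setNames(pt_panel, vapply(pt_panel, function(g) g$id,
                                          character(1)))
    drop <- vapply(seq_len(nrow(hits)), function(i) {
      ft <- pt_by_id[[hits$sseqid[i]]]$features
      if (is.null(ft) || !nrow(ft)) return(FALSE)
      ptmt <- ft[ft$kind == "ptmt_annotation", , drop = FALSE]
      if (!nrow(ptmt)) return(FALSE)
      slo <- min(hits$sstart[i], hits$send[i])
      shi <- max(hits$sstart[i], hits$send[i])
      any(interval_overlap(slo, shi, ptmt$start, ptmt$end) >= 1L)
    }, logical(1))
    hits <- hits[!drop, , drop = FALSE]
  }
  pt_features <- do.call(rbind, lapply(pt_panel, function(g) {
    if (!nrow(g$features)) return(NULL)
    data.frame(seqid = g$id, g$features)
  }))
  calls <- merge_mtpts(hits, max_gap, pt_features)
  if (!nrow(calls)) return(calls)
  calls$best_subject <- vapply(calls$hits, best_hit_subject, character(1))
  if (!is.null(taxonomy)) {
    calls$best_lineage <- vapply(calls$best_subject, function(id)
      format_lineage(taxonomy[[id]] %||% character(0)), character(1))
    calls$status <- vapply(seq_len(nrow(calls)), function(i) {
      bl <- taxonomy[[calls$best_subject[i]]]
      if (is.null(bl)) return("ambiguous")
      if (screen_best_hit(bl, mt$lineage, unrelated_depth))
        "putatively_foreign" else "native"
    }, character(1))
  } else {
    calls$best_lineage <- NA_character_
    calls$status <- NA_character_
  }
  calls
}

#' Per-genome MTPT content statistics
#'
#' @param calls merged call data.frame for one genome (non-overlapping).
#' @param mtdna_length genome length in bp.
#' @return one-row data.frame: `mt_id,mtdna_length,n_mtpts,
#'   total_mtpt_length,pct_mtdna`.
#' @export
genome_stats <- function(calls, mtdna_length) {
  if (nrow(calls)) {
    o <- order(calls$start)
    stopifnot(all(calls$start[o][-1] > calls$end[o][-nrow(calls)]))
  }
  data.frame(
    mt_id = if (nrow(calls)) calls$mt_id[1] else NA_character_,
    mtdna_length = mtdna_length,
    n_mtpts = nrow(calls),
    total_mtpt_length = sum(calls$length),
    pct_mtdna = 100 * sum(calls$length) / mtdna_length)
}

#' Spearman rank correlation with tie-aware mid-ranks
#'
#' rho is the Pearson correlation of mid-ranks (average ranks on ties).
#' The two-sided p-value uses the t approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` on n - 2 degrees of freedom;
#' for n <= 10 an exact permutation p-value over all n! orderings is
#' available.
#'
#' @param x,y numeric vectors of equal length, n >= 4.
#' @param exact compute the exact permutation p-value (n <= 10 only).
#' @return list with `rho`, `p_value`, `n`, and `undefined` (TRUE when
#'   either vector has zero rank variance, in which case rho is NA).
#' @export
spearman_test <- function(x, y, exact = FALSE) {
  n <- length(x)
  stopifnot(n == length(y), n >= 4L)
  rx <- rank(x); ry <- rank(y)
  if (stats::var(rx) == 0 || stats::var(ry) == 0)
    return(list(rho = NA_real_, p_value = NA_real_, n = n, undefined = TRUE))
  rho <- cor(rx, ry)
  if (exact) {
    if (n > 10L) stop("exact permutation p only for n <= 10")
    perms <- .permutations(n)
    rhos <- apply(perms, 1, function(p) cor(rx, ry[p]))
    p <- mean(abs(rhos) >= abs(rho) - 1e-12)
  } else if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), df = n - 2)
  }
  list(rho = rho, p_value = p, n = n, undefined = FALSE)
}

# all permutations of 1..n as a matrix (n! rows)
.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}
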