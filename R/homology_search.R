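#' Search parameter set for the internal nucleotide local aligner
#'
#' Scoring follows the classic BLASTN `-task blastn` defaults (+2/-3,
#' gap open 5, gap extend 2, Karlin-Altschul lambda 0.625, K 0.41); only
#' word size and the E-value ceiling are varied between the two search
#' directions of the pipeline (word 20 for mt-vs-pt, word 7 for
#' pt-vs-mt).
#'
#' `min_anchor` is a two-hit-like sensitivity heuristic: seed matches on
#' one diagonal are collapsed into maximal exact runs and only runs at
#' least `min_anchor` bp long nucleate an extension.  For small word
#' sizes this suppresses the flood of random 7-mer matches; it defaults
#' to `max(word_size, 11)`.
#'
#' @param word_size exact seed length (>= 4).
#' @param evalue_max E-value ceiling; hits above it are discarded.
#' @param match,mismatch,gap_open,gap_extend raw scoring scheme (a gap of
#'   length L costs `gap_open + gap_extend * L`).
#' @param lambda,K Karlin-Altschul constants for the scheme.
#' @param x_drop extension margin in bp around a seed cluster handed to
#'   the gapped aligner.
#' @param min_anchor minimal exact diagonal run that nucleates a hit.
#' @param max_window cap on the query span of one gapped extension;
#'   larger seed clusters are split at their widest internal gaps.
#' @return list of class `search_params`.
#' @export
search_params <- function(word_size = 20L, evalue_max = 1e-10,
                          match = 2, mismatch = -3,
                          gap_open = 5, gap_extend = 2,
                          lambda = 0.625, K = 0.41,
                          x_drop = 100L, min_anchor = NULL,
                          max_window = 6000L) {
  stopifnot(word_size >= 4L, evalue_max > 0)
  structure(list(word_size = as.integer(word_size), evalue_max = evalue_max,
                 match = match, mismatch = mismatch, gap_open = gap_open,
                 gap_extend = gap_extend, lambda = lambda, K = K,
                 x_drop = as.integer(x_drop),
                 min_anchor = as.integer(min_anchor %||%
                                           max(word_size, 12L)),
                 max_window = as.integer(max_window)),
            class = "search_params")
}

#' Convert a raw alignment score to a bitscore, and a bitscore to an
#' E-value
#'
#' Standard Karlin-Altschul bookkeeping: `S' = (lambda * S - ln K) / ln 2`
#' and `E = m * n * 2^-S'` for sequence lengths m and n.
#'
#' @param S raw score.
#' @param params a [search_params()] object.
#' @return bitscore (float).
#' @export
raw_to_bitscore <- function(S, params = search_params()) {
  (params$lambda * S - log(params$K)) / log(2)
}

#' @rdname raw_to_bitscore
#' @param bits bitscore.
#' @param m,n lengths of the two sequences searched.
#' @export
bitscore_to_evalue <- function(bits, m, n) {
  stopifnot(m > 0, n > 0)
  as.numeric(m) * as.numeric(n) * 2^(-bits)
}

# substitution matrix over the package alphabet; N is mildly penalized
# against everything (including N) so it never drives an alignment
.score_matrix <- function(params) {
  b <- c("A", "C", "G", "T", "N")
  m <- matrix(params$mismatch, 5, 5, dimnames = list(b, b))
  diag(m) <- params$match
  m["N", ] <- -1; m[, "N"] <- -1
  m
}

# memo store for k-mer vectors, k-mer position maps and reverse
# complements: panel searches reuse the same genomes many times over.
# Keys combine length and three sequence probes; distinct genomes
# collide with negligible probability.
.kmer_cache <- new.env(parent = emptyenv())

.cache_key <- function(s, tag) {
  n <- nchar(s)
  probe <- paste(substring(s, seq(1L, n, length.out = min(256L, n)),
                           seq(1L, n, length.out = min(256L, n))),
                 collapse = "")
  paste0(tag, "_", n, "_", probe)
}

.cache_put <- function(key, value) {
  if (length(ls(.kmer_cache)) > 400L)
    rm(list = ls(.kmer_cache), envir = .kmer_cache)
  assign(key, value, envir = .kmer_cache)
  value
}

# short sequences (focal regions, flanks) are one-shot queries: caching
# them would evict the genome indexes that panel searches reuse
.cacheable <- function(s) nchar(s) >= 10000L

.get_kmers <- function(s, k) {
  if (!.cacheable(s)) {
    i <- seq_len(nchar(s) - k + 1L)
    return(substring(s, i, i + k - 1L))
  }
  key <- .cache_key(s, paste0("v", k))
  v <- .kmer_cache[[key]]
  if (is.null(v)) {
    i <- seq_len(nchar(s) - k + 1L)
    v <- .cache_put(key, substring(s, i, i + k - 1L))
  }
  v
}

.get_kmer_map <- function(s, k) {
  build <- function() {
    sk <- .get_kmers(s, k)
    si <- seq_along(sk)
    keep <- !grepl("N", sk, fixed = TRUE)
    split(si[keep], sk[keep])
  }
  if (!.cacheable(s)) return(build())
  key <- .cache_key(s, paste0("m", k))
  m <- .kmer_cache[[key]]
  if (is.null(m)) m <- .cache_put(key, build())
  m
}

.get_revcomp <- function(s) {
  if (!.cacheable(s)) return(revcomp(s))
  key <- .cache_key(s, "r")
  v <- .kmer_cache[[key]]
  if (is.null(v)) v <- .cache_put(key, revcomp(s))
  v
}

# exact-seed positions: all (qpos, spos) pairs with identical word_size-mers
.seed_pairs <- function(q, s, k) {
  qk <- .get_kmers(q, k)
  smap <- .get_kmer_map(s, k)
  ql <- smap[qk]
  nh <- lengths(ql)
  if (sum(nh) == 0L)
    return(data.frame(qpos = integer(0), spos = integer(0)))
  data.frame(qpos = rep.int(seq_along(qk), nh),
             spos = unlist(ql, use.names = FALSE))
}

# collapse seeds into maximal exact runs per diagonal; keep runs >= min_anchor
.seed_runs <- function(seeds, k, min_anchor) {
  if (!nrow(seeds)) return(seeds[0, c("qpos", "spos")])
  d <- seeds$qpos - seeds$spos
  o <- order(d, seeds$qpos)
  qp <- seeds$qpos[o]; sp <- seeds$spos[o]; d <- d[o]
  new_run <- c(TRUE, diff(d) != 0L | diff(qp) != 1L)
  run_end <- c(new_run[-1], TRUE)
  qs <- qp[new_run]; qe <- qp[run_end] + k - 1L; ss <- sp[new_run]
  len <- qe - qs + 1L
  keep <- len >= min_anchor
  data.frame(qstart = qs[keep], qend = qe[keep], sstart = ss[keep],
             send = ss[keep] + len[keep] - 1L,
             diag = qs[keep] - ss[keep])
}

# single-linkage clustering of runs into extension candidates
.cluster_runs <- function(runs, gap = 500L, band = 60L) {
  runs <- runs[order(runs$qstart), , drop = FALSE]
  n <- nrow(runs)
  cl <- integer(n)
  envs <- list()  # per cluster: qend, diag range
  for (i in seq_len(n)) {
    assigned <- 0L
    for (j in seq_along(envs)) {
      e <- envs[[j]]
      if (runs$qstart[i] - e$qend <= gap &&
          runs$diag[i] >= e$dmin - band && runs$diag[i] <= e$dmax + band) {
        assigned <- j
        envs[[j]] <- list(qend = max(e$qend, runs$qend[i]),
                          dmin = min(e$dmin, runs$diag[i]),
                          dmax = max(e$dmax, runs$diag[i]))
        break
      }
    }
    if (!assigned) {
      envs[[length(envs) + 1L]] <- list(qend = runs$qend[i],
                                        dmin = runs$diag[i],
                                        dmax = runs$diag[i])
      assigned <- length(envs)
    }
    cl[i] <- assigned
  }
  split(runs, cl)
}

# split an oversized cluster at its widest internal query gaps
.split_cluster <- function(cluster, max_window) {
  span <- function(cc) max(cc$qend) - min(cc$qstart) + 1L
  out <- list(cluster[order(cluster$qstart), , drop = FALSE])
  repeat {
    big <- which(vapply(out, span, integer(1)) > max_window &
                   vapply(out, nrow, integer(1)) > 1L)
    if (!length(big)) break
    cc <- out[[big[1]]]
    gaps <- cc$qstart[-1] - head(cc$qend, -1)
    cut <- which.max(gaps)
    out <- c(out[-big[1]],
             list(cc[seq_len(cut), , drop = FALSE],
                  cc[-seq_len(cut), , drop = FALSE]))
  }
  out
}

# cheap ungapped screen for single-run clusters: best-scoring ungapped
# stretch (Kadane) along the run's diagonal in a padded window
.prescore <- function(cluster, q, s, params, pad = 150L) {
  d <- cluster$diag[1]
  qs <- max(1L, d + 1L, cluster$qstart[1] - pad)
  qe <- min(nchar(q), d + nchar(s), cluster$qend[1] + pad)
  a <- strsplit(substr(q, qs, qe), "")[[1]]
  b <- strsplit(substr(s, qs - d, qe - d), "")[[1]]
  sc <- ifelse(a == b & a %in% c("A", "C", "G", "T"),
               params$match, params$mismatch)
  p <- cumsum(sc)
  max(p - cummin(c(0, p[-length(p)])))
}

# gapped extension of one seed cluster via local pairwise alignment on a
# margin-padded window; returns one outfmt-6 row (query/plus-strand
# subject coordinates) or NULL
.extend_cluster <- function(cluster, q, s, params, mat) {
  margin <- max(150L, params$x_drop)
  qs <- max(1L, min(cluster$qstart) - margin)
  qe <- min(nchar(q), max(cluster$qend) + margin)
  ss <- max(1L, min(cluster$sstart) - margin)
  se <- min(nchar(s), max(cluster$send) + margin)
  # realign with a grown window while the local alignment abuts an edge
  # that is not a sequence end (poor man's x-drop restart)
  for (iter in 1:6) {
    pa <- Biostrings::pairwiseAlignment(
      substr(q, qs, qe), substr(s, ss, se), type = "local",
      substitutionMatrix = mat,
      gapOpening = params$gap_open, gapExtension = params$gap_extend)
    grow <- 400L
    touch_qlo <- Biostrings::start(Biostrings::pattern(pa)) <= 2L && qs > 1L
    touch_qhi <- qs + Biostrings::end(Biostrings::pattern(pa)) - 1L >=
      qe - 1L && qe < nchar(q)
    touch_slo <- Biostrings::start(Biostrings::subject(pa)) <= 2L && ss > 1L
    touch_shi <- ss + Biostrings::end(Biostrings::subject(pa)) - 1L >=
      se - 1L && se < nchar(s)
    if (!(touch_qlo || touch_qhi || touch_slo || touch_shi)) break
    if (touch_qlo) qs <- max(1L, qs - grow)
    if (touch_qhi) qe <- min(nchar(q), qe + grow)
    if (touch_slo) ss <- max(1L, ss - grow)
    if (touch_shi) se <- min(nchar(s), se + grow)
  }
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  aln_len <- length(ap)
  if (aln_len == 0L) return(NULL)
  both <- ap != "-" & as_ != "-"
  matches <- sum(both & ap == as_ & ap %in% c("A", "C", "G", "T"))
  mism <- sum(both) - matches
  gap_runs <- function(v) { r <- rle(v == "-"); sum(r$values) }
  n_gap_open <- gap_runs(ap) + gap_runs(as_)
  n_gap_char <- sum(ap == "-") + sum(as_ == "-")
  S <- params$match * matches + params$mismatch * mism -
    n_gap_open * params$gap_open - n_gap_char * params$gap_extend
  if (S <= 0) return(NULL)
  data.frame(
    pident = 100 * matches / aln_len, length = aln_len,
    mismatch = mism, gapopen = n_gap_open,
    qstart = qs + Biostrings::start(Biostrings::pattern(pa)) - 1L,
    qend = qs + Biostrings::end(Biostrings::pattern(pa)) - 1L,
    sstart = ss + Biostrings::start(Biostrings::subject(pa)) - 1L,
    send = ss + Biostrings::end(Biostrings::subject(pa)) - 1L,
    raw = S)
}

#' Find local alignments between two nucleotide sequences
#'
#' Desk-scale seed-and-extend search: exact `word_size` seeds on both
#' strands are collapsed into diagonal runs, runs are clustered, and
#' each cluster is grown into a maximal gapped local alignment.
#' Bitscores and E-values follow the Karlin-Altschul bookkeeping of
#' [raw_to_bitscore()]; hits with `evalue > evalue_max` are discarded
#' and overlapping extensions are deduplicated keeping the
#' highest-scoring hit.  Minus-strand subject hits are reported with
#' `sstart > send` (BLAST tabular convention).
#'
#' @param query,subject `genome_record` objects or plain sequence
#'   strings (a string gets id `"query"` / `"subject"`).
#' @param params a [search_params()] object.
#' @return data.frame in 12-column BLAST outfmt-6 shape, sorted by query
#'   start then descending bitscore.
#' @export
find_hits <- function(query, subject, params = search_params()) {
  qid <- if (inherits(query, "genome_record")) query$id else "query"
  sid <- if (inherits(subject, "genome_record")) subject$id else "subject"
  q <- if (inherits(query, "genome_record")) query$sequence else
    normalize_sequence(query, warn = FALSE)
  s <- if (inherits(subject, "genome_record")) subject$sequence else
    normalize_sequence(subject, warn = FALSE)
  stopifnot(nchar(q) > 0L, nchar(s) > 0L)
  if (params$word_size > min(nchar(q), nchar(s))) {
    warning("word_size exceeds a sequence length; no hits")
    return(empty_hits())
  }
  mat <- .score_matrix(params)
  mlen <- nchar(q); nlen <- nchar(s)
  out <- list()
  for (strand in c("+", "-")) {
    sseq <- if (strand == "+") s else .get_revcomp(s)
    seeds <- .seed_pairs(q, sseq, params$word_size)
    runs <- .seed_runs(seeds, params$word_size, params$min_anchor)
    if (!nrow(runs)) next
    clusters <- .cluster_runs(runs)
    clusters <- do.call(c, lapply(clusters, .split_cluster,
                                  max_window = params$max_window))
    # minimum raw score any reported hit must reach given the E-value cap
    bits_needed <- log2(as.numeric(mlen) * nlen / params$evalue_max)
    raw_needed <- (bits_needed * log(2) + log(params$K)) / params$lambda
    for (cc in clusters) {
      if (nrow(cc) == 1L &&
          .prescore(cc, q, sseq, params) < 0.6 * raw_needed) next
      h <- .extend_cluster(cc, q, sseq, params, mat)
      if (is.null(h)) next
      if (strand == "-") {
        tmp <- h$sstart
        h$sstart <- nlen - tmp + 1L
        h$send <- nlen - h$send + 1L
        # keep sstart as the larger coordinate (minus-strand convention)
        lo <- pmin(h$sstart, h$send); hi <- pmax(h$sstart, h$send)
        h$sstart <- hi; h$send <- lo
      }
      out[[length(out) + 1L]] <- h
    }
  }
  if (!length(out)) return(empty_hits())
  hits <- do.call(rbind, out)
  hits$bitscore <- raw_to_bitscore(hits$raw, params)
  hits$evalue <- bitscore_to_evalue(hits$bitscore, mlen, nlen)
  hits <- hits[hits$evalue <= params$evalue_max, , drop = FALSE]
  if (!nrow(hits)) return(empty_hits())
  hits <- .dedup_hits(hits)
  hits$qseqid <- qid; hits$sseqid <- sid
  hits <- hits[order(hits$qstart, -hits$bitscore),
               c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")]
  rownames(hits) <- NULL
  hits$bitscore <- round(hits$bitscore, 1)
  hits
}

# drop hits whose query AND subject intervals both overlap a
# higher-scoring kept hit by > 50% reciprocally
.dedup_hits <- function(hits) {
  o <- order(-hits$raw)
  hits <- hits[o, , drop = FALSE]
  slo <- pmin(hits$sstart, hits$send); shi <- pmax(hits$sstart, hits$send)
  keep <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    ki <- which(keep)
    dup <- FALSE
    for (j in ki) {
      qov <- reciprocal_overlap(hits$qstart[i], hits$qend[i],
                                hits$qstart[j], hits$qend[j])
      sov <- reciprocal_overlap(slo[i], shi[i], slo[j], shi[j])
      if (qov > 0.5 && sov > 0.5) { dup <- TRUE; break }
    }
    keep[i] <- !dup
  }
  hits[keep, , drop = FALSE]
}

#' Search one query against a panel of subject genomes
#'
#' @param query `genome_record`.
#' @param panel list of `genome_record`.
#' @param params [search_params()].
#' @param exclude_self drop the panel member whose id equals the query id.
#' @param max_panel warn when the panel exceeds this size (small word
#'   sizes against large panels are slow by design).
#' @return combined outfmt-6 data.frame.
#' @export
search_panel <- function(query, panel, params = search_params(),
                         exclude_self = TRUE, max_panel = 100L) {
  if (length(panel) > max_panel)
    warning("panel of ", length(panel), " genomes exceeds max_panel")
  res <- lapply(panel, function(g) {
    if (exclude_self && inherits(query, "genome_record") &&
        g$id == query$id) return(NULL)
    find_hits(query, g, params)
  })
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) return(empty_hits())
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}
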