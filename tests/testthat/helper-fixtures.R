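# small generators shared across test files

rnd_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                             collapse = "")

# point-mutate a fraction p of sites
mutate_seq <- function(s, p) {
  v <- strsplit(s, "")[[1]]
  i <- which(runif(length(v)) < p)
  if (length(i)) v[i] <- sample(c("A", "C", "G", "T"), length(i), TRUE)
  paste(v, collapse = "")
}

# one outfmt-6 row with defaults
make_hit <- function(qstart, qend, sstart = qstart, send = qend,
                     qseqid = "q", sseqid = "s", pident = 99,
                     bitscore = 500, evalue = 1e-50) {
  span <- qend - qstart + 1L
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = span, mismatch = 0L, gapopen = 0L,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore,
             stringsAsFactors = FALSE)
}

# brute-force transitive-closure merge oracle: repeatedly union any two
# intervals with gap < 100 until fixpoint
merge_oracle <- function(starts, ends, max_gap = 99L) {
  iv <- data.frame(s = starts, e = ends)
  repeat {
    n <- nrow(iv)
    merged <- FALSE
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        gap <- max(iv$s[i], iv$s[j]) - min(iv$e[i], iv$e[j]) - 1L
        if (gap <= max_gap) {
          iv$s[i] <- min(iv$s[i], iv$s[j]); iv$e[i] <- max(iv$e[i], iv$e[j])
          iv <- iv[-j, , drop = FALSE]
          merged <- TRUE
          break
        }
      }
      if (merged) break
    }
    if (!merged) break
  }
  iv[order(iv$s), ]
}

# shared default-corpus pipeline run, computed once per session and
# reused by the acceptance tests (criteria 3 and 6)
.default_run_cache <- new.env(parent = emptyenv())
default_corpus_run <- function() {
  if (!exists("run", envir = .default_run_cache)) {
    res <- run_all(sim_config(seed = 1L), n_bootstrap = 100L,
                   do_ptmt = FALSE)
    assign("run", res, envir = .default_run_cache)
  }
  get("run", envir = .default_run_cache)
}
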