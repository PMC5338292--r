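#' @importFrom stats cor pt rbinom rexp rgeom rpois runif setNames
#' @importFrom utils read.delim write.table head tail
NULL

# reverse complement of a plain character string (ACGTN alphabet)
revcomp <- function(x) {
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "", fixed = TRUE)[[1]]),
                                 collapse = ""))
}

#' Compare two taxonomy lineages
#'
#' A lineage is an ordered character vector of rank names from broad to
#' narrow (e.g. `c("rosids", "fabids", "Fabales")`).  The shared prefix
#' length is the number of leading ranks on which the two lineages agree.
#'
#' @param a,b character vectors of rank names.
#' @return `lineage_shared_prefix()`: integer count of shared leading ranks.
#' @export
lineage_shared_prefix <- function(a, b) {
  a <- trimws(a); b <- trimws(b)
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  same <- a[seq_len(n)] == b[seq_len(n)]
  if (all(same)) n else which(!same)[1L] - 1L
}

#' @rdname lineage_shared_prefix
#' @param depth rank depth (1-based count of leading ranks) at which the
#'   two lineages must agree to be called related.  The default 3
#'   corresponds to order level in lineages written as
#'   "clade; subclade; Order; Family; ...".  A lineage shorter than
#'   `depth` is related to `b` when it is a full prefix of `b` (and vice
#'   versa).
#' @return `lineage_related()`: logical.
#' @export
lineage_related <- function(a, b, depth = 3L) {
  a <- trimws(a); b <- trimws(b)
  need <- min(depth, length(a), length(b))
  lineage_shared_prefix(a, b) >= need
}

# parse "rosids; fabids; Fabales" -> c("rosids","fabids","Fabales")
parse_lineage <- function(x) {
  if (length(x) != 1L || is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

format_lineage <- function(ranks) paste(ranks, collapse = "; ")

# 1-based inclusive interval overlap length (0 when disjoint)
interval_overlap <- function(s1, e1, s2, e2) {
  pmax(0L, pmin(e1, e2) - pmax(s1, s2) + 1L)
}

# reciprocal overlap fraction of two intervals
reciprocal_overlap <- function(s1, e1, s2, e2) {
  ov <- interval_overlap(s1, e1, s2, e2)
  pmin(ov / (e1 - s1 + 1), ov / (e2 - s2 + 1))
}

`%||%` <- function(x, y) if (is.null(x)) y else x
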