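#' Construct a genome record
#'
#' The central container of the package: one organellar genome with its
#' compartment tag, gene annotations and taxonomy lineage.  Sequences are
#' plain uppercase character strings over {A,C,G,T,N}; coordinates are
#' 1-based inclusive everywhere at the package boundary.
#'
#' @param id accession-like identifier, unique within a collection.
#' @param sequence nucleotide string; normalized with [normalize_sequence()].
#' @param compartment `"mt"` (mitochondrial) or `"pt"` (plastid).
#' @param features data.frame with columns `name`, `start`, `end`,
#'   `strand` (`"+"`/`"-"`), `kind` (`"gene"`, `"mtpt_annotation"` or
#'   `"other"`).
#' @param lineage character vector of taxonomy ranks, broad to narrow.
#' @param circular logical; organellar genomes default to circular.
#' @return an object of class `genome_record`.
#' @export
genome_record <- function(id, sequence, compartment = c("mt", "pt"),
                          features = empty_features(), lineage = character(0),
                          circular = TRUE) {
  compartment <- match.arg(compartment)
  sequence <- normalize_sequence(sequence, warn = FALSE)
  stopifnot(nzchar(id), nchar(sequence) > 0L)
  features <- as.data.frame(features, stringsAsFactors = FALSE)
  if (nrow(features)) {
    stopifnot(all(features$start >= 1L),
              all(features$start <= features$end),
              all(features$end <= nchar(sequence)))
  }
  structure(list(id = id, compartment = compartment, sequence = sequence,
                 features = features, lineage = lineage, circular = circular),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s [%s] %d bp, %d features, lineage: %s\n",
              x$id, x$compartment, nchar(x$sequence), nrow(x$features),
              if (length(x$lineage)) format_lineage(x$lineage) else "<none>"))
  invisible(x)
}

#' @rdname genome_record
#' @export
empty_features <- function() {
  data.frame(name = character(0), start = integer(0), end = integer(0),
             strand = character(0), kind = character(0),
             stringsAsFactors = FALSE)
}

#' Normalize a nucleotide string
#'
#' Uppercases, maps U to T, and collapses every other non-ACGTN character
#' (IUPAC ambiguity codes, gaps) to N.  N never counts towards identity in
#' downstream alignments.
#'
#' @param x nucleotide string.
#' @param warn emit a warning when characters were collapsed to N.
#' @return normalized string.
#' @export
normalize_sequence <- function(x, warn = TRUE) {
  x <- chartr("u", "t", toupper(x))
  x <- chartr("U", "T", x)
  bad <- gsub("[ACGTN]", "", x)
  if (nzchar(bad)) {
    if (warn)
      warning(sprintf("%d non-ACGTN character(s) collapsed to N (e.g. '%s')",
                      nchar(bad), substr(bad, 1, 5)), call. = FALSE)
    x <- gsub("[^ACGTN]", "N", x)
  }
  x
}

#' Read a FASTA file into genome records
#'
#' Lineages and features are attached separately (see [read_taxonomy()]
#' and [read_gff3()]).
#'
#' @param path FASTA file, one or more records.
#' @param compartment compartment tag applied to all records.
#' @param circular logical, passed through to [genome_record()].
#' @return list of `genome_record`, named by id.
#' @export
read_fasta <- function(path, compartment = "mt", circular = TRUE) {
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  ids <- sub("\\s.*$", "", names(ss))
  if (anyDuplicated(ids))
    stop("duplicate FASTA ids: ", paste(unique(ids[duplicated(ids)]),
                                        collapse = ", "))
  recs <- lapply(seq_along(ss), function(i) {
    genome_record(ids[i], normalize_sequence(as.character(ss[[i]])),
                  compartment, circular = circular)
  })
  setNames(recs, ids)
}

#' Write genome records to FASTA
#' @param records list of `genome_record` (or named character vector).
#' @param path output file.
#' @param width line wrap width.
#' @export
write_fasta <- function(records, path, width = 70L) {
  con <- file(path, "w"); on.exit(close(con))
  if (is.character(records)) {
    seqs <- records
  } else {
    seqs <- vapply(records, function(r) r$sequence, character(1))
    names(seqs) <- vapply(records, function(r) r$id, character(1))
  }
  for (i in seq_along(seqs)) {
    writeLines(paste0(">", names(seqs)[i]), con)
    s <- seqs[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a 12-column BLAST tabular hit file (outfmt 6)
#'
#' Columns: qseqid sseqid pident length mismatch gapopen qstart qend
#' sstart send evalue bitscore.  Minus-strand subject hits are encoded by
#' `sstart > send` (BLAST convention) and are preserved as such.
#'
#' @param path tab-separated file.
#' @return data.frame with the 12 standard columns.
#' @export
read_hit_table <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) return(empty_hits())
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    bad <- which(nf != 12L)[1L]
    stop(sprintf("line %d of %s has %d columns, expected 12",
                 bad, path, nf[bad]))
  }
  m <- do.call(rbind, fields)
  hits <- data.frame(
    qseqid = m[, 1], sseqid = m[, 2],
    pident = as.numeric(m[, 3]), length = as.integer(m[, 4]),
    mismatch = as.integer(m[, 5]), gapopen = as.integer(m[, 6]),
    qstart = as.integer(m[, 7]), qend = as.integer(m[, 8]),
    sstart = as.integer(m[, 9]), send = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), bitscore = as.numeric(m[, 12]),
    stringsAsFactors = FALSE)
  stopifnot(all(hits$qstart <= hits$qend),
            all(hits$pident >= 0 & hits$pident <= 100))
  hits
}

#' @rdname read_hit_table
#' @param hits hit data.frame.
#' @export
write_hit_table <- function(hits, path) {
  df <- hits[, c("qseqid", "sseqid", "pident", "length", "mismatch",
                 "gapopen", "qstart", "qend", "sstart", "send",
                 "evalue", "bitscore")]
  df$pident <- sprintf("%.2f", df$pident)
  df$evalue <- format(df$evalue, digits = 3, scientific = TRUE)
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

empty_hits <- function() {
  data.frame(qseqid = character(0), sseqid = character(0),
             pident = numeric(0), length = integer(0),
             mismatch = integer(0), gapopen = integer(0),
             qstart = integer(0), qend = integer(0),
             sstart = integer(0), send = integer(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Read a taxonomy table
#'
#' TSV with column 1 = genome id and column 2 = semicolon-separated
#' lineage ranks, broad to narrow (Table-1 style, e.g.
#' "asterids; lamiids; Solanales").
#'
#' @param path TSV file (no header).
#' @return named list: id -> character vector of ranks.
#' @export
read_taxonomy <- function(path) {
  df <- read.delim(path, header = FALSE, stringsAsFactors = FALSE,
                   colClasses = "character")
  if (ncol(df) < 2L) stop("taxonomy file needs 2 columns: id, lineage")
  out <- lapply(df[[2]], parse_lineage)
  names(out) <- trimws(df[[1]])
  empty <- !vapply(out, length, integer(1))
  if (any(empty))
    stop("empty lineage for id(s): ", paste(names(out)[empty], collapse = ", "))
  out
}

#' @rdname read_taxonomy
#' @param taxonomy named list of rank vectors.
#' @export
write_taxonomy <- function(taxonomy, path) {
  writeLines(paste(names(taxonomy),
                   vapply(taxonomy, format_lineage, character(1)),
                   sep = "\t"), path)
  invisible(path)
}

#' Read / write newick trees with integer support labels
#'
#' Thin wrappers over \pkg{ape} that guarantee the round trip preserves
#' topology, branch lengths (6 decimals) and integer internal-node
#' support labels.
#'
#' @param path newick file.
#' @return `read_newick()`: an \pkg{ape} `phylo` object.
#' @export
read_newick <- function(path) {
  tr <- ape::read.tree(path)
  if (is.null(tr)) stop("malformed newick in ", path)
  tr
}

#' @rdname read_newick
#' @param tree a `phylo` object, optionally with `node.label` supports.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path, digits = 6)
  invisible(path)
}

#' Read a GFF3 annotation file
#'
#' Only the columns the pipeline consumes are kept: seqid, type, start,
#' end, strand, and the `Name` (falling back to `ID` or `gene`)
#' attribute.
#'
#' @param path GFF3 file.
#' @return data.frame with columns `seqid,name,start,end,strand,kind`;
#'   `kind` is `"mtpt_annotation"` for types containing "mtpt", `"gene"`
#'   for gene/CDS/rRNA/tRNA records, otherwise `"other"`.
#' @export
read_gff3 <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines))
    return(data.frame(seqid = character(0), empty_features()))
  f <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(f) < 9L)) stop("GFF3 rows must have 9 columns")
  m <- do.call(rbind, f)
  attr_get <- function(attrs, key) {
    vapply(attrs, function(a) {
      hit <- regmatches(a, regexpr(paste0("(^|;)\\s*", key, "=[^;]+"), a))
      if (length(hit)) sub(paste0(".*", key, "="), "", hit) else NA_character_
    }, character(1), USE.NAMES = FALSE)
  }
  nm <- attr_get(m[, 9], "Name")
  for (fallback in c("ID", "gene")) {
    miss <- is.na(nm)
    if (any(miss)) nm[miss] <- attr_get(m[miss, 9, drop = TRUE], fallback)
  }
  type <- m[, 3]
  kind <- ifelse(grepl("mtpt", type, ignore.case = TRUE), "mtpt_annotation",
                 ifelse(type %in% c("gene", "CDS", "rRNA", "tRNA"),
                        "gene", "other"))
  data.frame(seqid = m[, 1], name = nm, start = as.integer(m[, 4]),
             end = as.integer(m[, 5]), strand = m[, 7], kind = kind,
             stringsAsFactors = FALSE)
}

#' @rdname read_gff3
#' @param features data.frame as returned by `read_gff3`.
#' @export
write_gff3 <- function(features, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("##gff-version 3", con)
  if (nrow(features)) {
    type <- ifelse(features$kind == "mtpt_annotation", "mtpt_annotation",
                   ifelse(features$kind == "gene", "gene", "region"))
    writeLines(sprintf("%s\torgHGT\t%s\t%d\t%d\t.\t%s\t.\tName=%s",
                       features$seqid, type, features$start, features$end,
                       features$strand, features$name), con)
  }
  invisible(path)
}

#' Load the packaged foreign-MTPT summary table
#'
#' A transcription of the published table of 46 foreign MTPTs known in
#' flowering-plant mitochondrial genomes: coordinates, gene content,
#' bootstrap support, donor lineage, the donor-sister (omega) flag, the
#' 5' / 3' flank evidence codes and the host-parasite flag.  Flank codes
#' are tokens like `"yes4"` / `"no3"`: the prefix is the published
#' mt-to-mt verdict for that flank, the digit the six-way category
#' (1 no hit; 2 all recipient-related; 3 unrelated only; 4 all
#' donor-related; 5 diverse, settled by phylogeny; 6 external evidence).
#'
#' @param path override the packaged fixture (for testing).
#' @return data.frame with one row per foreign MTPT record.
#' @export
read_table1 <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "table1_foreign_mtpts.tsv",
                        package = "orgHGT", mustWork = TRUE)
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = "NA",
                   colClasses = c(flank5_code = "character",
                                  flank3_code = "character"))
  df$donor_sister_flag <- as.logical(df$donor_sister_flag)
  df$host_parasite_flag <- as.logical(df$host_parasite_flag)
  df
}
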