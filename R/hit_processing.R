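.HIT_COLS <- c("query_id", "subject_id", "pident", "align_len", "mismatch",
               "gapopen", "q_start", "q_end", "s_start", "s_end",
               "evalue", "bit_score")

.as_hit_table <- function(df) {
  class(df) <- c("hit_table", "data.frame")
  df
}

#' Read tabular homology-search results
#'
#' Parses the 12-column BLAST tabular format (`-outfmt 6`: qseqid, sseqid,
#' pident, length, mismatch, gapopen, qstart, qend, sstart, send, evalue,
#' bitscore; `#` comment lines allowed) and resolves each subject to a
#' reference gene and its genome's taxon through `gene_map`. For translated
#' searches of an arbitrary-strand read, `qstart > qend` encodes a hit on
#' the read's reverse strand; the parser derives `strand` and the sorted
#' query interval `q_lo`/`q_hi` from it. Subjects absent from `gene_map`
#' are dropped with a message (reference protein sets and annotation tables
#' drift independently; a missing subject is not fatal).
#'
#' @param path path to the tabular file.
#' @param gene_map data.frame with columns `subject_id`, `gene_id`,
#'   `taxon_id`, or path to a TSV with those columns.
#' @return A `hit_table`: data.frame with the 12 parsed columns plus
#'   `strand`, `q_lo`, `q_hi`, `gene_id`, `taxon_id`.
#' @export
read_blast_tabular <- function(path, gene_map) {
  if (!file.exists(path)) stop("hit file not found: ", path, call. = FALSE)
  if (is.character(gene_map) && length(gene_map) == 1L)
    gene_map <- read.delim(gene_map, header = TRUE, sep = "\t",
                           comment.char = "#", stringsAsFactors = FALSE)
  gene_map <- as.data.frame(gene_map)
  stopifnot(all(c("subject_id", "gene_id", "taxon_id") %in% names(gene_map)))

  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  fields <- strsplit(lines[keep], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != 12L)) {
    i <- which(nf != 12L)[1L]
    stop("line ", lineno[i], ": expected 12 tab-separated columns, found ",
         nf[i], call. = FALSE)
  }
  if (length(fields) == 0L) {
    empty <- as.data.frame(setNames(
      c(list(character(0), character(0)), replicate(10, numeric(0),
                                                    simplify = FALSE)),
      .HIT_COLS))
    empty$strand <- character(0); empty$q_lo <- integer(0)
    empty$q_hi <- integer(0); empty$gene_id <- character(0)
    empty$taxon_id <- integer(0)
    return(.as_hit_table(empty))
  }
  m <- matrix(unlist(fields), ncol = 12L, byrow = TRUE)
  num <- suppressWarnings(apply(m[, 3:12, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, ncol = 10L)
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1L, ]
    stop("line ", lineno[bad[1L]], ": non-numeric value in column ",
         bad[2L] + 2L, call. = FALSE)
  }
  hits <- data.frame(query_id = m[, 1L], subject_id = m[, 2L],
                     stringsAsFactors = FALSE)
  for (j in 3:12) hits[[.HIT_COLS[j]]] <- num[, j - 2L]
  for (j in c("align_len", "mismatch", "gapopen",
              "q_start", "q_end", "s_start", "s_end"))
    hits[[j]] <- as.integer(hits[[j]])
  if (any(pmin(hits$q_start, hits$q_end) < 1L))
    stop("query coordinate below 1", call. = FALSE)
  if (any(hits$evalue < 0)) stop("negative E-value", call. = FALSE)

  hits$strand <- ifelse(hits$q_start > hits$q_end, "-", "+")
  hits$q_lo <- pmin(hits$q_start, hits$q_end)
  hits$q_hi <- pmax(hits$q_start, hits$q_end)

  idx <- match(hits$subject_id, as.character(gene_map$subject_id))
  n_drop <- sum(is.na(idx))
  if (n_drop > 0L)
    message("read_blast_tabular: dropped ", n_drop,
            " hit(s) whose subject is absent from the gene map")
  hits <- hits[!is.na(idx), , drop = FALSE]
  idx <- idx[!is.na(idx)]
  hits$gene_id <- as.character(gene_map$gene_id)[idx]
  hits$taxon_id <- as.integer(gene_map$taxon_id)[idx]
  rownames(hits) <- NULL
  .as_hit_table(hits)
}

#' Filter hits by E-value and keep the top N per query
#'
#' Applies the two knobs of the screening step: an E-value cut-off and a
#' per-query cap on the number of retained hits. Within each query, hits
#' passing the E-value cut are ranked by descending bit score (bit scores
#' are database-size independent, unlike E-values), with ties broken by
#' ascending E-value and then subject id, and truncated to `top_n`. With a
#' fixed `e_max`, retained sets are nested in `top_n`.
#'
#' @param hits a `hit_table`.
#' @param e_max E-value cut-off (default `1e-5`).
#' @param top_n per-query cap (default `250`).
#' @return The filtered `hit_table`, rows ordered by query id then rank.
#' @export
filter_hits <- function(hits, e_max = 1e-5, top_n = 250L) {
  stopifnot(e_max > 0, top_n >= 1L)
  hits <- as.data.frame(hits)
  hits <- hits[hits$evalue <= e_max, , drop = FALSE]
  if (nrow(hits) > 0L) {
    o <- order(hits$query_id, -hits$bit_score, hits$evalue, hits$subject_id)
    hits <- hits[o, , drop = FALSE]
    keep <- ave(seq_len(nrow(hits)), hits$query_id,
                FUN = seq_along) <= top_n
    hits <- hits[keep, , drop = FALSE]
  }
  rownames(hits) <- NULL
  .as_hit_table(hits)
}

#' Cluster the hits of one read into candidate coding loci
#'
#' Hits on one read are grouped into candidate CDS loci by single-linkage
#' clustering of their query intervals: two hits join the same locus iff
#' they lie on the same read strand and their interval overlap exceeds
#' `max_overlap_fraction` of the shorter interval. Opposite-strand hits
#' never merge (overlapping genes on opposite strands are genuine adjacent
#' pairs, not one locus). The locus interval is the union of its members'
#' intervals; the number of loci is the read's candidate CDS count.
#'
#' @param hits `hit_table` rows of a single query.
#' @param max_overlap_fraction overlap threshold as a fraction of the
#'   shorter interval (default 0.5).
#' @return A list of class `cds_loci` with elements `loci` (data.frame:
#'   `locus_id`, `query_id`, `lo`, `hi`, `strand`, `n_hits`) and
#'   `membership` (integer vector: locus id of each input hit row). Loci
#'   are numbered along the read (by `lo`, then `hi`).
#' @export
cluster_hits_to_loci <- function(hits, max_overlap_fraction = 0.5) {
  stopifnot(max_overlap_fraction >= 0, max_overlap_fraction <= 1)
  hits <- as.data.frame(hits)
  n <- nrow(hits)
  if (n > 0L && length(unique(hits$query_id)) != 1L)
    stop("cluster_hits_to_loci expects hits of a single query", call. = FALSE)
  if (n == 0L) {
    return(structure(list(
      loci = data.frame(locus_id = integer(0), query_id = character(0),
                        lo = integer(0), hi = integer(0),
                        strand = character(0), n_hits = integer(0)),
      membership = integer(0)), class = "cds_loci"))
  }
  # union-find single linkage
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
    if (hits$strand[i] != hits$strand[j]) next
    ov <- min(hits$q_hi[i], hits$q_hi[j]) - max(hits$q_lo[i], hits$q_lo[j]) + 1L
    if (ov <= 0L) next
    shorter <- min(hits$q_hi[i] - hits$q_lo[i] + 1L,
                   hits$q_hi[j] - hits$q_lo[j] + 1L)
    if (ov > max_overlap_fraction * shorter)
      parent[find(j)] <- find(i)
  }
  comp <- vapply(seq_len(n), find, integer(1))
  lo <- tapply(hits$q_lo, comp, min)
  hi <- tapply(hits$q_hi, comp, max)
  strand <- tapply(hits$strand, comp, `[`, 1L)
  sz <- tapply(seq_len(n), comp, length)
  o <- order(as.integer(lo), as.integer(hi))
  loci <- data.frame(locus_id = seq_along(o),
                     query_id = hits$query_id[1L],
                     lo = as.integer(lo)[o], hi = as.integer(hi)[o],
                     strand = as.character(strand)[o],
                     n_hits = as.integer(sz)[o],
                     stringsAsFactors = FALSE)
  relabel <- setNames(seq_along(o), names(lo)[o])
  membership <- unname(relabel[as.character(comp)])
  structure(list(loci = loci, membership = membership), class = "cds_loci")
}
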