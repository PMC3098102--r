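#' Find adjacency-consistent hit pairs on one read
#'
#' The core of the method. Hits of one read (already E-value/top-N filtered
#' and clustered into candidate CDS loci) are grouped by the taxon of their
#' subject genome. Within each taxon, every pair of hits from two distinct
#' loci is tested: the pair is *consistent* when (i) the two subject genes
#' are directly adjacent on one replicon of that taxon, and (ii) the
#' read-side arrangement — the order of the two loci along the read together
#' with their read strands — equals the reference arrangement (genomic order
#' plus strands) under the read as-is or under its reverse complement (a
#' shotgun read's orientation is arbitrary). Adjacent pairs failing (ii) are
#' emitted flagged inconsistent and play no further role; pairs of
#' non-adjacent genes are not emitted at all. With
#' `arrangement = "direction"` the test relaxes to equality of the
#' transcriptional direction class only (which is invariant under reverse
#' complement).
#'
#' Evidence is deduplicated at the (taxon, gene pair, consistency) level:
#' several hit pairs supporting the same reference gene pair count once.
#'
#' @param hits `hit_table` rows of one read, after [filter_hits].
#' @param loci the [cluster_hits_to_loci] result for these hits.
#' @param index an [build_adjacency_index] result.
#' @param arrangement `"full"` (order + strands, default) or `"direction"`.
#' @return data.frame of class `pair_evidence` with columns `read_id`,
#'   `taxon_id`, `genome_id`, `replicon_id`, `gene_a`, `gene_b` (genomic
#'   order), `direction`, `consistent`; ordered by (taxon_id, gene_a,
#'   gene_b).
#' @export
find_consistent_pairs <- function(hits, loci, index,
                                  arrangement = c("full", "direction")) {
  arrangement <- match.arg(arrangement)
  hits <- as.data.frame(hits)
  empty <- data.frame(read_id = character(0), taxon_id = integer(0),
                      genome_id = character(0), replicon_id = character(0),
                      gene_a = character(0), gene_b = character(0),
                      direction = character(0), consistent = logical(0),
                      stringsAsFactors = FALSE)
  class(empty) <- c("pair_evidence", "data.frame")
  if (nrow(hits) == 0L) return(empty)
  stopifnot(length(loci$membership) == nrow(hits))
  read_id <- hits$query_id[1L]

  # candidate units: distinct (taxon, gene, locus)
  cand <- unique(data.frame(taxon_id = hits$taxon_id,
                            gene_id = hits$gene_id,
                            locus_id = loci$membership,
                            stringsAsFactors = FALSE))
  cand$locus_lo <- loci$loci$lo[cand$locus_id]
  cand$locus_strand <- loci$loci$strand[cand$locus_id]

  lk <- .adjacency_lookup(index)
  rows <- vector("list", 0L)
  for (tx in unique(cand$taxon_id)) {
    sub <- cand[cand$taxon_id == tx, , drop = FALSE]
    if (length(unique(sub$locus_id)) < 2L) next
    n <- nrow(sub)
    for (i in seq_len(n - 1L)) for (j in seq.int(i + 1L, n)) {
      if (sub$locus_id[i] == sub$locus_id[j]) next
      ga <- sub$gene_id[i]; gb <- sub$gene_id[j]
      if (ga == gb) next
      ri <- get0(paste(tx, ga, gb, sep = "\r"), envir = lk)
      if (is.null(ri)) next
      ref <- index[ri, ]
      # orient the two units along the read (locus order = read order)
      if (sub$locus_id[i] < sub$locus_id[j]) { a <- i; b <- j } else { a <- j; b <- i }
      g1 <- sub$gene_id[a]; s1 <- sub$locus_strand[a]
      g2 <- sub$gene_id[b]; s2 <- sub$locus_strand[b]
      ok <- if (arrangement == "direction") {
        direction_class(s1, s2) == ref$direction
      } else {
        (g1 == ref$gene_lo && g2 == ref$gene_hi &&
           s1 == ref$strand_lo && s2 == ref$strand_hi) ||
        (g1 == ref$gene_hi && g2 == ref$gene_lo &&
           s1 == .flip_strand(ref$strand_hi) &&
           s2 == .flip_strand(ref$strand_lo))
      }
      rows[[length(rows) + 1L]] <- data.frame(
        read_id = read_id, taxon_id = as.integer(tx),
        genome_id = ref$genome_id, replicon_id = ref$replicon_id,
        gene_a = ref$gene_lo, gene_b = ref$gene_hi,
        direction = ref$direction, consistent = ok,
        stringsAsFactors = FALSE)
    }
  }
  if (length(rows) == 0L) return(empty)
  out <- unique(do.call(rbind, rows))
  out <- out[order(out$taxon_id, out$gene_a, out$gene_b), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("pair_evidence", "data.frame")
  out
}

.assignment_row <- function(read_id, tree = NULL, taxon = NA_integer_,
                            n_taxa = 0L, n_pairs = 0L) {
  assigned <- !is.na(taxon)
  proj <- setNames(rep(NA_integer_, length(.RANKS)), .RANKS)
  rank <- NA_character_; name <- NA_character_
  if (assigned) {
    for (r in .RANKS) proj[r] <- project_to_rank(tree, taxon, r)
    rank <- taxon_rank(tree, taxon)
    name <- taxon_name(tree, taxon)
  }
  out <- data.frame(read_id = read_id,
                    status = if (assigned) "assigned" else "unclassified",
                    taxon_id = taxon, rank = rank, name = name,
                    stringsAsFactors = FALSE)
  for (r in .RANKS) out[[r]] <- proj[[r]]
  out$n_supporting_taxa <- n_taxa
  out$n_consistent_pairs <- n_pairs
  out
}

#' Assign one read by LCA over its supporting taxa
#'
#' Takes the consistent-pair evidence of one read, collects the supporting
#' taxa (taxa with at least one consistent adjacent pair), and assigns the
#' read to their lowest common ancestor. Reads with fewer supporting taxa
#' than `min_support` (default 1, i.e. any consistent evidence suffices)
#' are left unclassified.
#'
#' @param pairs a `pair_evidence` data.frame from [find_consistent_pairs]
#'   (all rows from one read).
#' @param tree a [taxonomy_tree].
#' @param read_id read identifier, required when `pairs` is empty.
#' @param min_support minimum number of distinct supporting taxa.
#' @return One-row data.frame: `read_id`, `status`, `taxon_id`, `rank`,
#'   `name`, one column per canonical rank with the projected taxon id (NA
#'   where the lineage has no node at that rank), `n_supporting_taxa`,
#'   `n_consistent_pairs`.
#' @export
assign_read <- function(pairs, tree, read_id = NULL, min_support = 1L) {
  pairs <- as.data.frame(pairs)
  if (is.null(read_id)) {
    if (nrow(pairs) == 0L)
      stop("read_id required when pairs is empty", call. = FALSE)
    read_id <- pairs$read_id[1L]
  }
  cons <- pairs[pairs$consistent, , drop = FALSE]
  taxa <- sort(unique(cons$taxon_id))
  if (nrow(cons) == 0L || length(taxa) < min_support)
    return(.assignment_row(read_id))
  .assignment_row(read_id, tree, lca(tree, taxa),
                  n_taxa = length(taxa), n_pairs = nrow(cons))
}

#' Bin a whole dataset of reads
#'
#' Runs the full pipeline over every query in a hit table: E-value/top-N
#' filtering, clustering of hits into candidate CDS loci, detection of
#' adjacency-consistent pairs per reference taxon, and LCA assignment. One
#' assignment row is produced for every query id present in the input
#' table, unclassified ones included. `method = "lca"` is the comparison
#' mode without the adjacency criterion: each read is assigned by plain LCA
#' over the taxa of all its filtered hits (no pairing, no arrangement
#' check).
#'
#' @param hits a `hit_table` (see [read_blast_tabular]).
#' @param index an [build_adjacency_index] result (unused for
#'   `method = "lca"`).
#' @param tree a [taxonomy_tree].
#' @param e_max,top_n filtering criteria, see [filter_hits].
#' @param max_overlap_fraction see [cluster_hits_to_loci].
#' @param min_support see [assign_read].
#' @param arrangement see [find_consistent_pairs].
#' @param method `"adjacency"` (the method) or `"lca"` (plain-LCA control).
#' @return data.frame of class `binning_result`, one row per read (see
#'   [assign_read]), ordered by `read_id`; criteria stored in
#'   `attr(, "criteria")`.
#' @export
bin_dataset <- function(hits, index, tree, e_max = 1e-5, top_n = 250L,
                        max_overlap_fraction = 0.5, min_support = 1L,
                        arrangement = c("full", "direction"),
                        method = c("adjacency", "lca")) {
  arrangement <- match.arg(arrangement)
  method <- match.arg(method)
  hits <- as.data.frame(hits)
  all_reads <- sort(unique(hits$query_id))
  kept <- as.data.frame(filter_hits(hits, e_max = e_max, top_n = top_n))
  parts <- split(seq_len(nrow(kept)), kept$query_id)
  rows <- lapply(all_reads, function(rid) {
    idx <- parts[[rid]]
    if (is.null(idx) || length(idx) == 0L) return(.assignment_row(rid))
    rh <- kept[idx, , drop = FALSE]
    if (method == "lca") {
      taxa <- sort(unique(rh$taxon_id))
      if (length(taxa) < min_support) return(.assignment_row(rid))
      return(.assignment_row(rid, tree, lca(tree, taxa),
                             n_taxa = length(taxa), n_pairs = 0L))
    }
    loci <- cluster_hits_to_loci(rh, max_overlap_fraction)
    if (nrow(loci$loci) < 2L) return(.assignment_row(rid))
    ev <- find_consistent_pairs(rh, loci, index, arrangement = arrangement)
    assign_read(ev, tree, read_id = rid, min_support = min_support)
  })
  template <- .assignment_row("")[0, , drop = FALSE]
  out <- do.call(rbind, c(rows, list(template)))
  rownames(out) <- NULL
  attr(out, "criteria") <- list(e_max = e_max, top_n = top_n,
                                max_overlap_fraction = max_overlap_fraction,
                                min_support = min_support,
                                arrangement = arrangement, method = method)
  class(out) <- c("binning_result", "data.frame")
  out
}

#' @export
print.binning_result <- function(x, ...) {
  n <- nrow(x)
  na <- sum(x$status == "assigned")
  cat("<binning_result> ", n, " read(s): ", na, " assigned, ", n - na,
      " unclassified", sep = "")
  if (n > 0L)
    cat(" (recovery ", format_rate(recovery_rate(na, n)), "%)", sep = "")
  cat("\n")
  invisible(x)
}
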