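# Brute-force oracle for the consistent-pair search, kept independent of
# the package's adjacency index: adjacency is recomputed by sorting the raw
# gene table, and both read orientations are enumerated explicitly as
# arrangement tuples.

oracle_adjacent <- function(genes, replicons, taxon, ga, gb) {
  g <- genes[genes$taxon_id == taxon, , drop = FALSE]
  ia <- which(g$gene_id == ga); ib <- which(g$gene_id == gb)
  if (length(ia) != 1 || length(ib) != 1) return(NULL)
  if (g$replicon_id[ia] != g$replicon_id[ib]) return(NULL)
  r <- g[g$replicon_id == g$replicon_id[ia], , drop = FALSE]
  r <- r[order(r$start, r$end, r$gene_id), , drop = FALSE]
  pa <- which(r$gene_id == ga); pb <- which(r$gene_id == gb)
  n <- nrow(r)
  topo <- replicons$topology[match(r$replicon_id[1], replicons$replicon_id)]
  if (abs(pa - pb) == 1) {
    lo <- min(pa, pb); hi <- max(pa, pb)
  } else if (identical(topo, "circular") && n >= 3 &&
             setequal(c(pa, pb), c(1, n))) {
    lo <- n; hi <- 1          # local order crossing the origin
  } else return(NULL)
  list(gene_lo = r$gene_id[lo], strand_lo = r$strand[lo],
       gene_hi = r$gene_id[hi], strand_hi = r$strand[hi])
}

oracle_flip <- function(s) ifelse(s == "+", "-", "+")

oracle_consistent_pairs <- function(hits, membership, loci_df, genes,
                                    replicons) {
  units <- unique(data.frame(taxon_id = hits$taxon_id,
                             gene_id = hits$gene_id,
                             locus_id = membership,
                             stringsAsFactors = FALSE))
  out <- NULL
  n <- nrow(units)
  if (n >= 2) for (i in 1:(n - 1)) for (j in (i + 1):n) {
    ui <- units[i, ]; uj <- units[j, ]
    if (ui$taxon_id != uj$taxon_id) next
    if (ui$locus_id == uj$locus_id) next
    if (ui$gene_id == uj$gene_id) next
    ref <- oracle_adjacent(genes, replicons, ui$taxon_id,
                           ui$gene_id, uj$gene_id)
    if (is.null(ref)) next
    # read arrangement, both orientations, as explicit 4-tuples
    first <- if (ui$locus_id < uj$locus_id) ui else uj
    second <- if (ui$locus_id < uj$locus_id) uj else ui
    s1 <- loci_df$strand[first$locus_id]
    s2 <- loci_df$strand[second$locus_id]
    fwd <- c(first$gene_id, s1, second$gene_id, s2)
    rc <- c(second$gene_id, oracle_flip(s2), first$gene_id, oracle_flip(s1))
    reftup <- c(ref$gene_lo, ref$strand_lo, ref$gene_hi, ref$strand_hi)
    ok <- identical(fwd, reftup) || identical(rc, reftup)
    out <- rbind(out, data.frame(taxon_id = ui$taxon_id,
                                 gene_a = ref$gene_lo, gene_b = ref$gene_hi,
                                 consistent = ok, stringsAsFactors = FALSE))
  }
  if (is.null(out))
    return(data.frame(taxon_id = integer(0), gene_a = character(0),
                      gene_b = character(0), consistent = logical(0)))
  out <- unique(out)
  out[order(out$taxon_id, out$gene_a, out$gene_b), , drop = FALSE]
}

# random instance: a random small catalog plus hits scattered over random
# disjoint read loci
random_instance <- function() {
  n_genomes <- sample(1:3, 1)
  genes <- NULL
  replicons <- NULL
  for (k in seq_len(n_genomes)) {
    n_g <- sample(4:8, 1)
    len <- sample(200:900, n_g, replace = TRUE)
    gap <- sample(0:200, n_g, replace = TRUE)
    start <- cumsum(c(1, (len + gap)[-n_g]))
    topo <- sample(c("linear", "circular"), 1)
    genes <- rbind(genes, data.frame(
      genome_id = paste0("g", k), replicon_id = paste0("r", k),
      taxon_id = k, gene_id = paste0("g", k, "_", seq_len(n_g)),
      start = start, end = start + len - 1,
      strand = sample(c("+", "-"), n_g, replace = TRUE),
      stringsAsFactors = FALSE))
    replicons <- rbind(replicons, data.frame(
      replicon_id = paste0("r", k), topology = topo,
      length = max(start + len - 1) + 50, stringsAsFactors = FALSE))
  }
  n_loci <- sample(2:4, 1)
  loci_df <- data.frame(locus_id = seq_len(n_loci),
                        query_id = "q1",
                        lo = seq(1, by = 400, length.out = n_loci),
                        hi = seq(300, by = 400, length.out = n_loci),
                        strand = sample(c("+", "-"), n_loci, replace = TRUE),
                        n_hits = 0L, stringsAsFactors = FALSE)
  n_hits <- sample(2:12, 1)
  pick <- sample(seq_len(nrow(genes)), n_hits, replace = TRUE)
  locus <- sample(seq_len(n_loci), n_hits, replace = TRUE)
  hits <- do.call(rbind, lapply(seq_len(n_hits), function(h) {
    hit_row("q1", genes$gene_id[pick[h]], genes$taxon_id[pick[h]],
            loci_df$lo[locus[h]], loci_df$hi[locus[h]],
            strand = loci_df$strand[locus[h]])
  }))
  class(hits) <- c("hit_table", "data.frame")
  list(genes = genes, replicons = replicons,
       catalog = gene_catalog(genes, replicons),
       hits = hits, membership = locus, loci_df = loci_df)
}

check_oracle_equivalence <- function(n_instances, seed) {
  withr::with_seed(seed, {
    for (it in seq_len(n_instances)) {
      inst <- random_instance()
      index <- build_adjacency_index(inst$catalog)
      loci <- loci_of(inst$hits, inst$membership, inst$loci_df)
      got <- find_consistent_pairs(inst$hits, loci, index)
      got <- as.data.frame(got)[, c("taxon_id", "gene_a", "gene_b",
                                    "consistent")]
      class(got) <- "data.frame"
      rownames(got) <- NULL
      want <- oracle_consistent_pairs(inst$hits, inst$membership,
                                      inst$loci_df, inst$genes,
                                      inst$replicons)
      rownames(want) <- NULL
      expect_equal(got, want, info = paste("instance", it))
    }
  })
}
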