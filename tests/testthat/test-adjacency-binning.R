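# reference for worked examples: tiny_catalog genome GA (taxon 61) has
# a1(+) a2(+) a3(-) in that order; GB (taxon 62) is circular b1(+) b2(-)
# b3(+); GC (taxon 63) has c1(+) c2(+).

two_locus_read <- function(gene1, strand1, gene2, strand2, taxon = 61) {
  hits <- rbind(hit_row("r1", gene1, taxon, 1, 300, strand = strand1),
                hit_row("r1", gene2, taxon, 400, 700, strand = strand2))
  loci <- loci_of(hits, c(1L, 2L), data.frame(
    locus_id = 1:2, query_id = "r1", lo = c(1L, 400L), hi = c(300L, 700L),
    strand = c(strand1, strand2), n_hits = 1L, stringsAsFactors = FALSE))
  list(hits = hits, loci = loci)
}

test_that("a read matching the reference arrangement yields a consistent pair", {
  idx <- build_adjacency_index(tiny_catalog())
  rd <- two_locus_read("a1", "+", "a2", "+")
  ev <- find_consistent_pairs(rd$hits, rd$loci, idx)
  expect_equal(nrow(ev), 1L)
  expect_true(ev$consistent)
  expect_equal(ev$direction, "unidirectional")
  expect_equal(c(ev$gene_a, ev$gene_b), c("a1", "a2"))
})

test_that("swapped gene order without strand flips is flagged inconsistent", {
  idx <- build_adjacency_index(tiny_catalog())
  rd <- two_locus_read("a2", "+", "a1", "+")
  ev <- find_consistent_pairs(rd$hits, rd$loci, idx)
  expect_equal(nrow(ev), 1L)
  expect_false(ev$consistent)
})

test_that("the reverse-complement of a valid arrangement is consistent", {
  idx <- build_adjacency_index(tiny_catalog())
  # a1(+) a2(+) read in reverse complement: a2 first, both on reverse strand
  rd <- two_locus_read("a2", "-", "a1", "-")
  ev <- find_consistent_pairs(rd$hits, rd$loci, idx)
  expect_true(ev$consistent)
  # convergent pair a2(+) a3(-): as-is and reverse complement both valid
  rd2 <- two_locus_read("a2", "+", "a3", "-")
  expect_true(find_consistent_pairs(rd2$hits, rd2$loci, idx)$consistent)
  rd3 <- two_locus_read("a3", "+", "a2", "-")
  expect_true(find_consistent_pairs(rd3$hits, rd3$loci, idx)$consistent)
  # but flipping only one strand breaks the arrangement
  rd4 <- two_locus_read("a2", "+", "a3", "+")
  expect_false(find_consistent_pairs(rd4$hits, rd4$loci, idx)$consistent)
})

test_that("non-adjacent genes yield no pair and same-locus hits never pair", {
  idx <- build_adjacency_index(tiny_catalog())
  rd <- two_locus_read("a1", "+", "a3", "-")   # a2 lies between them
  expect_equal(nrow(find_consistent_pairs(rd$hits, rd$loci, idx)), 0L)
  # two hits on one locus are alternative identities of one CDS
  hits <- rbind(hit_row("r1", "a1", 61, 1, 300),
                hit_row("r1", "a2", 61, 1, 300))
  loci <- loci_of(hits, c(1L, 1L), data.frame(
    locus_id = 1L, query_id = "r1", lo = 1L, hi = 300L, strand = "+",
    n_hits = 2L, stringsAsFactors = FALSE))
  expect_equal(nrow(find_consistent_pairs(hits, loci, idx)), 0L)
  # hits in different taxa never pair with each other
  hits2 <- rbind(hit_row("r1", "a1", 61, 1, 300),
                 hit_row("r1", "b2", 62, 400, 700, strand = "-"))
  loci2 <- loci_of(hits2, c(1L, 2L), data.frame(
    locus_id = 1:2, query_id = "r1", lo = c(1L, 400L),
    hi = c(300L, 700L), strand = c("+", "-"), n_hits = 1L,
    stringsAsFactors = FALSE))
  expect_equal(nrow(find_consistent_pairs(hits2, loci2, idx)), 0L)
})

test_that("the circular wrap pair is usable evidence", {
  idx <- build_adjacency_index(tiny_catalog())
  # b3(+) then b1(+) crossing the origin of circular chrB
  rd <- two_locus_read("b3", "+", "b1", "+", taxon = 62)
  ev <- find_consistent_pairs(rd$hits, rd$loci, idx)
  expect_true(ev$consistent)
  expect_equal(c(ev$gene_a, ev$gene_b), c("b3", "b1"))
})

test_that("direction-only mode relaxes the arrangement requirement", {
  idx <- build_adjacency_index(tiny_catalog())
  # swapped unidirectional pair: inconsistent in full mode, fine by class
  rd <- two_locus_read("a2", "+", "a1", "+")
  expect_false(find_consistent_pairs(rd$hits, rd$loci, idx)$consistent)
  expect_true(find_consistent_pairs(rd$hits, rd$loci, idx,
                                    arrangement = "direction")$consistent)
})

test_that("consistent-pair search matches the brute-force oracle", {
  check_oracle_equivalence(n_instances = 200, seed = 1234)
})

test_that("reverse-complementing the read leaves pair labels unchanged", {
  withr::with_seed(77, {
    for (it in 1:50) {
      inst <- random_instance()
      idx <- build_adjacency_index(inst$catalog)
      loci <- loci_of(inst$hits, inst$membership, inst$loci_df)
      ev1 <- find_consistent_pairs(inst$hits, loci, idx)
      # flip the read: reverse locus order, flip all strands
      n <- nrow(inst$loci_df)
      span <- max(inst$loci_df$hi) + 1L
      flipped_df <- data.frame(
        locus_id = 1:n, query_id = "q1",
        lo = span - inst$loci_df$hi[n:1],
        hi = span - inst$loci_df$lo[n:1],
        strand = ifelse(inst$loci_df$strand[n:1] == "+", "-", "+"),
        n_hits = 0L, stringsAsFactors = FALSE)
      new_membership <- (n + 1L) - inst$membership
      fhits <- inst$hits
      fhits$strand <- ifelse(fhits$strand == "+", "-", "+")
      fhits$q_lo <- flipped_df$lo[new_membership]
      fhits$q_hi <- flipped_df$hi[new_membership]
      ev2 <- find_consistent_pairs(fhits,
                                   loci_of(fhits, new_membership, flipped_df),
                                   idx)
      expect_equal(ev1, ev2)
    }
  })
})

test_that("reads are assigned by LCA over supporting taxa", {
  tr <- tiny_tree()
  ev1 <- data.frame(read_id = "r1", taxon_id = 61L, genome_id = "GA",
                    replicon_id = "chrA", gene_a = "a1", gene_b = "a2",
                    direction = "unidirectional", consistent = TRUE)
  a1 <- assign_read(ev1, tr)
  expect_equal(a1$status, "assigned")
  expect_equal(a1$taxon_id, 61L)
  expect_equal(a1$species, 61L)
  expect_equal(a1$genus, 50L)
  expect_equal(a1$phylum, 10L)
  # two species under one genus -> genus; species projection lost
  ev2 <- rbind(ev1, within(ev1, { taxon_id <- 62L; gene_a <- "b1"
                                  gene_b <- "b2" }))
  a2 <- assign_read(ev2, tr)
  expect_equal(a2$taxon_id, 50L)
  expect_equal(a2$rank, "genus")
  expect_true(is.na(a2$species))
  expect_equal(a2$n_supporting_taxa, 2L)
  # no consistent evidence -> unclassified
  ev3 <- within(ev1, consistent <- FALSE)
  a3 <- assign_read(ev3, tr)
  expect_equal(a3$status, "unclassified")
  expect_equal(a3$n_consistent_pairs, 0L)
  # min_support above the support level -> unclassified
  expect_equal(assign_read(ev1, tr, min_support = 2)$status, "unclassified")
})

test_that("bin_dataset composes the pipeline over every query", {
  cat <- tiny_catalog(); idx <- build_adjacency_index(cat)
  tr <- tiny_tree()
  hits <- rbind(
    hit_row("r1", "a1", 61, 1, 300),           # consistent pair on r1
    hit_row("r1", "a2", 61, 400, 700),
    hit_row("r2", "c1", 63, 1, 250),           # single locus on r2
    hit_row("r3", "a1", 61, 1, 300, evalue = 1e-3))  # fails E cut
  res <- bin_dataset(hits, idx, tr)
  expect_s3_class(res, "binning_result")
  expect_equal(res$read_id, c("r1", "r2", "r3"))
  expect_equal(res$status, c("assigned", "unclassified", "unclassified"))
  expect_equal(res$taxon_id[1], 61L)
  # determinism: identical inputs give identical output
  expect_identical(as.data.frame(res),
                   as.data.frame(bin_dataset(hits, idx, tr)))
  # empty table -> empty result
  expect_equal(nrow(bin_dataset(hits[0, ], idx, tr)), 0L)
})

test_that("reads with fewer than two loci are always unclassified", {
  com <- small_community(seed = 5, n_reads = 120)
  res <- bin_dataset(com$hits, com$index, com$tree)
  single <- com$reads$read_id[com$reads$n_genes < 2]
  expect_true(all(res$status[res$read_id %in% single] == "unclassified"))
})

test_that("the consistent-pair set is nested in top_n", {
  # nested hit sets (fixed loci) can only grow the consistent-pair set
  withr::with_seed(9, {
    for (it in 1:30) {
      inst <- random_instance()
      idx <- build_adjacency_index(inst$catalog)
      o <- order(-inst$hits$bit_score, inst$hits$evalue,
                 inst$hits$subject_id)
      prev <- NULL
      for (tn in c(2, 4, 8, nrow(inst$hits))) {
        keep <- sort(o[seq_len(min(tn, length(o)))])
        ev <- find_consistent_pairs(inst$hits[keep, , drop = FALSE],
                                    loci_of(NULL, inst$membership[keep],
                                            inst$loci_df), idx)
        keys <- paste(ev$taxon_id, ev$gene_a, ev$gene_b, ev$consistent)
        if (!is.null(prev)) expect_true(all(prev %in% keys))
        prev <- keys
      }
    }
  })
})
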