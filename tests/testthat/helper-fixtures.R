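# Shared fixtures: a small three-genome catalog, a two-lineage taxonomy,
# and constructors for hand-built hit tables and loci.

tiny_catalog <- function() {
  genes <- data.frame(
    genome_id = c("GA", "GA", "GA", "GB", "GB", "GB", "GC", "GC"),
    replicon_id = c("chrA", "chrA", "chrA", "chrB", "chrB", "chrB",
                    "chrC", "chrC"),
    taxon_id = c(61, 61, 61, 62, 62, 62, 63, 63),
    gene_id = c("a1", "a2", "a3", "b1", "b2", "b3", "c1", "c2"),
    start = c(1, 1001, 2001, 1, 901, 1801, 100, 800),
    end = c(900, 1900, 2900, 800, 1700, 2600, 700, 1400),
    strand = c("+", "+", "-", "+", "-", "+", "+", "+"),
    stringsAsFactors = FALSE)
  replicons <- data.frame(replicon_id = c("chrA", "chrB", "chrC"),
                          topology = c("linear", "circular", "linear"),
                          length = c(3000, 3000, 1500),
                          stringsAsFactors = FALSE)
  gene_catalog(genes, replicons)
}

tiny_tree <- function() {
  taxonomy_tree(data.frame(
    taxon_id  = c(1, 2, 10, 11, 20, 21, 30, 31, 40, 41, 50, 51, 52,
                  61, 62, 63, 70, 90),
    parent_id = c(NA, 1, 2, 2, 10, 11, 20, 21, 30, 31, 40, 40, 41,
                  50, 50, 51, 52, 21),
    rank = c("no rank", "superkingdom", "phylum", "phylum", "class",
             "class", "order", "order", "family", "family", "genus",
             "genus", "genus", "species", "species", "species",
             "species", "no rank"),
    name = c("root", "Bacteria", "P1", "P2", "C1", "C2", "O1", "O2",
             "F1", "F2", "G1", "G2", "G3", "s1", "s2", "s3", "s4",
             "clade_x"),
    stringsAsFactors = FALSE))
}

# one hand-built hit-table row in the shape read_blast_tabular produces
hit_row <- function(query, gene, taxon, q_lo, q_hi, strand = "+",
                    evalue = 1e-20, bit = 100, subject = gene) {
  data.frame(query_id = query, subject_id = subject, pident = 95,
             align_len = as.integer((q_hi - q_lo + 1) %/% 3),
             mismatch = 2L, gapopen = 0L,
             q_start = if (strand == "+") q_lo else q_hi,
             q_end = if (strand == "+") q_hi else q_lo,
             s_start = 1L, s_end = 100L, evalue = evalue,
             bit_score = bit, strand = strand,
             q_lo = as.integer(q_lo), q_hi = as.integer(q_hi),
             gene_id = gene, taxon_id = as.integer(taxon),
             stringsAsFactors = FALSE)
}

hit_table_of <- function(...) {
  out <- do.call(rbind, list(...))
  class(out) <- c("hit_table", "data.frame")
  out
}

# loci built by construction (bypassing cluster_hits_to_loci): hits are
# placed on predefined disjoint loci
loci_of <- function(hits, locus_id, loci_df) {
  structure(list(loci = loci_df, membership = as.integer(locus_id)),
            class = "cds_loci")
}

small_community <- function(seed = 11, n_reads = 150, ...) {
  simulate_community(sim_config(n_reads = n_reads, n_genomes = 8,
                                genes_per_genome = 30, seed = seed, ...))
}
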