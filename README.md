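# adjbin — taxonomic binning of metagenomic fragments by conserved gene adjacency

Homology-based taxonomic binning of Sanger-scale shotgun metagenomes
discards 30–40% of fragments whose BLAST scores fall below the usual
cut-offs. Many of those fragments are ~1 kb long — about the average gene
density of prokaryotic genomes (one gene per 1,000 nt) — so roughly half of
them carry *two* partial coding regions. `adjbin` rescues such fragments
with a criterion that two weak hits cannot fake by chance: the two hit
genes must be **directly adjacent** in a reference genome, with a
**transcriptional arrangement** (gene order and strands, hence the
direction class →→, →← or ←→) consistent with what the read shows, up to
the read's arbitrary orientation. Reads passing the criterion are assigned
by **lowest common ancestor** (LCA) over all supporting taxa; the rest stay
`unclassified`.

The package is aimed at microbiome researchers who have BLASTX-style
tabular hits of unassigned reads against an annotated reference genome set
and want to recover taxonomic signal from the discard pile — plus the
evaluation machinery to decide whether to trust it.

## Method in brief

For each read: parse 12-column tabular hits, keep hits with E ≤ *E*max
(default 10⁻⁵) and the top *N* (default 250) by bit score; cluster hit
intervals into candidate CDS loci (single-linkage, same strand, overlap
above half the shorter interval merges); group hits by reference taxon;
for every pair of hits from two distinct loci, test whether the subject
genes are adjacent (consecutive along a replicon; the last–first pair also
counts on circular replicons) and whether read-side order and strands
equal the genomic arrangement under the read as-is or reverse-complemented;
assign by LCA over taxa with consistent pairs.

Accuracy on truth-labeled data is scored per taxonomic class *i* at each
rank:

    Sn_i = TP_i / (TP_i + FN_i + U_i)        Sp_i = TP_i / (TP_i + FP_i)

where `U_i` counts fragments of class *i* that are unclassified or
assigned above the rank. Composition profiles of two binnings are compared
by Pearson correlation after pooling phylotypes with fewer than five
fragments into a shared "other" category.

A seeded simulator (`simulate_community()`) generates reference genomes at
the 1-gene-per-kb density, ~1 kb reads with truth labels, and noisy hit
tables (true hits, adjacency-preserving homolog hits in sister species,
spurious hits), so the whole pipeline is testable without downloads.

## Worked example

```r
library(adjbin)

cfg <- sim_config(n_reads = 400, seed = 1)
com <- simulate_community(cfg)
com
#> <sim_community> 400 read(s) from 8 genome(s); 1550 hit(s); 367 read(s) overlap >= 2 genes

res <- bin_dataset(com$hits, com$index, com$tree, e_max = 1e-5, top_n = 250)
res
#> <binning_result> 400 read(s): 365 assigned, 35 unclassified (recovery 91.2%)

acc <- accuracy_table(confusion_counts(res, com$truth, com$tree, "genus"))
attr(acc, "summary")
#>    rank  macro_sn macro_sp micro_sn micro_sp
#> 1 genus 0.9124177        1   0.9125        1

bm <- run_benchmark(com, e_values = 1e-4, top_ns = 250, ranks = "family")
bm[, c("method", "rank", "micro_sn", "micro_sp", "recovery")]
#>      method   rank micro_sn micro_sp recovery
#> 1 adjacency family    91.25      100    91.25
#> 2       lca family    69.50      100   100.00
```

365 of 400 simulated reads (91.2%) are recovered; 35 stay unclassified
because they overlap fewer than two genes. Genus-rank specificity is 1:
every genus-level call is correct, because a consistent adjacent pair is
essentially impossible to produce from wrong-taxon hits. The benchmark row
shows the point of the adjacency criterion: plain LCA over the same
filtered hits assigns *every* read but lands above family for a third of
them (Sn 69.5% vs 91.3%), since homolog hits in related species pull the
LCA up; demanding a consistent adjacent pair keeps the assignment low and
specific. Composition profiles compare the estimated to the true community:

```r
p_est <- composition_profile(res, com$tree, "genus")
p_est
#>   taxon_id    name count
#> 1        9 genus_2    96
#> 2        8 genus_1    94
#> 3       10 genus_3    93
#> 4       11 genus_4    82
truth_asg <- data.frame(read_id = names(com$truth), status = "assigned",
                        taxon_id = unname(com$truth))
pooled <- pool_rare_phylotypes(p_est,
                               composition_profile(truth_asg, com$tree, "genus"))
pearson_compare(pooled$a, pooled$b)
#> [1] 0.9110383
```

A thin command-line wrapper ships in `inst/exec/adjbin`
(`adjbin simulate | assign | evaluate | compare`).

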