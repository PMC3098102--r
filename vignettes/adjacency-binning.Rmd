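---
title: "Binning discarded metagenomic fragments by conserved gene adjacency"
author: "adjbin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Binning discarded metagenomic fragments by conserved gene adjacency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem and the idea

Taxonomic binning of shotgun metagenomes by translated homology search
throws away every fragment whose best hit is too weak. For Sanger-scale
reads (~1 kb) that discard pile is large — typically 30–40% of the data —
yet far from hopeless: prokaryotic genomes average about one gene per
1,000 nucleotides, so a 1 kb fragment frequently straddles *two* partial
coding regions. Two individually unconvincing hits become convincing
jointly when the two hit genes are **directly adjacent** in a reference
genome and their arrangement on the read — order along the fragment and
strand of each hit — matches the genomic arrangement. Gene order decays
quickly over evolutionary distance, so a conserved adjacent pair is a
strong, taxon-specific signal that single-hit scores cannot provide, and
one that horizontal transfer of single genes rarely mimics.

`adjbin` implements this criterion end to end: reference indexing, hit
filtering, adjacency testing, lowest-common-ancestor (LCA) assignment,
accuracy evaluation, composition-profile comparison, and a seeded
simulator for benchmarking.

## The procedure

1. **Reference index.** Gene annotations (TSV dialect or GFF3) become a
   `gene_catalog`: genes sorted along each replicon get a 0-based
   `order_rank`; adjacency is *consecutive order rank*, so an intervening
   annotated gene breaks adjacency even when coordinates are close, and
   coordinate-overlapping gene pairs (common in prokaryotes) are adjacent
   like any other neighbours. Each adjacent pair carries its
   transcriptional direction class taken in genomic order: unidirectional
   (→→ or ←←), convergent (→←), divergent (←→). Pairs never span
   replicons — a plasmid gene is never adjacent to a chromosomal one.
2. **Hit filtering.** 12-column tabular hits (BLAST `-outfmt 6`) are kept
   when E ≤ `e_max` and ranked per read by descending bit score (ties:
   ascending E-value, then subject id), truncated to `top_n`. Bit-score
   ranking is deliberate: bit scores are database-size independent, and
   the deterministic tie-break makes retained sets nested in `top_n`.
3. **Locus clustering.** A read's hits are clustered into candidate CDS
   loci by single linkage: hits merge when on the same read strand and
   overlapping by more than `max_overlap_fraction` (default 0.5) of the
   shorter interval. Opposite-strand hits never merge, because genuinely
   overlapping genes on opposite strands are two CDSs, not one.
4. **Consistent pairs.** Hits are grouped by the taxon of their subject
   genome. Within a taxon, each pair of hits from two *distinct* loci is
   tested: the subject genes must be adjacent, and the read-side
   arrangement must equal the reference arrangement under the read as-is
   or under its reverse complement — a shotgun read's orientation is
   arbitrary, so both global orientations are accepted, but mixed
   per-gene flips are not. Adjacent pairs failing the arrangement test
   are recorded and removed; non-adjacent pairs are ignored. Two hits on
   one locus are alternative identities of a single CDS and are never
   paired. Evidence is deduplicated per (taxon, gene pair).
5. **Assignment.** A read with at least `min_support` (default 1)
   supporting taxa is assigned to the LCA of those taxa; otherwise it is
   `unclassified`. This is the plain LCA with no minimum-support or
   top-percent heuristics beyond the `min_support` knob; the assignment
   is projected onto the seven canonical ranks, with `NA` where the
   lineage has no node at a rank.

### Assumptions

The method presumes (i) reads long enough to span two genes — it is a
Sanger/long-read method, pointless below ~700 nt; (ii) a reference set
containing relatives of the community members close enough to conserve
local gene order; (iii) hits annotated with a species-level taxon per
subject genome. Reads carrying fewer than two candidate loci are
structurally unclassifiable, which caps the achievable recovery.

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| `e_max` | 1e-5 | — | loose by design; the adjacency requirement supplies the stringency. The benchmark grid covers 1e-2/1e-4/1e-6 |
| `top_n` | 250 | hits/read | best-hit-only binning destroys the pair signal; 250 keeps enough co-hits. Grid covers 50–350 |
| `max_overlap_fraction` | 0.5 | fraction of shorter interval | merges split HSPs of one CDS while keeping genuinely distinct, slightly overlapping loci apart |
| `min_support` | 1 | taxa | any consistent pair suffices; raise for conservative calls |
| `arrangement` | `"full"` | — | order + strand equality (strictest reading of arrangement consistency); `"direction"` relaxes to direction-class equality only |

## Evaluation

Accuracy on truth-labeled reads is per class *i* at rank *r*:
`Sn_i = TP_i/(TP_i+FN_i+U_i)`, `Sp_i = TP_i/(TP_i+FP_i)`, where `U_i`
counts class-*i* reads left unclassified *or* assigned above the rank,
and `Sp_i` is undefined (`NA`, excluded from macro averages) when nothing
was predicted as *i*. Reads whose truth lineage lacks a node at the rank
are excluded, so `sum(TP+FN+U)` equals the number of truth reads with a
class at that rank — an invariant the tests assert. Macro averages are
unweighted over classes; micro averages pool counts and give the
dataset-level rates. Because an assignment correct at genus is correct at
phylum, pooled sensitivity is non-increasing from phylum toward genus.

Composition profiles count assigned reads per taxon at a rank. Before two
profiles are correlated, phylotypes with counts below 5 are pooled into a
shared `"other"` category; the default pools only taxa rare in *both*
profiles, since pooling a category abundant in one profile would discard
real signal (an `"either"` variant is available). The Pearson coefficient
is computed on the paired counts; it is affine-invariant, so proportions
give the same value.

### Reporting conventions

Per-sample recovery rates are **truncated** to one decimal
(`format_rate`): published per-sample rates follow that convention
(2050/7078 = 28.96 is reported as 28.9). Aggregate summaries (means, SDs)
**round half-up** (`round_half_up`). CDS-count distribution percentages
round half-up to one decimal. These two conventions are separate on
purpose; mixing them changes several values by 0.1.

## The simulator

`simulate_community()` generates the study conditions rather than
emulating an aligner:

- **Genomes.** One circular replicon per genome; gene lengths
  N(950, 150²) truncated at 90 nt, gaps N(50, 15²) truncated at 0 —
  the one-gene-per-kb density — and strand runs with flip probability
  0.25 per step, giving all three direction classes. Genomes of one
  genus share a single layout: gene order conservation between close
  relatives, which is exactly what makes homolog noise
  adjacency-preserving.
- **Taxonomy.** Species per genome, grouped by `lineage_branching`
  (default 2) per level up to a single superkingdom.
- **Reads.** `read_length` 1,000 nt, start positions uniform with
  modular wrap-around on circular replicons, strand uniform. Truth is
  the source species.
- **Hits.** True hits for every gene overlapped by ≥ `min_overlap` nt
  (E log-uniform on [1e-40, 1e-10]); homolog hits mirroring a read's
  true hits into each sister species with probability 0.5 (E on
  [1e-25, 1e-8]); spurious hits, Poisson mean 1 per read, to random
  genes rejected if identical or adjacent to a gene already hit (E on
  [1e-8, 1e-2]). Bit scores decrease with E plus noise. Reverse-strand
  hits use the `qstart > qend` convention.

Every output is a pure function of the `sim_config`, including its seed.

What the simulator does *not* emulate: alignment-level realism (HSP
splitting, frameshifts, compositional bias), assembly artefacts, uneven
species abundances, reference incompleteness (every read's species is in
the reference set), and detection failure of short overlaps — with the
default `min_overlap = 1` a 20 nt gene fragment still yields a hit, which
no translated search would find. Consequently the simulated fraction of
reads with ≥ 2 detected loci (~95%, the geometric value) is far above the
~49% seen for real discarded singletons, and simulated recovery (~91%) is
far above the published 13–31%: passing tests demonstrate correctness of
the machinery under conserved adjacency, not real-data recovery rates.
Raising `min_overlap` to ~230 nt reproduces the ~49% regime if a more
realistic two-CDS fraction is wanted.

## Numerical and design choices

- **Circular topology.** The (last, first) gene pair counts as adjacent
  on replicons declared circular with ≥ 3 genes; the wrap pair is stored
  in traversal order (last gene first). Default topology is linear unless
  declared — a convention, since annotation formats rarely state
  topology.
- **Sorting and ties.** Genes sort by start, then end, then gene id;
  loci order by interval start; evidence orders by (taxon, gene pair);
  assignments by read id. Every output is deterministic.
- **Degenerate inputs.** Empty files give empty catalogs/tables; a read
  whose hits are all filtered out, or that has one locus, is
  unclassified; `Sp` with an empty prediction class is `NA`; Pearson on
  < 2 categories or zero variance is `NA` with a warning, and profiles
  with different category sets are an error (pool first).
- **Unmapped subjects** in a hit table are dropped with a message, not an
  error: protein databases and annotation tables drift independently.
- **Both-orientation acceptance** is a deliberate interpretation of
  arrangement consistency: demanding the as-is orientation only would
  halve sensitivity for no specificity gain, since read orientation
  carries no information. The `arrangement = "direction"` flag exists
  because direction-class-only consistency is a defensible weaker
  reading; the default is the strict one.
- **Grouping key.** Adjacency lookup is keyed by (taxon, gene pair);
  gene ids must be unique within a genome. Plasmid-borne genes group
  with their host genome's taxon as annotated.

## Problem sizes used by the tests

The property suites run on deliberately small instances: oracle
equivalence against a brute-force enumerator on 1,000 random catalogs of
1–3 genomes × 4–8 genes with ≤ 12 hits; communities of 8 genomes × 30–40
genes with 60–400 reads for determinism, noise-free recovery and the
12-cell benchmark grid; these sizes give exhaustive coverage of the
combinatorics (wrap pairs, paralogs, multi-locus reads) while keeping the
full suite around two minutes.

## Known limitations

- Adjacency evidence requires the reference relative to conserve the
  *specific* gene pair; rearranged neighbourhoods make reads
  unclassifiable even when single-hit methods would (riskily) assign
  them.
- A single consistent pair from one taxon assigns at species level with
  `min_support = 1`; in sparse reference regions this can be
  overconfident — raise `min_support` or inspect `n_supporting_taxa`.
- The hit-pair test is per pair; no synteny chains across ≥ 3 loci are
  required (any consistent pair suffices), matching the two-or-more-CDS
  rationale but leaving longer-range order information unused.
- Composition profiles count reads, not genome equivalents; length or
  copy-number normalisation is out of scope.
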