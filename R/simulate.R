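#' Configuration for the synthetic-community simulator
#'
#' Defaults emulate the setting the method targets: prokaryotic gene
#' density of about one gene per 1,000 nt (950 nt genes, 50 nt intergenic
#' gaps) and ~1 kb Sanger-style reads, so roughly half of the simulated
#' reads overlap two or more genes. Genomes of one genus share their gene
#' layout (gene order conservation between close relatives), which is what
#' makes sister-taxon homolog hits adjacency-preserving.
#'
#' @param n_genomes number of genomes (= species) in the community.
#' @param genes_per_genome genes per replicon.
#' @param gene_len_mean,gene_len_sd gene length distribution, nt (normal,
#'   truncated at 90 nt; `sd = 0` gives constant lengths).
#' @param gap_mean,gap_sd intergenic gap distribution, nt (truncated at 0).
#' @param strand_flip_prob probability that a gene flips strand relative to
#'   its predecessor (operon-like strand runs).
#' @param topology `"circular"` (default; prokaryotic chromosomes) or
#'   `"linear"`.
#' @param read_length read length, nt.
#' @param n_reads number of reads sampled uniformly over the community.
#' @param lineage_branching children per internal taxonomy node (species
#'   per genus, genera per family, ...).
#' @param homolog_prob probability, per read and per sister species, that
#'   the read's true hits are mirrored into that sister (homologs with
#'   conserved adjacency).
#' @param spurious_rate mean number (Poisson) of spurious hits per read, to
#'   random genes not adjacent to any gene already hit by the read.
#' @param true_e_range,homolog_e_range,spurious_e_range E-value ranges; all
#'   E-values are sampled log-uniformly within their range.
#' @param min_overlap minimum read/gene overlap (nt) for a gene to count as
#'   carried by a read and to yield a true hit.
#' @param seed integer seed; every simulator output is a pure function of
#'   the configuration including this seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_genomes = 8L, genes_per_genome = 40L,
                       gene_len_mean = 950, gene_len_sd = 150,
                       gap_mean = 50, gap_sd = 15,
                       strand_flip_prob = 0.25,
                       topology = c("circular", "linear"),
                       read_length = 1000L, n_reads = 400L,
                       lineage_branching = 2L,
                       homolog_prob = 0.5, spurious_rate = 1,
                       true_e_range = c(1e-40, 1e-10),
                       homolog_e_range = c(1e-25, 1e-8),
                       spurious_e_range = c(1e-8, 1e-2),
                       min_overlap = 1L, seed = 42L) {
  topology <- match.arg(topology)
  cfg <- list(n_genomes = as.integer(n_genomes),
              genes_per_genome = as.integer(genes_per_genome),
              gene_len_mean = gene_len_mean, gene_len_sd = gene_len_sd,
              gap_mean = gap_mean, gap_sd = gap_sd,
              strand_flip_prob = strand_flip_prob, topology = topology,
              read_length = as.integer(read_length),
              n_reads = as.integer(n_reads),
              lineage_branching = as.integer(lineage_branching),
              homolog_prob = homolog_prob, spurious_rate = spurious_rate,
              true_e_range = true_e_range,
              homolog_e_range = homolog_e_range,
              spurious_e_range = spurious_e_range,
              min_overlap = as.integer(min_overlap),
              seed = as.integer(seed))
  stopifnot(cfg$n_genomes >= 1L, cfg$genes_per_genome >= 1L,
            cfg$gene_len_mean > 0, cfg$read_length > 0,
            cfg$homolog_prob >= 0, cfg$homolog_prob <= 1,
            cfg$strand_flip_prob >= 0, cfg$strand_flip_prob <= 1,
            cfg$spurious_rate >= 0)
  class(cfg) <- "sim_config"
  cfg
}

# taxonomy over the genomes: species -> genus -> family -> order -> class
# -> phylum -> superkingdom -> root, grouping `b` children per parent
.sim_taxonomy <- function(n_species, b) {
  level_names <- c("species", "genus", "family", "order", "class", "phylum")
  sizes <- integer(6)
  sizes[1] <- n_species
  for (i in 2:6) sizes[i] <- max(1L, ceiling(sizes[i - 1] / b))
  ids <- vector("list", 6)
  next_id <- 3L  # 1 = root, 2 = superkingdom
  for (i in 6:1) { # phylum first so that higher ranks get smaller ids
    ids[[i]] <- seq.int(next_id, length.out = sizes[i])
    next_id <- next_id + sizes[i]
  }
  nodes <- data.frame(taxon_id = 1:2, parent_id = c(NA_integer_, 1L),
                      rank = c("no rank", "superkingdom"),
                      name = c("root", "Bacteria"),
                      stringsAsFactors = FALSE)
  for (i in 6:1) {
    parent_ids <- if (i == 6) rep(2L, sizes[i])
                  else ids[[i + 1]][ceiling(seq_len(sizes[i]) / b)]
    nodes <- rbind(nodes, data.frame(
      taxon_id = ids[[i]], parent_id = parent_ids,
      rank = level_names[i],
      name = paste0(level_names[i], "_", seq_len(sizes[i])),
      stringsAsFactors = FALSE))
  }
  list(tree = taxonomy_tree(nodes), species_ids = ids[[1]],
       genus_of = ids[[2]][ceiling(seq_len(n_species) /
                                   max(1L, b))])
}

.trunc_norm <- function(n, mean, sd, lower) {
  if (sd <= 0) return(rep(round(mean), n))
  pmax(lower, round(rnorm(n, mean, sd)))
}

# one gene layout shared by all genomes of a genus
.sim_layout <- function(cfg) {
  n <- cfg$genes_per_genome
  len <- .trunc_norm(n, cfg$gene_len_mean, cfg$gene_len_sd, 90)
  gap <- .trunc_norm(n, cfg$gap_mean, cfg$gap_sd, 0)
  strand <- character(n)
  strand[1] <- "+"
  if (n > 1) {
    flip <- runif(n - 1) < cfg$strand_flip_prob
    for (i in 2:n) strand[i] <- if (flip[i - 1]) .flip_strand(strand[i - 1])
                                else strand[i - 1]
  }
  start <- cumsum(c(1, (len + gap)[-n]))
  end <- start + len - 1
  replicon_length <- end[n] + gap[n]
  list(start = as.integer(start), end = as.integer(end), strand = strand,
       replicon_length = as.integer(replicon_length))
}

.sample_evalue <- function(n, range) {
  10^runif(n, log10(range[1]), log10(range[2]))
}

#' Simulate a synthetic community with reads and truth labels
#'
#' Generates, deterministically for a fixed seed: a small taxonomy over
#' `n_genomes` species; one replicon per genome laid out gene by gene with
#' sampled lengths, intergenic gaps and strand runs (genomes of a genus
#' share one layout); `n_reads` reads sampled uniformly over replicon
#' positions and strands (with modular wrap-around on circular replicons);
#' the genes each read overlaps, in read coordinates; a truth map read ->
#' source species; and a noisy hit table (see [simulate_hit_table]).
#'
#' @param config a [sim_config].
#' @return A list of class `sim_community` with elements `catalog`,
#'   `index`, `tree`, `reads`, `overlaps`, `hits`, `gene_map`, `truth`,
#'   `config`.
#' @export
simulate_community <- function(config = sim_config()) {
  cfg <- config
  com <- withr::with_seed(cfg$seed, {
    tax <- .sim_taxonomy(cfg$n_genomes, cfg$lineage_branching)
    layouts <- lapply(unique(tax$genus_of), function(g) .sim_layout(cfg))
    names(layouts) <- as.character(unique(tax$genus_of))

    genes <- do.call(rbind, lapply(seq_len(cfg$n_genomes), function(k) {
      ly <- layouts[[as.character(tax$genus_of[k])]]
      data.frame(genome_id = paste0("G", k),
                 replicon_id = paste0("G", k, "_chr"),
                 taxon_id = tax$species_ids[k],
                 gene_id = paste0("G", k, "_g",
                                  seq_len(cfg$genes_per_genome)),
                 start = ly$start, end = ly$end, strand = ly$strand,
                 stringsAsFactors = FALSE)
    }))
    rep_len <- vapply(seq_len(cfg$n_genomes), function(k)
      layouts[[as.character(tax$genus_of[k])]]$replicon_length, integer(1))
    if (any(rep_len < cfg$read_length) && cfg$topology == "linear")
      stop("infeasible geometry: read longer than a linear replicon",
           call. = FALSE)
    if (any(vapply(layouts, function(ly)
          max(ly$end - ly$start + 1L), integer(1)) > min(rep_len)))
      stop("infeasible geometry: gene longer than its replicon",
           call. = FALSE)
    replicons <- data.frame(replicon_id = paste0("G",
                              seq_len(cfg$n_genomes), "_chr"),
                            length = rep_len, topology = cfg$topology,
                            stringsAsFactors = FALSE)
    catalog <- gene_catalog(genes, replicons)
    index <- build_adjacency_index(catalog)

    # reads: uniform over genomes, positions and strands
    reads <- if (cfg$n_reads > 0L) {
      src <- sample.int(cfg$n_genomes, cfg$n_reads, replace = TRUE)
      L <- cfg$read_length
      start <- vapply(src, function(k) {
        if (cfg$topology == "circular") sample.int(rep_len[k], 1L)
        else sample.int(rep_len[k] - L + 1L, 1L)
      }, integer(1))
      data.frame(read_id = sprintf("read_%05d", seq_len(cfg$n_reads)),
                 genome_id = paste0("G", src),
                 replicon_id = paste0("G", src, "_chr"),
                 start = start, end = start + L - 1L,
                 strand = sample(c("+", "-"), cfg$n_reads, replace = TRUE),
                 truth_taxon = tax$species_ids[src],
                 stringsAsFactors = FALSE)
    } else {
      data.frame(read_id = character(0), genome_id = character(0),
                 replicon_id = character(0), start = integer(0),
                 end = integer(0), strand = character(0),
                 truth_taxon = integer(0), stringsAsFactors = FALSE)
    }
    overlaps <- .read_gene_overlaps(reads, catalog, cfg)
    reads$n_genes <- as.integer(table(factor(overlaps$read_id,
                                             levels = reads$read_id)))
    list(catalog = catalog, index = index, tree = tax$tree, reads = reads,
         overlaps = overlaps,
         truth = setNames(reads$truth_taxon, reads$read_id),
         config = cfg)
  })
  class(com) <- "sim_community"
  com$gene_map <- data.frame(subject_id = com$catalog$genes$gene_id,
                             gene_id = com$catalog$genes$gene_id,
                             taxon_id = com$catalog$genes$taxon_id,
                             stringsAsFactors = FALSE)
  com$hits <- simulate_hit_table(com, cfg)
  com
}

# genes overlapped by each read, with read-coordinate intervals and the
# strand each gene presents on the read (wrap-aware on circular replicons)
.read_gene_overlaps <- function(reads, catalog, cfg) {
  g <- catalog$genes
  rep_len <- setNames(catalog$replicons$length, catalog$replicons$replicon_id)
  circ <- setNames(catalog$replicons$topology == "circular",
                   catalog$replicons$replicon_id)
  out <- vector("list", nrow(reads))
  for (i in seq_len(nrow(reads))) {
    rd <- reads[i, ]
    gg <- g[g$replicon_id == rd$replicon_id, , drop = FALSE]
    Lr <- rep_len[[rd$replicon_id]]
    shifts <- if (circ[[rd$replicon_id]]) c(0L, Lr) else 0L
    acc <- NULL
    for (sh in shifts) {
      s <- gg$start + sh; e <- gg$end + sh
      olo <- pmax(s, rd$start); ohi <- pmin(e, rd$end)
      hit <- which(ohi - olo + 1L >= cfg$min_overlap)
      if (length(hit) == 0L) next
      if (rd$strand == "+") {
        r_lo <- olo[hit] - rd$start + 1L
        r_hi <- ohi[hit] - rd$start + 1L
        s_on_read <- gg$strand[hit]
      } else {
        r_lo <- rd$end - ohi[hit] + 1L
        r_hi <- rd$end - olo[hit] + 1L
        s_on_read <- .flip_strand(gg$strand[hit])
      }
      acc <- rbind(acc, data.frame(
        read_id = rd$read_id, genome_id = rd$genome_id,
        gene_id = gg$gene_id[hit], gene_index = gg$order_rank[hit],
        r_lo = r_lo, r_hi = r_hi, strand_on_read = s_on_read,
        overlap_len = ohi[hit] - olo[hit] + 1L,
        stringsAsFactors = FALSE))
    }
    out[[i]] <- acc
  }
  res <- do.call(rbind, c(out, list(data.frame(
    read_id = character(0), genome_id = character(0),
    gene_id = character(0), gene_index = integer(0), r_lo = integer(0),
    r_hi = integer(0), strand_on_read = character(0),
    overlap_len = integer(0), stringsAsFactors = FALSE))))
  rownames(res) <- NULL
  res
}

.mk_hits <- function(read_id, gene_id, taxon_id, r_lo, r_hi, strand, e_range,
                     bit_base) {
  n <- length(gene_id)
  if (n == 0L) return(NULL)
  ev <- .sample_evalue(n, e_range)
  pid <- round(runif(n, 75, 99.5), 1)
  alen <- pmax(1L, as.integer((r_hi - r_lo + 1L) %/% 3L))
  data.frame(query_id = read_id, subject_id = gene_id,
             pident = pid, align_len = alen,
             mismatch = as.integer(round(alen * (1 - pid / 100))),
             gapopen = 0L,
             q_start = ifelse(strand == "+", r_lo, r_hi),
             q_end = ifelse(strand == "+", r_hi, r_lo),
             s_start = 1L, s_end = alen,
             evalue = ev,
             bit_score = round(bit_base - 1.5 * log10(ev) +
                               rnorm(n, 0, 3), 1),
             strand = strand, q_lo = r_lo, q_hi = r_hi,
             gene_id = gene_id, taxon_id = taxon_id,
             stringsAsFactors = FALSE)
}

#' Simulate a noisy homology hit table for a community
#'
#' Stands in for a translated homology search: for every read, *true* hits
#' to each gene it overlaps (low E-values); *homolog* hits mirroring the
#' read's true hits into sister species of the same genus with probability
#' `homolog_prob` per sister (sister genomes share the gene layout, so
#' homolog hits preserve adjacency and arrangement); and *spurious* hits
#' (Poisson, mean `spurious_rate` per read) to random genes chosen not to
#' be identical or adjacent to any gene already hit by the read. Query
#' coordinates follow the BLAST convention: a hit on the read's reverse
#' strand has `q_start > q_end`.
#'
#' @param community a `sim_community` (its `reads` and `overlaps` are
#'   used; its stored `hits` are ignored).
#' @param config a [sim_config]; `config$seed` makes the table
#'   deterministic.
#' @return A `hit_table` in the same form as [read_blast_tabular] output.
#' @export
simulate_hit_table <- function(community, config = community$config) {
  cfg <- config
  withr::with_seed(cfg$seed + 1L, {
    ov <- community$overlaps
    reads <- community$reads
    cat_genes <- community$catalog$genes
    species_of_genome <- community$catalog$genome_taxon
    lk <- .adjacency_lookup(community$index)

    # genus siblings: genomes whose species share a genus
    genus_of <- setNames(
      project_to_rank(community$tree, species_of_genome, "genus"),
      names(species_of_genome))

    parts <- split(seq_len(nrow(ov)), ov$read_id)
    all_rows <- vector("list", nrow(reads))
    for (i in seq_len(nrow(reads))) {
      rd <- reads[i, ]
      idx <- parts[[rd$read_id]]
      o <- if (is.null(idx)) ov[0, ] else ov[idx, , drop = FALSE]
      rows <- list()
      if (nrow(o) > 0L) {
        rows[[length(rows) + 1L]] <- .mk_hits(
          rd$read_id, o$gene_id, species_of_genome[[rd$genome_id]],
          o$r_lo, o$r_hi, o$strand_on_read, cfg$true_e_range, 60)
        sisters <- names(species_of_genome)[
          genus_of == genus_of[[rd$genome_id]] &
          names(species_of_genome) != rd$genome_id]
        for (sg in sisters) {
          if (runif(1) >= cfg$homolog_prob) next
          sister_gene <- paste0(sg, "_g", o$gene_index + 1L)
          rows[[length(rows) + 1L]] <- .mk_hits(
            rd$read_id, sister_gene, species_of_genome[[sg]],
            o$r_lo, o$r_hi, o$strand_on_read, cfg$homolog_e_range, 45)
        }
      }
      n_spur <- rpois(1L, cfg$spurious_rate)
      if (n_spur > 0L) {
        hit_genes <- unlist(lapply(rows, `[[`, "gene_id"))
        for (s in seq_len(n_spur)) {
          pick <- NULL
          for (try in 1:20) {
            j <- sample.int(nrow(cat_genes), 1L)
            cand <- cat_genes$gene_id[j]
            if (cand %in% hit_genes) next
            tx <- cat_genes$taxon_id[j]
            adj <- any(vapply(hit_genes, function(h)
              !is.null(get0(paste(tx, cand, h, sep = "\r"), envir = lk)),
              logical(1)))
            if (!adj) { pick <- j; break }
          }
          if (is.null(pick)) next
          qlen <- min(sample(150:500, 1L), cfg$read_length)
          qlo <- sample.int(cfg$read_length - qlen + 1L, 1L)
          rows[[length(rows) + 1L]] <- .mk_hits(
            rd$read_id, cat_genes$gene_id[pick], cat_genes$taxon_id[pick],
            qlo, qlo + qlen - 1L, sample(c("+", "-"), 1L),
            cfg$spurious_e_range, 25)
          hit_genes <- c(hit_genes, cat_genes$gene_id[pick])
        }
      }
      all_rows[[i]] <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
    }
    out <- do.call(rbind, c(all_rows, list(.mk_hits(
      character(0), character(0), integer(0), integer(0), integer(0),
      character(0), c(1e-10, 1e-5), 0))))
    if (is.null(out)) out <- .mk_hits("x", "g", 1L, 1L, 3L, "+",
                                      c(1e-10, 1e-5), 0)[0, ]
    rownames(out) <- NULL
    .as_hit_table(out)
  })
}

#' @export
print.sim_community <- function(x, ...) {
  cat("<sim_community> ", nrow(x$reads), " read(s) from ",
      x$config$n_genomes, " genome(s); ", nrow(x$hits), " hit(s); ",
      sum(x$reads$n_genes >= 2), " read(s) overlap >= 2 genes\n", sep = "")
  invisible(x)
}

#' Benchmark the binner over a criteria grid
#'
#' Runs [bin_dataset] at every (E-value cut-off, hit-number cap)
#' combination of the grid — the default grid is 3 E-values times 4 hit
#' numbers, twelve combinations — for the adjacency method and, for
#' comparison, the plain-LCA mode that ignores adjacency, and evaluates
#' per-class sensitivity and specificity at the requested ranks against
#' the community's truth labels.
#'
#' @param community a `sim_community`.
#' @param e_values E-value cut-offs.
#' @param top_ns per-read hit caps.
#' @param ranks ranks at which accuracy is evaluated.
#' @param methods `"adjacency"`, `"lca"` or both.
#' @param min_support passed to [bin_dataset].
#' @return data.frame of class `benchmark_result`: one row per (method,
#'   e_max, top_n, rank) with macro/micro `Sn` and `Sp` (as percentages),
#'   the number of assigned reads and the recovery rate.
#' @export
run_benchmark <- function(community,
                          e_values = c(1e-2, 1e-4, 1e-6),
                          top_ns = c(50L, 150L, 250L, 350L),
                          ranks = c("phylum", "order", "family", "genus"),
                          methods = c("adjacency", "lca"),
                          min_support = 1L) {
  grid <- expand.grid(e_max = e_values, top_n = top_ns,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- list()
  for (meth in methods) {
    for (k in seq_len(nrow(grid))) {
      res <- bin_dataset(community$hits, community$index, community$tree,
                         e_max = grid$e_max[k], top_n = grid$top_n[k],
                         min_support = min_support, method = meth)
      n_assigned <- sum(res$status == "assigned")
      for (r in ranks) {
        cc <- accuracy_table(confusion_counts(res, community$truth,
                                              community$tree, r))
        sm <- attr(cc, "summary")
        rows[[length(rows) + 1L]] <- data.frame(
          method = meth, e_max = grid$e_max[k], top_n = grid$top_n[k],
          rank = r,
          macro_sn = 100 * sm$macro_sn, macro_sp = 100 * sm$macro_sp,
          micro_sn = 100 * sm$micro_sn, micro_sp = 100 * sm$micro_sp,
          n_assigned = n_assigned,
          recovery = recovery_rate(n_assigned, nrow(res)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("benchmark_result", "data.frame")
  out
}

#' Write a simulated community to plain-text files
#'
#' Writes `annotations.tsv` (gene table with topology), `taxonomy.tsv`,
#' `hits.tab` (12-column BLAST tabular), `gene_map.tsv`, `truth.tsv` and
#' `reads.fasta` (placeholder sequences; the pipeline never reads bases) so
#' that the files can be fed back through the readers and the command-line
#' interface.
#'
#' @param community a `sim_community`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_community <- function(community, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  g <- community$catalog$genes
  topo <- setNames(community$catalog$replicons$topology,
                   community$catalog$replicons$replicon_id)
  ann <- g[, c("genome_id", "replicon_id", "taxon_id", "gene_id",
               "start", "end", "strand")]
  ann$topology <- unname(topo[ann$replicon_id])
  write.table(ann, file.path(dir, "annotations.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  tr <- community$tree
  write.table(data.frame(taxon_id = tr$id,
                         parent_id = unname(tr$parent[as.character(tr$id)]),
                         rank = unname(tr$rank[as.character(tr$id)]),
                         name = unname(tr$name[as.character(tr$id)])),
              file.path(dir, "taxonomy.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  h <- as.data.frame(community$hits)[, .HIT_COLS]
  write.table(h, file.path(dir, "hits.tab"), sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  write.table(community$gene_map, file.path(dir, "gene_map.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(data.frame(read_id = names(community$truth),
                         taxon_id = unname(community$truth)),
              file.path(dir, "truth.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  fa <- file(file.path(dir, "reads.fasta"), "w")
  for (i in seq_len(nrow(community$reads)))
    writeLines(c(paste0(">", community$reads$read_id[i]),
                 strrep("N", community$config$read_length)), fa)
  close(fa)
  invisible(dir)
}
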