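#' @importFrom stats ave cor rnorm runif rpois sd setNames
#' @importFrom utils head read.delim write.table
NULL

# Strands are stored as "+"/"-" (the GFF convention); "forward"/"reverse"
# are accepted on input.
.normalize_strand <- function(x) {
  out <- ifelse(x %in% c("+", "forward", "f", "F", "1"), "+",
         ifelse(x %in% c("-", "reverse", "r", "R", "-1"), "-", NA_character_))
  if (anyNA(out)) {
    bad <- unique(x[is.na(out)])
    stop("invalid strand value(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  out
}

.flip_strand <- function(x) ifelse(x == "+", "-", "+")

#' Construct a gene catalog from a gene table
#'
#' A gene catalog holds the reference gene arrangement: one row per gene with
#' its replicon, 1-based inclusive coordinates, strand and the species-level
#' taxon of its genome. Genes are sorted along each replicon and given a
#' 0-based `order_rank`; adjacency ("directly next to each other") is defined
#' on consecutive order ranks, so intervening annotated genes break adjacency
#' even when genes physically overlap.
#'
#' @param genes data.frame with columns `genome_id`, `replicon_id`,
#'   `taxon_id`, `gene_id`, `start`, `end`, `strand`. Coordinates are 1-based
#'   inclusive; strand is `+`/`-` (or `forward`/`reverse`).
#' @param replicons optional data.frame with columns `replicon_id`,
#'   `topology` (`linear` or `circular`) and optionally `length`. Replicons
#'   absent from this table default to linear, with length equal to the
#'   maximum gene end.
#' @return An object of class `gene_catalog`: a list with elements `genes`
#'   (the validated table with an added `order_rank` column), `replicons`,
#'   and `genome_taxon` (named vector genome_id -> taxon_id).
#' @export
gene_catalog <- function(genes, replicons = NULL) {
  required <- c("genome_id", "replicon_id", "taxon_id", "gene_id",
                "start", "end", "strand")
  missing_cols <- setdiff(required, names(genes))
  if (length(missing_cols) > 0L)
    stop("gene table lacks mandatory field(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  genes <- as.data.frame(genes)[, required]
  if (nrow(genes) == 0L) {
    genes$order_rank <- integer(0)
    out <- list(genes = genes,
                replicons = data.frame(replicon_id = character(0),
                                       genome_id = character(0),
                                       length = integer(0),
                                       topology = character(0)),
                genome_taxon = integer(0))
    class(out) <- "gene_catalog"
    return(out)
  }
  genes$genome_id <- as.character(genes$genome_id)
  genes$replicon_id <- as.character(genes$replicon_id)
  genes$gene_id <- as.character(genes$gene_id)
  genes$taxon_id <- as.integer(genes$taxon_id)
  genes$start <- as.integer(genes$start)
  genes$end <- as.integer(genes$end)
  genes$strand <- .normalize_strand(as.character(genes$strand))

  bad <- which(genes$start > genes$end)
  if (length(bad) > 0L)
    stop("gene record with start > end: gene_id ",
         genes$gene_id[bad[1L]], call. = FALSE)
  dup <- duplicated(genes[, c("genome_id", "gene_id")])
  if (any(dup))
    stop("duplicate gene_id within genome: ",
         genes$gene_id[which(dup)[1L]], " in ",
         genes$genome_id[which(dup)[1L]], call. = FALSE)
  g2t <- unique(genes[, c("genome_id", "taxon_id")])
  if (anyDuplicated(g2t$genome_id))
    stop("genome mapped to more than one taxon_id: ",
         g2t$genome_id[anyDuplicated(g2t$genome_id)], call. = FALSE)

  # order_rank: ascending start, ties by ascending end then gene_id
  o <- order(genes$genome_id, genes$replicon_id,
             genes$start, genes$end, genes$gene_id)
  genes <- genes[o, , drop = FALSE]
  key <- paste(genes$genome_id, genes$replicon_id, sep = "\r")
  genes$order_rank <- stats::ave(seq_len(nrow(genes)), key,
                                 FUN = function(i) seq_along(i) - 1L)
  rownames(genes) <- NULL

  rep_tab <- unique(genes[, c("genome_id", "replicon_id")])
  max_end <- tapply(genes$end,
                    paste(genes$genome_id, genes$replicon_id, sep = "\r"),
                    max)
  rep_tab$length <- as.integer(
    max_end[paste(rep_tab$genome_id, rep_tab$replicon_id, sep = "\r")])
  rep_tab$topology <- "linear"
  if (!is.null(replicons)) {
    replicons <- as.data.frame(replicons)
    m <- match(rep_tab$replicon_id, replicons$replicon_id)
    if ("topology" %in% names(replicons)) {
      topo <- replicons$topology[m]
      rep_tab$topology <- ifelse(is.na(topo), "linear", as.character(topo))
    }
    if ("length" %in% names(replicons)) {
      len <- suppressWarnings(as.integer(replicons$length[m]))
      rep_tab$length <- ifelse(is.na(len), rep_tab$length, len)
    }
    if (!all(rep_tab$topology %in% c("linear", "circular")))
      stop("replicon topology must be 'linear' or 'circular'", call. = FALSE)
    if (any(rep_tab$length < max_end[paste(rep_tab$genome_id,
                                           rep_tab$replicon_id, sep = "\r")]))
      stop("declared replicon length shorter than a gene end", call. = FALSE)
  }
  rownames(rep_tab) <- NULL

  out <- list(genes = genes,
              replicons = rep_tab,
              genome_taxon = setNames(g2t$taxon_id, g2t$genome_id))
  class(out) <- "gene_catalog"
  out
}

#' @export
print.gene_catalog <- function(x, ...) {
  cat("<gene_catalog> ", nrow(x$genes), " genes on ",
      nrow(x$replicons), " replicon(s), ",
      length(x$genome_taxon), " genome(s), ",
      length(unique(x$genome_taxon)), " taxa\n", sep = "")
  invisible(x)
}

#' Read reference gene annotations
#'
#' Loads reference gene annotations from either a tab-separated table or a
#' GFF3 file and builds a [gene_catalog]. The TSV dialect has a header line
#' and columns `genome_id`, `replicon_id`, `taxon_id`, `gene_id`, `start`,
#' `end`, `strand`, and optionally `topology` (per-replicon, `linear` or
#' `circular`); `#` comment lines are ignored. For GFF3 the `seqid` column
#' is used as the replicon id and the `ID` attribute as the gene id; since
#' GFF3 carries neither genome nor taxon identifiers these are supplied as
#' arguments (one genome per file).
#'
#' @param path path to the annotation file.
#' @param format `"tsv"` or `"gff3"`.
#' @param genome_id,taxon_id genome identifier and species-level taxon for
#'   GFF3 input (ignored for TSV, which carries its own columns).
#' @param feature_type GFF3 feature type to keep (`"CDS"` or `"gene"`).
#' @param topology topology applied to all replicons of a GFF3 file.
#' @return A [gene_catalog].
#' @export
read_gene_annotations <- function(path, format = c("tsv", "gff3"),
                                  genome_id = "genome1", taxon_id = 1L,
                                  feature_type = c("CDS", "gene"),
                                  topology = "linear") {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path, call. = FALSE)
  if (format == "tsv") {
    tab <- read.delim(path, header = TRUE, sep = "\t", comment.char = "#",
                      stringsAsFactors = FALSE)
    if (nrow(tab) == 0L) return(gene_catalog(tab[, intersect(names(tab),
        c("genome_id", "replicon_id", "taxon_id", "gene_id",
          "start", "end", "strand")), drop = FALSE]))
    reps <- NULL
    if ("topology" %in% names(tab))
      reps <- unique(tab[, c("replicon_id", "topology")])
    return(gene_catalog(tab, replicons = reps))
  }
  # GFF3 via rtracklayer
  if (!requireNamespace("rtracklayer", quietly = TRUE))
    stop("reading GFF3 requires the rtracklayer package", call. = FALSE)
  feature_type <- match.arg(feature_type)
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- as.character(gr$ID)
  if (anyNA(ids)) stop("GFF3 record without an ID attribute", call. = FALSE)
  genes <- data.frame(
    genome_id = genome_id,
    replicon_id = as.character(GenomicRanges::seqnames(gr)),
    taxon_id = as.integer(taxon_id),
    gene_id = ids,
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    stringsAsFactors = FALSE)
  genes$strand[genes$strand == "*"] <- "+"
  reps <- data.frame(replicon_id = unique(genes$replicon_id),
                     topology = topology)
  gene_catalog(genes, replicons = reps)
}

#' Transcriptional direction class of an adjacent gene pair
#'
#' Adjacent prokaryotic gene pairs fall in three transcriptional direction
#' classes depending on the strands of the two genes taken in genomic order:
#' unidirectional (`-> ->` or its mirror `<- <-`), convergent (`-> <-`) and
#' divergent (`<- ->`).
#'
#' @param first,second strands (`+`/`-`, or `forward`/`reverse`) of the two
#'   genes, with `first` the gene that comes earlier in genomic order;
#'   vectorized. Alternatively one-row data.frames with `strand` (and
#'   optionally `gene_id`) columns.
#' @return character vector in `c("unidirectional", "convergent",
#'   "divergent")`.
#' @export
direction_class <- function(first, second) {
  if (is.data.frame(first) || is.list(first)) {
    if (!is.null(first$gene_id) && !is.null(second$gene_id) &&
        identical(first$gene_id, second$gene_id))
      stop("direction_class: the same gene was passed twice", call. = FALSE)
    first <- first$strand
    second <- second$strand
  }
  a <- .normalize_strand(first)
  b <- .normalize_strand(second)
  ifelse(a == b, "unidirectional",
         ifelse(a == "+", "convergent", "divergent"))
}

#' Build the gene-adjacency index
#'
#' Two genes are adjacent when they occupy consecutive order ranks on the
#' same replicon; on a circular replicon with at least three genes the
#' (last, first) pair is additionally adjacent. Each pair is recorded in its
#' genomic-order orientation (`gene_lo` before `gene_hi` in the local
#' traversal) together with its transcriptional [direction_class]. Pairs
#' never span replicons, so plasmid and chromosome genes of one genome are
#' never adjacent.
#'
#' @param catalog a [gene_catalog].
#' @return An object of class `adjacency_index`: a data.frame with columns
#'   `genome_id`, `replicon_id`, `taxon_id`, `gene_lo`, `gene_hi`,
#'   `strand_lo`, `strand_hi`, `direction`, `wrap`.
#' @export
build_adjacency_index <- function(catalog) {
  stopifnot(inherits(catalog, "gene_catalog"))
  g <- catalog$genes
  empty <- data.frame(genome_id = character(0), replicon_id = character(0),
                      taxon_id = integer(0), gene_lo = character(0),
                      gene_hi = character(0), strand_lo = character(0),
                      strand_hi = character(0), direction = character(0),
                      wrap = logical(0), stringsAsFactors = FALSE)
  if (nrow(g) == 0L) {
    class(empty) <- c("adjacency_index", "data.frame")
    return(empty)
  }
  topo <- setNames(catalog$replicons$topology,
                   paste(catalog$replicons$genome_id,
                         catalog$replicons$replicon_id, sep = "\r"))
  key <- paste(g$genome_id, g$replicon_id, sep = "\r")
  parts <- split(seq_len(nrow(g)), key)
  rows <- lapply(names(parts), function(k) {
    idx <- parts[[k]][order(g$order_rank[parts[[k]]])]
    n <- length(idx)
    if (n < 2L) return(NULL)
    lo <- idx[-n]; hi <- idx[-1L]; wrap <- rep(FALSE, n - 1L)
    if (identical(unname(topo[k]), "circular") && n >= 3L) {
      lo <- c(lo, idx[n]); hi <- c(hi, idx[1L]); wrap <- c(wrap, TRUE)
    }
    data.frame(genome_id = g$genome_id[lo],
               replicon_id = g$replicon_id[lo],
               taxon_id = g$taxon_id[lo],
               gene_lo = g$gene_id[lo], gene_hi = g$gene_id[hi],
               strand_lo = g$strand[lo], strand_hi = g$strand[hi],
               direction = direction_class(g$strand[lo], g$strand[hi]),
               wrap = wrap, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(empty)))
  rownames(out) <- NULL
  class(out) <- c("adjacency_index", "data.frame")
  out
}

# Fast lookup environment: "<taxon>\r<geneA>\r<geneB>" -> row index, both
# orientations of each pair. Built once per index and cached in an attribute.
.adjacency_lookup <- function(index) {
  lk <- attr(index, ".lookup", exact = TRUE)
  if (!is.null(lk)) return(lk)
  lk <- new.env(parent = emptyenv(), size = max(2L * nrow(index), 16L))
  if (nrow(index) > 0L) {
    k1 <- paste(index$taxon_id, index$gene_lo, index$gene_hi, sep = "\r")
    k2 <- paste(index$taxon_id, index$gene_hi, index$gene_lo, sep = "\r")
    for (i in seq_len(nrow(index))) {
      assign(k1[i], i, envir = lk)
      assign(k2[i], i, envir = lk)
    }
  }
  lk
}

#' Test adjacency of two genes within a taxon
#'
#' @param index an [build_adjacency_index] result.
#' @param taxon_id taxon of the genome carrying both genes.
#' @param gene_a,gene_b gene identifiers (order irrelevant).
#' @return The matching index row (one-row data.frame) or `NULL` when the
#'   two genes are not directly adjacent.
#' @export
adjacency_pair <- function(index, taxon_id, gene_a, gene_b) {
  lk <- .adjacency_lookup(index)
  i <- get0(paste(taxon_id, gene_a, gene_b, sep = "\r"), envir = lk)
  if (is.null(i)) NULL else index[i, , drop = FALSE]
}
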