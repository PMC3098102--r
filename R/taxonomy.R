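.RANKS <- c("superkingdom", "phylum", "class", "order", "family",
            "genus", "species")

#' Construct a taxonomy tree
#'
#' @param nodes data.frame with columns `taxon_id`, `parent_id`, `rank`
#'   and optionally `name`. The root is the single node whose parent is
#'   itself or `NA`. Rank labels are the seven canonical ranks
#'   (superkingdom, phylum, class, order, family, genus, species) plus
#'   `"no rank"`.
#' @return An object of class `taxonomy_tree`.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- as.data.frame(nodes)
  required <- c("taxon_id", "parent_id", "rank")
  if (!all(required %in% names(nodes)))
    stop("taxonomy table needs columns taxon_id, parent_id, rank",
         call. = FALSE)
  if (nrow(nodes) == 0L) stop("empty taxonomy: no root node", call. = FALSE)
  id <- as.integer(nodes$taxon_id)
  parent <- as.integer(nodes$parent_id)
  rank <- gsub("-", " ", tolower(as.character(nodes$rank)))
  name <- if ("name" %in% names(nodes)) as.character(nodes$name)
          else as.character(id)
  if (anyDuplicated(id))
    stop("duplicate taxon_id: ", id[anyDuplicated(id)], call. = FALSE)
  bad_rank <- setdiff(unique(rank), c(.RANKS, "no rank"))
  if (length(bad_rank) > 0L)
    stop("unknown rank label(s): ", paste(bad_rank, collapse = ", "),
         call. = FALSE)

  is_root <- is.na(parent) | parent == id
  if (sum(is_root) != 1L)
    stop("taxonomy must have exactly one root (parent = self or NA), found ",
         sum(is_root), call. = FALSE)
  root <- id[is_root]
  orphan <- !is.na(parent) & !(parent %in% id)
  if (any(orphan))
    stop("orphan parent reference: node ", id[which(orphan)[1L]],
         " points to absent parent ", parent[which(orphan)[1L]],
         call. = FALSE)

  key <- as.character(id)
  parent_v <- setNames(parent, key)
  parent_v[as.character(root)] <- NA_integer_
  # cycle check: walk every node to the root
  depth <- setNames(rep(NA_integer_, length(id)), key)
  depth[as.character(root)] <- 0L
  for (k in key) {
    path <- character(0)
    cur <- k
    while (is.na(depth[cur])) {
      if (cur %in% path)
        stop("cycle detected in taxonomy at node ", cur, call. = FALSE)
      path <- c(path, cur)
      cur <- as.character(parent_v[cur])
    }
    d <- depth[cur]
    for (p in rev(path)) {
      d <- d + 1L
      depth[p] <- d
    }
  }

  out <- list(id = id,
              parent = parent_v,
              rank = setNames(rank, key),
              name = setNames(name, key),
              depth = depth,
              root = root)
  class(out) <- "taxonomy_tree"
  out
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", length(x$id), " nodes, root ", x$root,
      " (", x$name[as.character(x$root)], "), max depth ",
      max(x$depth), "\n", sep = "")
  invisible(x)
}

#' Read a taxonomy from NCBI dmp files or a TSV
#'
#' Supports the NCBI `nodes.dmp`/`names.dmp` dialect (fields separated by
#' `\t|\t`, lines terminated by `\t|`; only `scientific name` rows of
#' names.dmp are used) and a simple TSV with header columns `taxon_id`,
#' `parent_id`, `rank`, `name`.
#'
#' @param nodes_path path to nodes.dmp or the TSV.
#' @param names_path optional path to names.dmp (dmp dialect only).
#' @param format `"auto"` (dmp when the first line contains `"\t|"`),
#'   `"dmp"` or `"tsv"`.
#' @return A [taxonomy_tree].
#' @export
read_taxonomy <- function(nodes_path, names_path = NULL,
                          format = c("auto", "dmp", "tsv")) {
  format <- match.arg(format)
  if (!file.exists(nodes_path))
    stop("taxonomy file not found: ", nodes_path, call. = FALSE)
  if (format == "auto") {
    first <- readLines(nodes_path, n = 1L)
    format <- if (length(first) > 0L && grepl("\t\\|", first)) "dmp" else "tsv"
  }
  if (format == "tsv") {
    tab <- read.delim(nodes_path, header = TRUE, sep = "\t",
                      comment.char = "#", stringsAsFactors = FALSE)
    return(taxonomy_tree(tab))
  }
  parse_dmp <- function(path) {
    lines <- readLines(path)
    lines <- sub("\t\\|$", "", lines)
    strsplit(lines, "\t\\|\t")
  }
  recs <- parse_dmp(nodes_path)
  if (length(recs) == 0L) stop("empty taxonomy: no root node", call. = FALSE)
  nodes <- data.frame(
    taxon_id = as.integer(vapply(recs, `[`, "", 1L)),
    parent_id = as.integer(vapply(recs, `[`, "", 2L)),
    rank = vapply(recs, `[`, "", 3L),
    stringsAsFactors = FALSE)
  nodes$rank[!(gsub("-", " ", tolower(nodes$rank)) %in% .RANKS)] <- "no rank"
  if (!is.null(names_path)) {
    nrec <- parse_dmp(names_path)
    cls <- vapply(nrec, function(r) if (length(r) >= 4L) r[4L] else "", "")
    sci <- nrec[cls == "scientific name"]
    nm <- setNames(vapply(sci, `[`, "", 2L),
                   vapply(sci, `[`, "", 1L))
    nodes$name <- unname(nm[as.character(nodes$taxon_id)])
    nodes$name[is.na(nodes$name)] <- as.character(
      nodes$taxon_id[is.na(nodes$name)])
  }
  taxonomy_tree(nodes)
}

.check_taxa <- function(tree, taxa) {
  known <- as.character(taxa) %in% names(tree$parent)
  if (!all(known))
    stop("unknown taxon id(s): ",
         paste(unique(taxa[!known]), collapse = ", "), call. = FALSE)
}

#' Lineage of a taxon
#'
#' @param tree a [taxonomy_tree].
#' @param taxon a taxon id.
#' @return Integer vector of taxon ids from the root down to `taxon`.
#' @export
lineage <- function(tree, taxon) {
  .check_taxa(tree, taxon)
  path <- integer(0)
  cur <- as.integer(taxon)
  while (!is.na(cur)) {
    path <- c(cur, path)
    cur <- tree$parent[as.character(cur)]
  }
  unname(path)
}

#' Lowest common ancestor of a taxon set
#'
#' The deepest node that is an ancestor-or-self of every input taxon. This
#' is the plain LCA (no minimum-support or top-percent heuristics); support
#' thresholds are applied by the caller.
#'
#' @param tree a [taxonomy_tree].
#' @param taxa non-empty vector of taxon ids.
#' @return A single taxon id.
#' @export
lca <- function(tree, taxa) {
  taxa <- unique(as.integer(taxa))
  if (length(taxa) == 0L) stop("lca of an empty taxon set", call. = FALSE)
  .check_taxa(tree, taxa)
  common <- lineage(tree, taxa[1L])
  for (t in taxa[-1L]) {
    ln <- lineage(tree, t)
    n <- min(length(common), length(ln))
    eq <- common[seq_len(n)] == ln[seq_len(n)]
    common <- common[seq_len(if (all(eq)) n else which(!eq)[1L] - 1L)]
  }
  common[length(common)]
}

#' Project a taxon onto a taxonomic rank
#'
#' Walks the lineage of `taxon` and returns the unique ancestor-or-self
#' carrying the requested rank, or `NA` when the lineage has no node at that
#' rank (the taxon sits above it, or the lineage skips it). Nodes of rank
#' `"no rank"` are transparent: the walk passes through them.
#'
#' @param tree a [taxonomy_tree].
#' @param taxon vector of taxon ids (vectorized).
#' @param rank one of superkingdom, phylum, class, order, family, genus,
#'   species.
#' @return Integer vector of taxon ids, `NA` where the rank is absent.
#' @export
project_to_rank <- function(tree, taxon, rank) {
  rank <- gsub("-", " ", tolower(rank))
  if (length(rank) != 1L || !(rank %in% .RANKS))
    stop("unknown rank label: ", rank, call. = FALSE)
  taxon <- as.integer(taxon)
  .check_taxa(tree, taxon[!is.na(taxon)])
  uq <- unique(taxon[!is.na(taxon)])
  proj <- vapply(uq, function(t) {
    cur <- t
    while (!is.na(cur)) {
      if (tree$rank[as.character(cur)] == rank) return(cur)
      cur <- tree$parent[as.character(cur)]
    }
    NA_integer_
  }, integer(1))
  out <- proj[match(taxon, uq)]
  unname(out)
}

#' Rank label of a taxon
#' @param tree a [taxonomy_tree].
#' @param taxon vector of taxon ids.
#' @return Character vector of rank labels.
#' @export
taxon_rank <- function(tree, taxon) {
  .check_taxa(tree, taxon)
  unname(tree$rank[as.character(taxon)])
}

#' Name of a taxon
#' @param tree a [taxonomy_tree].
#' @param taxon vector of taxon ids.
#' @return Character vector of names.
#' @export
taxon_name <- function(tree, taxon) {
  out <- tree$name[as.character(taxon)]
  unname(out)
}

#' Is `ancestor` an ancestor-or-self of `taxon`?
#' @param tree a [taxonomy_tree].
#' @param ancestor,taxon taxon ids.
#' @return Logical.
#' @export
is_ancestor <- function(tree, ancestor, taxon) {
  as.integer(ancestor) %in% lineage(tree, taxon)
}
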