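# Report formatting helpers. Per-sample recovery rates are truncated to one
# decimal (2050/7078 = 28.96 prints as 28.9); aggregate summaries (means,
# SDs) round half-up instead.

#' Truncate a percentage to one decimal for per-sample reporting
#' @param x numeric vector of percentages.
#' @param digits decimals kept (default 1).
#' @return Numeric vector truncated (not rounded) to `digits` decimals.
#' @export
format_rate <- function(x, digits = 1L) {
  f <- 10^digits
  trunc(x * f + 1e-9) / f
}

#' Round half-up to a number of decimals
#' @param x numeric vector.
#' @param digits decimals kept.
#' @return Numeric vector rounded half-up (0.05 -> 0.1).
#' @export
round_half_up <- function(x, digits = 1L) {
  f <- 10^digits
  floor(x * f + 0.5 + 1e-9) / f
}

#' Recovery rate of discarded fragments
#'
#' The percentage of previously discarded fragments that the method assigns
#' to a taxon. Returned at full precision; use [format_rate] for the
#' truncated per-sample presentation.
#'
#' @param n_assigned number of fragments assigned.
#' @param n_discarded number of discarded fragments analyzed (> 0).
#' @return `100 * n_assigned / n_discarded`.
#' @export
recovery_rate <- function(n_assigned, n_discarded) {
  if (any(n_discarded <= 0))
    stop("recovery_rate: n_discarded must be > 0", call. = FALSE)
  if (any(n_assigned > n_discarded))
    stop("recovery_rate: n_assigned exceeds n_discarded", call. = FALSE)
  100 * n_assigned / n_discarded
}

#' Per-class confusion counts at a taxonomic rank
#'
#' Projects both the truth label and the assignment of every truth-labeled
#' read onto `rank` and tallies, for each class `i` at that rank: `TP`
#' (truth `i`, assigned `i`), `FP` (truth `j != i`, assigned `i`), `FN`
#' (truth `i`, assigned to some other class at the rank) and `U` (truth `i`
#' but unclassified, or assigned above the rank so no class can be
#' inferred). Reads whose *truth* lineage has no node at the rank are
#' excluded, so `sum(TP + FN + U)` equals the number of truth-labeled reads
#' having a class at the rank.
#'
#' @param assignments a `binning_result` (or any data.frame with `read_id`,
#'   `status`, `taxon_id`). Reads in `truth` but absent here count as
#'   unclassified.
#' @param truth named vector `read_id -> true taxon_id` (leaves of the
#'   tree, typically species).
#' @param tree a [taxonomy_tree].
#' @param rank a canonical rank label.
#' @return data.frame of class `confusion_counts`: `rank`, `class_id`,
#'   `class_name`, `TP`, `FP`, `FN`, `U`.
#' @export
confusion_counts <- function(assignments, truth, tree, rank) {
  assignments <- as.data.frame(assignments)
  truth_ids <- as.integer(truth)
  .check_taxa(tree, truth_ids)
  reads <- names(truth)
  truth_cls <- project_to_rank(tree, truth_ids, rank)
  keep <- !is.na(truth_cls)
  reads <- reads[keep]; truth_cls <- truth_cls[keep]

  m <- match(reads, assignments$read_id)
  asg_taxon <- assignments$taxon_id[m]
  asg_taxon[is.na(m) | assignments$status[m] != "assigned"] <- NA_integer_
  pred_cls <- rep(NA_integer_, length(reads))
  has_asg <- !is.na(asg_taxon)
  pred_cls[has_asg] <- project_to_rank(tree, asg_taxon[has_asg], rank)

  classes <- sort(unique(c(truth_cls, pred_cls[!is.na(pred_cls)])))
  out <- data.frame(
    rank = rank,
    class_id = classes,
    class_name = taxon_name(tree, classes),
    TP = vapply(classes, function(i)
      sum(truth_cls == i & !is.na(pred_cls) & pred_cls == i), integer(1)),
    FP = vapply(classes, function(i)
      sum(truth_cls != i & !is.na(pred_cls) & pred_cls == i), integer(1)),
    FN = vapply(classes, function(i)
      sum(truth_cls == i & !is.na(pred_cls) & pred_cls != i), integer(1)),
    U = vapply(classes, function(i)
      sum(truth_cls == i & is.na(pred_cls)), integer(1)),
    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("confusion_counts", "data.frame")
  out
}

#' Per-class sensitivity
#'
#' `Sn_i = TP_i / (TP_i + FN_i + U_i)`: the fraction of fragments of class
#' `i` correctly classified, counting unclassifiable fragments in the
#' denominator. `NA` for classes absent from the truth.
#'
#' @param counts a [confusion_counts] data.frame (vectorized over rows).
#' @return Numeric vector of fractions in `[0, 1]`.
#' @export
sensitivity <- function(counts) {
  den <- counts$TP + counts$FN + counts$U
  ifelse(den > 0, counts$TP / den, NA_real_)
}

#' Per-class specificity
#'
#' `Sp_i = TP_i / (TP_i + FP_i)`: the reliability of predictions made for
#' class `i`. Undefined (`NA`) when nothing was predicted as `i`.
#'
#' @param counts a [confusion_counts] data.frame (vectorized over rows).
#' @return Numeric vector of fractions in `[0, 1]`, `NA` where undefined.
#' @export
specificity <- function(counts) {
  den <- counts$TP + counts$FP
  ifelse(den > 0, counts$TP / den, NA_real_)
}

#' Accuracy table over classes of one rank
#'
#' Adds per-class `Sn`/`Sp` to confusion counts. Macro averages are
#' unweighted means over classes with a defined value; micro ("pooled")
#' averages aggregate counts first and are the dataset-level fractions.
#'
#' @param counts a [confusion_counts] data.frame.
#' @return The table with `Sn` and `Sp` columns; macro and micro averages
#'   in `attr(, "summary")`.
#' @export
accuracy_table <- function(counts) {
  counts$Sn <- sensitivity(counts)
  counts$Sp <- specificity(counts)
  tp <- sum(counts$TP); fp <- sum(counts$FP)
  fnu <- sum(counts$FN + counts$U)
  attr(counts, "summary") <- data.frame(
    rank = if (nrow(counts) > 0L) counts$rank[1L] else NA_character_,
    macro_sn = mean(counts$Sn, na.rm = TRUE),
    macro_sp = mean(counts$Sp, na.rm = TRUE),
    micro_sn = if (tp + fnu > 0) tp / (tp + fnu) else NA_real_,
    micro_sp = if (tp + fp > 0) tp / (tp + fp) else NA_real_)
  counts
}

#' Distribution of candidate CDS counts per read
#'
#' Bins reads by their number of candidate coding loci into 0, 1, 2 and
#' 3-or-more, the categories used to gauge how many discarded fragments
#' carry the two-gene signal the adjacency criterion needs.
#'
#' @param loci_per_read integer vector: candidate CDS count of each read.
#' @return data.frame with `bin` (`"0"`, `"1"`, `"2"`, `"3+"`), `count`,
#'   and `pct` (rounded half-up to one decimal).
#' @export
cds_count_distribution <- function(loci_per_read) {
  x <- as.integer(loci_per_read)
  bins <- c("0", "1", "2", "3+")
  binned <- ifelse(x >= 3L, "3+", as.character(x))
  count <- vapply(bins, function(b) sum(binned == b), integer(1))
  total <- length(x)
  pct <- if (total > 0L) round_half_up(100 * count / total, 1L) else
    rep(NA_real_, 4L)
  data.frame(bin = bins, count = unname(count), pct = unname(pct),
             stringsAsFactors = FALSE)
}

#' Composition profile of assigned reads at a rank
#'
#' Counts assigned reads per taxon at the requested rank. Unclassified
#' reads and reads whose assignment sits above the rank are excluded from
#' the profile and reported in `attr(, "n_excluded")`.
#'
#' @param assignments a `binning_result`.
#' @param tree a [taxonomy_tree].
#' @param rank a canonical rank label.
#' @return data.frame of class `composition_profile` (`taxon_id`, `name`,
#'   `count`), rank in `attr(, "rank")`.
#' @export
composition_profile <- function(assignments, tree, rank) {
  assignments <- as.data.frame(assignments)
  asg <- assignments[assignments$status == "assigned", , drop = FALSE]
  cls <- if (nrow(asg) > 0L) project_to_rank(tree, asg$taxon_id, rank)
         else integer(0)
  keep <- !is.na(cls)
  tab <- table(cls[keep])
  out <- data.frame(taxon_id = as.integer(names(tab)),
                    count = as.integer(tab), stringsAsFactors = FALSE)
  out$name <- if (nrow(out) > 0L) taxon_name(tree, out$taxon_id)
              else character(0)
  out <- out[order(-out$count, out$taxon_id), c("taxon_id", "name", "count")]
  rownames(out) <- NULL
  attr(out, "rank") <- rank
  attr(out, "n_excluded") <- nrow(assignments) - sum(keep)
  class(out) <- c("composition_profile", "data.frame")
  out
}

.profile_counts <- function(p) {
  if (is.data.frame(p)) setNames(p$count, as.character(
    if (!is.null(p$taxon_id)) p$taxon_id else p$name))
  else p
}

#' Pool rare phylotypes of two composition profiles
#'
#' Before correlating two composition profiles, phylotypes that only make a
#' marginal contribution are combined into a shared `"other"` category so
#' that many near-zero categories do not dominate the comparison. The
#' category set is the union of both profiles (absent means count 0). By
#' default a phylotype is pooled only when its count is below `threshold`
#' in *both* profiles (pooling a category abundant in one profile would
#' discard real signal); `rule = "either"` pools when below threshold in
#' at least one. Totals are preserved exactly.
#'
#' @param a,b [composition_profile]s (or named count vectors) at one rank.
#' @param threshold pooling threshold (default 5, i.e. counts < 5).
#' @param rule `"both"` (default) or `"either"`.
#' @return List with elements `a` and `b`: named count vectors over an
#'   identical category set, including `"other"` when anything was pooled.
#' @export
pool_rare_phylotypes <- function(a, b, threshold = 5L,
                                 rule = c("both", "either")) {
  rule <- match.arg(rule)
  ca <- .profile_counts(a); cb <- .profile_counts(b)
  cats <- sort(unique(c(names(ca), names(cb))))
  va <- setNames(ifelse(is.na(ca[cats]), 0L, ca[cats]), cats)
  vb <- setNames(ifelse(is.na(cb[cats]), 0L, cb[cats]), cats)
  pool <- if (rule == "both") va < threshold & vb < threshold
          else va < threshold | vb < threshold
  if (any(pool)) {
    keep <- cats[!pool]
    va <- c(va[keep], other = sum(va[pool]))
    vb <- c(vb[keep], other = sum(vb[pool]))
  }
  list(a = va, b = vb)
}

#' Pearson correlation of two composition profiles
#'
#' Product-moment correlation of the paired per-phylotype counts of two
#' profiles sharing an identical category set (pool first, see
#' [pool_rare_phylotypes]). Because the coefficient is affine-invariant,
#' counts and per-profile proportions give the same value.
#'
#' @param a,b named count vectors over an identical category set, or
#'   [composition_profile]s.
#' @return Pearson `r`, or `NA` (with a warning) when fewer than two
#'   categories are present or one profile has zero variance.
#' @export
pearson_compare <- function(a, b) {
  va <- .profile_counts(a); vb <- .profile_counts(b)
  if (!identical(sort(names(va)), sort(names(vb))))
    stop("profiles must share an identical category set; pool first",
         call. = FALSE)
  vb <- vb[names(va)]
  if (length(va) < 2L) {
    warning("fewer than 2 categories: correlation undefined")
    return(NA_real_)
  }
  if (sd(va) == 0 || sd(vb) == 0) {
    warning("zero variance in a profile: correlation undefined")
    return(NA_real_)
  }
  unname(cor(as.numeric(va), as.numeric(vb)))
}
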