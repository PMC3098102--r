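asg_row <- function(read, status, taxon = NA_integer_) {
  data.frame(read_id = read, status = status, taxon_id = taxon,
             stringsAsFactors = FALSE)
}

test_that("confusion counts enumerate TP/FP/FN/U per class", {
  tr <- tiny_tree()
  # 4 reads of species s1 (class G1 at genus): 2 right, 1 wrong (G3 via
  # s4), 1 unclassified
  truth <- setNames(c(61, 61, 61, 61), paste0("r", 1:4))
  asg <- rbind(asg_row("r1", "assigned", 61L),
               asg_row("r2", "assigned", 62L),   # still genus G1
               asg_row("r3", "assigned", 70L),   # genus G3: wrong
               asg_row("r4", "unclassified"))
  cc <- confusion_counts(asg, truth, tr, "genus")
  g1 <- cc[cc$class_id == 50, ]
  expect_equal(c(g1$TP, g1$FN, g1$U, g1$FP), c(2L, 1L, 1L, 0L))
  g3 <- cc[cc$class_id == 52, ]
  expect_equal(c(g3$TP, g3$FP), c(0L, 1L))
  # an assignment above the rank counts as unclassifiable for its class
  asg2 <- rbind(asg_row("r1", "assigned", 40L))  # family-level assignment
  cc2 <- confusion_counts(asg2, truth["r1"], tr, "genus")
  expect_equal(cc2$U[cc2$class_id == 50], 1L)
  # all unclassified / perfect assignment edge cases
  cc3 <- confusion_counts(rbind(asg_row("r1", "unclassified"),
                                asg_row("r2", "unclassified")),
                          truth[1:2], tr, "genus")
  expect_equal(c(sum(cc3$TP), sum(cc3$FP), sum(cc3$FN)), c(0L, 0L, 0L))
  expect_equal(sum(cc3$U), 2L)
  cc4 <- confusion_counts(rbind(asg_row("r1", "assigned", 61L)),
                          truth["r1"], tr, "species")
  expect_equal(c(cc4$TP, cc4$FP, cc4$FN, cc4$U), c(1L, 0L, 0L, 0L))
})

test_that("sensitivity and specificity follow the per-class definitions", {
  cc <- data.frame(TP = c(2L, 0L, 3L, 9L, 0L, 0L),
                   FN = c(1L, 5L, 0L, 0L, 4L, 0L),
                   U = c(1L, 0L, 0L, 0L, 0L, 0L),
                   FP = c(0L, 0L, 0L, 1L, 4L, 0L))
  expect_equal(sensitivity(cc), c(0.5, 0, 1, 1, 0, NA))
  expect_equal(specificity(cc), c(1, NA, 1, 0.9, 0, NA))
})

test_that("counts are conserved and Sn/Sp stay within [0, 1]", {
  tr <- tiny_tree()
  species <- c(61, 62, 63, 70)
  withr::with_seed(41, {
    for (it in 1:20) {
      n <- sample(5:40, 1)
      truth <- setNames(sample(species, n, replace = TRUE),
                        paste0("r", seq_len(n)))
      status <- sample(c("assigned", "unclassified"), n, replace = TRUE,
                       prob = c(0.7, 0.3))
      taxon <- ifelse(status == "assigned",
                      sample(c(species, 50, 40, 2), n, replace = TRUE),
                      NA_integer_)
      asg <- data.frame(read_id = names(truth), status = status,
                        taxon_id = as.integer(taxon))
      for (rank in c("phylum", "family", "genus", "species")) {
        cc <- confusion_counts(asg, truth, tr, rank)
        n_at_rank <- sum(!is.na(project_to_rank(tr, truth, rank)))
        expect_equal(sum(cc$TP + cc$FN + cc$U), n_at_rank)
        sn <- sensitivity(cc); sp <- specificity(cc)
        expect_true(all(sn >= 0 & sn <= 1, na.rm = TRUE))
        expect_true(all(sp >= 0 & sp <= 1, na.rm = TRUE))
      }
    }
  })
})

test_that("recovery rates compute exactly and truncate for display", {
  expect_equal(format_rate(recovery_rate(1050, 7039)), 14.9)
  expect_equal(format_rate(recovery_rate(2050, 7078)), 28.9)  # 28.96 truncates
  expect_equal(format_rate(recovery_rate(3711, 11791)), 31.4) # 31.47 truncates
  expect_equal(recovery_rate(0, 100), 0)
  expect_error(recovery_rate(1, 0), "> 0")
  expect_error(recovery_rate(5, 4), "exceeds")
})

test_that("CDS-count distribution bins reads as 0/1/2/3+", {
  d <- cds_count_distribution(c(0, 1, 1, 2, 5, 3))
  expect_equal(d$bin, c("0", "1", "2", "3+"))
  expect_equal(d$count, c(1L, 2L, 1L, 2L))       # 5 and 3 land in 3+
  expect_equal(sum(d$count), 6L)
  expect_equal(d$pct, round(100 * d$count / 6, 1))
  all0 <- cds_count_distribution(rep(0, 10))
  expect_equal(all0$pct, c(100, 0, 0, 0))
})

test_that("composition profiles count assigned reads at a rank", {
  tr <- tiny_tree()
  asg <- rbind(asg_row("r1", "assigned", 61L),
               asg_row("r2", "assigned", 62L),
               asg_row("r3", "assigned", 63L),
               asg_row("r4", "assigned", 70L),
               asg_row("r5", "unclassified"),
               asg_row("r6", "assigned", 2L))  # above phylum: excluded
  p <- composition_profile(asg, tr, "phylum")
  expect_equal(setNames(p$count, p$taxon_id), c("10" = 3L, "11" = 1L))
  expect_equal(attr(p, "n_excluded"), 2L)
  empty <- composition_profile(asg[0, ], tr, "phylum")
  expect_equal(nrow(empty), 0L)
})

test_that("rare-phylotype pooling shares the category set and keeps totals", {
  a <- c(X = 100, Y = 3, Z = 2)
  b <- c(X = 90, Y = 4, Z = 1)
  pooled <- pool_rare_phylotypes(a, b, threshold = 5)
  expect_equal(pooled$a, c(X = 100, other = 5))
  expect_equal(pooled$b, c(X = 90, other = 5))
  # nothing below threshold: unchanged (category union, no "other")
  p2 <- pool_rare_phylotypes(c(X = 10, Y = 6), c(X = 5, Y = 9))
  expect_false("other" %in% names(p2$a))
  # everything rare collapses to a single "other", totals preserved
  p3 <- pool_rare_phylotypes(c(X = 2), c(X = 1))
  expect_equal(p3$a, c(other = 2))
  expect_equal(p3$b, c(other = 1))
  # "both" vs "either": Y is abundant in one profile only
  a2 <- c(X = 50, Y = 100); b2 <- c(X = 40, Y = 2)
  expect_true("Y" %in% names(pool_rare_phylotypes(a2, b2)$a))
  expect_false("Y" %in% names(pool_rare_phylotypes(a2, b2,
                                                   rule = "either")$a))
  # totals preserved under random profiles
  withr::with_seed(51, {
    for (it in 1:20) {
      n <- sample(2:12, 1)
      x <- setNames(rpois(n, 4), paste0("t", 1:n))
      y <- setNames(rpois(n, 4), paste0("t", sample(1:n)))
      p <- pool_rare_phylotypes(x, y, threshold = sample(2:8, 1))
      expect_equal(sum(p$a), sum(x))
      expect_equal(sum(p$b), sum(y))
      expect_equal(names(p$a), names(p$b))
    }
  })
})

test_that("profile correlation is the product-moment coefficient", {
  expect_equal(pearson_compare(c(a = 1, b = 2, c = 3),
                               c(a = 1, b = 2, c = 3)), 1.0)
  expect_equal(pearson_compare(c(a = 1, b = 2, c = 3),
                               c(a = 3, b = 2, c = 1)), -1.0)
  # independent closed-form evaluation of r for (10,0,5,1) vs (8,1,6,0)
  x <- c(10, 0, 5, 1); y <- c(8, 1, 6, 0)
  r_closed <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  expect_equal(pearson_compare(setNames(x, letters[1:4]),
                               setNames(y, letters[1:4])), r_closed)
  expect_warning(r1 <- pearson_compare(c(a = 1), c(a = 2)), "fewer than 2")
  expect_true(is.na(r1))
  expect_warning(r2 <- pearson_compare(c(a = 3, b = 3), c(a = 1, b = 2)),
                 "zero variance")
  expect_true(is.na(r2))
  expect_error(pearson_compare(c(a = 1, b = 2), c(a = 1, c = 2)),
               "identical category set")
})

test_that("correlation is invariant to converting counts to proportions", {
  withr::with_seed(52, {
    for (it in 1:20) {
      n <- sample(3:10, 1)
      x <- setNames(rpois(n, 10) + 1, paste0("t", 1:n))
      y <- setNames(rpois(n, 10) + 1, paste0("t", 1:n))
      r_counts <- pearson_compare(x, y)
      r_props <- pearson_compare(x / sum(x), y / sum(y))
      expect_equal(r_counts, r_props, tolerance = 1e-12)
    }
  })
})

test_that("pooled sensitivity does not increase from phylum toward genus", {
  com <- small_community(seed = 13)
  res <- bin_dataset(com$hits, com$index, com$tree)
  sn <- vapply(c("phylum", "order", "family", "genus"), function(r) {
    s <- attr(accuracy_table(confusion_counts(res, com$truth, com$tree, r)),
              "summary")
    s$micro_sn
  }, numeric(1))
  expect_true(all(diff(sn) <= 1e-12))
})
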