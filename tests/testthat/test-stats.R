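test_that("ANOVA F and P match the textbook brute-force computation", {
  set.seed(61)
  d <- tibble::tibble(
    group = rep(c("a", "b", "c"), times = c(5, 6, 7)),
    y = c(rnorm(5, 0), rnorm(6, 1), rnorm(7, 0.5))
  )
  cmp <- group_anova(d, "y")
  # independent oracle: direct sums of squares
  gm <- mean(d$y)
  means <- tapply(d$y, d$group, mean)
  ns <- tapply(d$y, d$group, length)
  ssb <- sum(ns * (means - gm)^2)
  ssw <- sum((d$y - means[d$group])^2)
  F_oracle <- (ssb / 2) / (ssw / (18 - 3))
  expect_equal(cmp$anova$F, F_oracle, tolerance = 1e-10)
  expect_equal(cmp$anova$p, pf(F_oracle, 2, 15, lower.tail = FALSE),
               tolerance = 1e-10)
  # cross-check against stats::aov
  a <- summary(stats::aov(y ~ group, data = d))[[1]]
  expect_equal(cmp$anova$F, a[["F value"]][1], tolerance = 1e-10)
})

test_that("pairwise LSD t-tests match the pooled-variance formula", {
  set.seed(62)
  d <- tibble::tibble(
    group = rep(c("a", "b", "c"), each = 6),
    y = rnorm(18, rep(c(0, 0.8, 2), each = 6))
  )
  cmp <- group_anova(d, "y")
  means <- tapply(d$y, d$group, mean)
  ns <- tapply(d$y, d$group, length)
  msw <- cmp$anova$ms_within
  for (r in seq_len(nrow(cmp$pairwise))) {
    g1 <- cmp$pairwise$group1[r]; g2 <- cmp$pairwise$group2[r]
    t_oracle <- (means[[g1]] - means[[g2]]) /
      sqrt(msw * (1 / ns[[g1]] + 1 / ns[[g2]]))
    p_oracle <- 2 * pt(abs(t_oracle), 18 - 3, lower.tail = FALSE)
    expect_equal(cmp$pairwise$t[r], unname(t_oracle), tolerance = 1e-10)
    expect_equal(cmp$pairwise$p[r], unname(p_oracle), tolerance = 1e-10)
  }
})

test_that("Hochberg adjustment is monotone and never below the raw P", {
  set.seed(63)
  d <- tibble::tibble(group = rep(letters[1:4], each = 5),
                      y = rnorm(20, rep(c(0, 0.3, 1, 1.4), each = 5)))
  cmp <- group_anova(d, "y")
  pw <- cmp$pairwise
  expect_true(all(pw$p_adj >= pw$p - 1e-15))
  o <- order(pw$p)
  expect_true(all(diff(pw$p_adj[o]) >= -1e-15))
  expect_equal(pw$p_adj, p.adjust(pw$p, "hochberg"))
})

test_that("separated exact groups give near-zero P and singleton subsets", {
  d <- tibble::tibble(group = rep(c("lo", "hi"), each = 4),
                      y = rep(c(1, 2), each = 4) + rep(c(0, 1e-9, -1e-9, 0), 2))
  cmp <- group_anova(d, "y")
  expect_lt(cmp$anova$p, 1e-12)
  expect_equal(length(cmp$subsets), 2)
  expect_true(all(lengths(cmp$subsets) == 1))
})

test_that("samples from one distribution are usually not separated", {
  set.seed(64)
  d <- tibble::tibble(group = rep(letters[1:3], each = 10), y = rnorm(30))
  cmp <- group_anova(d, "y")
  expect_gt(cmp$anova$p, 0.05)
  expect_equal(length(cmp$subsets), 1)
  expect_setequal(cmp$subsets[[1]], letters[1:3])
})

test_that("degenerate groups are reported, not silently dropped", {
  d <- tibble::tibble(group = c("a", "a", "a", "b", "b", "c"),
                      y = c(1, 2, 1.5, 4, 5, 9))
  cmp <- group_anova(d, "y")
  expect_equal(cmp$degenerate, "c")
  expect_setequal(cmp$groups$group, c("a", "b"))
})

test_that("percentile trimming follows the linear-interpolation convention", {
  x <- c(3, 1, 4, 1.5, 9, 2.6, 5.3, 5.8, 9.7, 9.3)
  tr <- trimmed_subset(x)
  q <- quantile(x, c(0.2, 0.8), type = 7, names = FALSE)
  expect_setequal(as.numeric(tr), x[x >= q[1] & x <= q[2]])
  # all-equal values survive trimming
  expect_equal(as.numeric(trimmed_subset(rep(2, 6))), rep(2, 6))
  # idempotence
  expect_identical(trimmed_subset(trimmed_subset(x)), trimmed_subset(x))
})

test_that("Pearson correlations match the hand formula and flag constants", {
  x <- c(1, 2, 3, 5, 8)
  y <- c(2.2, 1.9, 3.5, 4.9, 9.1)
  d <- tibble::tibble(x = x, y = y, const = 1)
  cm <- correlation_matrix(d)
  r_oracle <- sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  row <- cm[cm$var1 == "x" & cm$var2 == "y", ]
  expect_equal(row$r, r_oracle, tolerance = 1e-10)
  m <- attr(cm, "matrix")
  expect_equal(diag(m), c(x = 1, y = 1, const = 1))
  expect_equal(m["x", "y"], m["y", "x"])
  expect_equal(cm$significance[cm$var1 == "x" & cm$var2 == "const"],
               "undefined")
})

test_that("model sensitivity correlates with the naive index on a cohort", {
  co <- generate_cohort(
    simo_cohort_defaults(n = c(NGT = 16, IFG = 16, IGT = 16,
                               "IFG+IGT" = 15, T2DM = 15)),
    seed = 71)
  panel <- ogtt_indices(co)
  tru <- cohort_truth(co)
  d <- dplyr::left_join(panel, tru[, c("subject", "k_xgi")], by = "subject")
  cm <- correlation_matrix(d, vars = c("k_xgi", "IS_NAIF", "HOMA_IS"))
  row <- cm[cm$var1 == "k_xgi" & cm$var2 == "IS_NAIF", ]
  expect_gt(row$r, 0)
  expect_lt(row$p, 0.01)
})

test_that("coefficient-of-variation summaries follow the n-1 convention", {
  d <- tibble::tibble(group = c("a", "a", "a", "b", "b"),
                      y = c(1, 1, 1, 2, 4))
  s <- cv_summary(d, "y")
  expect_equal(s$by_group$cv[s$by_group$group == "a"], 0)
  expect_equal(s$by_group$cv[s$by_group$group == "b"], sd(c(2, 4)) / 3)
  d5 <- tibble::tibble(group = rep(letters[1:5], each = 2),
                       y = rep(c(2, 4), 5))
  s5 <- cv_summary(d5, "y")
  expect_equal(s5$average_cv, s5$by_group$cv[1])
  expect_true(all(s5$by_group$cv == s5$by_group$cv[1]))
})
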