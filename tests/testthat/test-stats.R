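test_that("pearson correlation matches the two-pass formula and is affine-invariant", {
  perfect <- pearson(1:10, 2 * (1:10) + 1)
  expect_equal(perfect$r, 1)

  expect_error(pearson(rep(1, 5), 1:5), "zero variance")
  expect_error(pearson(1:4, 1:5), "equal length")

  two_pass <- function(x, y) {
    sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
  }
  set.seed(91)
  for (i in 1:25) {
    x <- rnorm(30); y <- rnorm(30)
    expect_equal(pearson(x, y)$r, two_pass(x, y), tolerance = 1e-12)
    shifted <- pearson(3 * x + 7, -2 * y + 1)
    expect_equal(shifted$r, -pearson(x, y)$r, tolerance = 1e-12)
  }
})

test_that("the pooled t statistic matches the closed form", {
  same <- unpaired_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$statistic, 0)
  expect_equal(same$p.value, 1)

  res <- unpaired_t(c(1, 2, 3), c(4, 5, 6))
  # pooled s^2 = 1, t = -3 / sqrt(2/3)
  expect_equal(res$statistic, -3 / sqrt(2 / 3), tolerance = 1e-12)

  welch <- unpaired_t(c(1, 2, 3), c(4, 6, 9), pooled = FALSE)
  expect_lt(welch$df, 4)  # Welch degrees of freedom are fractional
  expect_error(unpaired_t(c(1), c(2, 3)), "n >= 2")
})

test_that("the t test holds its nominal type-I error under the null", {
  set.seed(92)
  n_sim <- 10000L
  rejected <- vapply(seq_len(n_sim), function(i)
    unpaired_t(rnorm(8), rnorm(8))$p.value < 0.05, TRUE)
  expect_lt(abs(mean(rejected) - 0.05), 0.01)
})

test_that("p values are uniform under the null (KS check)", {
  set.seed(93)
  p_t <- vapply(1:2000, function(i) unpaired_t(rnorm(8), rnorm(8))$p.value, 0)
  expect_gt(suppressWarnings(ks.test(p_t, "punif"))$p.value, 0.01)
  p_r <- vapply(1:2000, function(i) pearson(rnorm(20), rnorm(20))$p.value, 0)
  expect_gt(suppressWarnings(ks.test(p_r, "punif"))$p.value, 0.01)
})

test_that("ANOVA reduces to t^2 for two groups and matches the SS oracle", {
  identical_groups <- one_way_anova(list(c(1, 1, 1), c(1, 1, 1)))
  expect_equal(identical_groups$statistic, 0)
  expect_equal(identical_groups$p.value, 1)

  set.seed(94)
  a <- rnorm(10); b <- rnorm(10, 0.5)
  f2 <- one_way_anova(list(a, b))
  t2 <- unpaired_t(a, b)$statistic^2
  expect_lt(abs(f2$statistic - t2), 1e-10)

  groups <- list(rnorm(7), rnorm(9, 1), rnorm(8, 2))
  res <- one_way_anova(groups)
  all_y <- unlist(groups)
  ss_between <- sum(vapply(groups, function(g)
    length(g) * (mean(g) - mean(all_y))^2, 0))
  ss_within <- sum(vapply(groups, function(g)
    sum((g - mean(g))^2), 0))
  expect_lt(abs(res$ss_between - ss_between), 1e-10)
  expect_lt(abs(res$ss_within - ss_within), 1e-10)
  expect_error(one_way_anova(list(rnorm(3))), ">= 2 groups")
})

test_that("Tukey HSD returns adjusted pairwise contrasts", {
  set.seed(95)
  groups <- list(rnorm(8), rnorm(8), rnorm(8, 3))
  hsd <- tukey_hsd(groups, labels = c("g1", "g2", "g3"))
  expect_identical(nrow(hsd), 3L)
  expect_true(all(hsd$p_adj >= 0 & hsd$p_adj <= 1))
  expect_lt(hsd$p_adj[hsd$comparison == "g3-g1"], 0.05)
  expect_gt(hsd$p_adj[hsd$comparison == "g2-g1"], 0.05)
})

test_that("decade bins match the cohort grouping and exclude out-of-range ages", {
  bins <- bin_by_decade(c(17, 26, 27, 46, 47, 77))
  expect_identical(names(bins),
                   c("17-26", "27-36", "37-46", "47-56", "57-66", "67-77"))
  expect_identical(bins[["17-26"]], c(17, 26))
  expect_identical(bins[["27-36"]], 27)
  expect_identical(bins[["37-46"]], 46)
  expect_identical(bins[["67-77"]], 77)
  expect_message(out <- bin_by_decade(c(16, 30, 78)), "excluded")
  expect_identical(unlist(out, use.names = FALSE), 30)
})

test_that("fold changes are ratios of group means", {
  expect_equal(fold_change(c(2, 2), c(1, 1)), 2)
  expect_error(fold_change(c(1, 2), c(0, 0)), "zero denominator")
  expect_error(fold_change(numeric(), 1), "empty")
  cmp <- group_comparison(c(8, 9, 10), c(1, 1.2, 0.8))
  expect_gt(cmp$fold_change, 8)
  expect_lt(cmp$p.value, 0.01)
})
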