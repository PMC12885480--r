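test_that("region summaries compute mean, variance and skewness", {
  dims <- c(1L, 2L, 3L)
  mask <- array(TRUE, dims)
  # constant map: zero variance and (by convention) zero skewness
  s1 <- summarize_region(array(0.7, dims), mask)
  expect_equal(s1$mean, 0.7)
  expect_equal(s1$variance, 0)
  expect_equal(s1$skewness, 0)
  expect_equal(s1$n_voxels, 6)
  # two-voxel case with hand-computed sample variance
  m2 <- array(NA_real_, dims); m2[1, 1, 1] <- 0.6; m2[1, 2, 1] <- 0.8
  s2 <- summarize_region(m2, mask)
  expect_equal(s2$mean, 0.7)
  expect_equal(s2$variance, 0.02)
  expect_equal(s2$n_voxels, 2)
  # symmetric values: zero skewness
  m3 <- array(c(0.1, 0.2, 0.3, 0.4, 0.5, NA), dims)
  expect_lt(abs(summarize_region(m3, mask)$skewness), 1e-12)
  # empty intersection warns and returns NULL
  expect_warning(s4 <- summarize_region(array(NA_real_, dims), mask),
                 "no valid voxels")
  expect_null(s4)
})

test_that("hemisphere pooling averages equally or by voxel count", {
  tab <- data.frame(subject_id = c("f1", "f1", "f2"),
                    mean = c(0.68, 0.70, 0.71),
                    n_voxels = c(100, 300, 80))
  eq <- pool_hemispheres(tab)
  expect_equal(eq$mean[eq$subject_id == "f1"], 0.69)
  expect_equal(eq$mean[eq$subject_id == "f2"], 0.71)   # single side passes through
  expect_equal(eq$n_hemispheres, c(2L, 1L))
  vw <- pool_hemispheres(data.frame(subject_id = "s", mean = c(0.6, 0.8),
                                    n_voxels = c(100, 300)),
                         voxel_weighted = TRUE)
  expect_equal(vw$mean, 0.75)
})

test_that("summary-statistic t equals the raw-sample t for matching samples", {
  # construct a sample with exactly the requested mean and SD
  make_sample <- function(n, m, s) {
    x <- scale(rnorm(n))[, 1]
    m + s * x
  }
  set.seed(33)
  x <- make_sample(15, 0.715, 0.018)
  y <- make_sample(15, 0.701, 0.022)
  from_summary <- t_test_summary(15, 0.715, 0.018, 15, 0.701, 0.022)
  from_raw <- compare_independent(list(x, y))
  expect_equal(from_summary$statistic, from_raw$statistic, tolerance = 1e-10)
  expect_equal(from_summary$df, from_raw$df)
  expect_equal(from_summary$p_value, from_raw$p_value, tolerance = 1e-10)
})

test_that("summary-statistic ANOVA matches a per-observation reconstruction", {
  make_sample <- function(n, m, s) m + s * scale(rnorm(n))[, 1]
  set.seed(44)
  n <- c(13, 15, 15); mu <- c(0.730, 0.715, 0.701); sd_ <- c(0.019, 0.018, 0.022)
  groups <- Map(make_sample, n, mu, sd_)
  from_summary <- oneway_anova_summary(n, mu, sd_)
  from_raw <- compare_independent(groups)
  expect_equal(from_summary$statistic, from_raw$statistic, tolerance = 1e-8)
  expect_equal(from_summary$df, from_raw$df)
  expect_equal(from_summary$p_value, from_raw$p_value, tolerance = 1e-8)
})

test_that("degenerate group comparisons return zero statistics", {
  g <- rep(0.5, 5)
  r2 <- compare_independent(list(g, g))
  expect_equal(r2$statistic, 0)
  expect_equal(r2$p_value, 1)
  r3 <- compare_independent(list(g, g, g))
  expect_equal(r3$statistic, 0)
  expect_equal(r3$p_value, 1)
})

test_that("paired comparisons handle matched, equal and shifted inputs", {
  a <- c(0.68, 0.70, 0.69, 0.72)
  expect_error(compare_paired(a, a[-1]), "equal length")
  same <- compare_paired(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  shifted <- compare_paired(a + 0.05, a)
  expect_true(is.infinite(shifted$statistic) && shifted$statistic > 0)
  expect_equal(shifted$p_value, 0)
  real <- compare_paired(c(0.746, 0.75, 0.74), c(0.682, 0.69, 0.68))
  expect_equal(real$df, 2)
  expect_gt(real$statistic, 0)
})

test_that("repeated-measures ANOVA matches the textbook SS decomposition", {
  set.seed(55)
  n <- 4; k <- 3
  tab <- matrix(rnorm(n * k, mean = rep(c(0.68, 0.70, 0.71), each = n),
                      sd = 0.02), n, k)
  res <- compare_paired(tab)
  # brute-force two-way (subject + condition) sums of squares
  grand <- mean(tab)
  ss_cond <- n * sum((colMeans(tab) - grand)^2)
  ss_subj <- k * sum((rowMeans(tab) - grand)^2)
  ss_tot <- sum((tab - grand)^2)
  ss_err <- ss_tot - ss_cond - ss_subj
  f_ref <- (ss_cond / (k - 1)) / (ss_err / ((k - 1) * (n - 1)))
  expect_equal(res$statistic, f_ref, tolerance = 1e-10)
  expect_equal(res$df, c(k - 1, (k - 1) * (n - 1)))
  # for k = 2 the RM-ANOVA F equals the squared paired t
  tab2 <- tab[, 1:2]
  f2 <- compare_paired(tab2)$statistic
  t2 <- compare_paired(tab2[, 1], tab2[, 2])$statistic
  expect_equal(f2, t2^2, tolerance = 1e-10)
})

test_that("Bonferroni adjustment never decreases p and caps at one", {
  set.seed(66)
  p <- runif(20)
  for (m in c(1, 3, 10)) {
    adj <- pmin(1, m * p)
    res <- compare_independent(
      list(rnorm(5), rnorm(5), rnorm(5)), adjustment = "bonferroni")
    for (cmp in res$posthoc) {
      expect_gte(cmp$adjusted_p, cmp$p_value)
      expect_lte(cmp$adjusted_p, 1)
    }
    expect_true(all(adj >= p) && all(adj <= 1))
  }
})

test_that("map correlations recover exact and null relationships", {
  dims <- c(1L, 100L, 100L)
  mask <- array(TRUE, dims)
  set.seed(77)
  a <- array(runif(prod(dims), 0.6, 0.8), dims)
  # exact negative linear relation
  r_neg <- param_correlation(a, -a + 1, mask)
  expect_equal(r_neg$r, -1, tolerance = 1e-12)
  # duplicated map
  r_pos <- param_correlation(a, a, mask)
  expect_equal(r_pos$r, 1, tolerance = 1e-12)
  # independent maps at n = 10^4: negligible correlation
  b <- array(runif(prod(dims), 3, 4), dims)
  r0 <- param_correlation(a, b, mask)
  expect_lt(abs(r0$r), 0.03)
  expect_true(r0$conf_int[1] < r0$r && r0$r < r0$conf_int[2])
  # constant map is undefined
  expect_warning(rc <- param_correlation(array(1, dims), b, mask), "constant")
  expect_null(rc)
})

test_that("pooled-t rejection rate matches closed-form power", {
  # two-group design in the conditioning-experiment regime:
  # effect 0.017, SD 0.02, n = 18 and 19
  n1 <- 18; n2 <- 19; delta <- 0.017; sdv <- 0.02
  set.seed(88)
  n_sim <- 1000
  rejections <- 0
  for (i in seq_len(n_sim)) {
    x <- rnorm(n1, 0.735, sdv)
    y <- rnorm(n2, 0.735 - delta, sdv)
    if (compare_independent(list(x, y))$p_value < 0.05)
      rejections <- rejections + 1
  }
  emp <- rejections / n_sim
  ref <- power.t.test(n = (n1 + n2) / 2, delta = delta, sd = sdv,
                      sig.level = 0.05)$power
  expect_lt(abs(emp - ref), 0.05)
})
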