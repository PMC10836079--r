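# Null distributions, p-values, confidence intervals and the full
# permutation-test pipeline.

test_that("max null distribution behaves under degeneracy and duplication", {
  set.seed(20)
  s1 <- matrix(rnorm(1000), 1000, 1)
  nd_max <- build_null_distribution(s1, "two", "max")
  nd_none <- build_null_distribution(s1, "two", "none")
  expect_equal(nd_max$null, as.vector(nd_none$null))  # single variable
  # duplicating a variable leaves the max distribution unchanged
  s2 <- cbind(s1, s1)
  expect_equal(build_null_distribution(s2, "two", "max")$null, nd_max$null)
  # 20 independent variables: corrected 95th percentile strictly exceeds
  # the single-variable one (order statistics of the max)
  s20 <- matrix(rnorm(1000 * 20), 1000, 20)
  q_corr <- quantile(build_null_distribution(s20, "two", "max")$null, 0.95)
  q_unc <- quantile(abs(s20[, 1]), 0.95)
  expect_gt(q_corr, q_unc)
})

test_that("empirical p-values honour tie and boundary semantics", {
  null <- c(0.1, 0.5, 1, 2, 3)  # absolute-scale null, m = 5
  expect_equal(p_from_distribution(4, null, "two"), 0)     # beyond all
  expect_equal(p_from_distribution(3, null, "two"), 1 / 5) # tie counts
  expect_equal(p_from_distribution(0.1, null, "two"), 1)   # at the minimum
  expect_equal(p_from_distribution(-3, null, "two"), 1 / 5) # magnitude
  expect_equal(p_from_distribution(2, null, "right"), 2 / 5)
  expect_equal(p_from_distribution(0.5, null, "left"), 2 / 5)
  expect_equal(p_from_distribution(3, null, "two", add_one = TRUE), 2 / 6)
  expect_true(is.na(p_from_distribution(NA, null, "two")))
})

test_that("CIs scale by se, collapse on degenerate nulls, honour alpha", {
  null_abs <- abs(rnorm(10000))
  ci <- ci_from_distribution(2, 0.5, null_abs, alpha = 0.05, tail = "two")
  c95 <- quantile(null_abs, 0.95, names = FALSE)
  expect_equal(ci, c(2 - c95 * 0.5, 2 + c95 * 0.5))
  # degenerate null -> interval collapses to the point estimate
  expect_equal(ci_from_distribution(1.5, 0.3, rep(0, 100), 0.05, "two"),
               c(1.5, 1.5))
  # one-tailed: one side infinite
  expect_equal(ci_from_distribution(1, 1, rnorm(100), 0.05, "right")[2], Inf)
  expect_equal(ci_from_distribution(1, 1, rnorm(100), 0.05, "left")[1], -Inf)
  # re-centred construction at alpha = 0.05 uses the 2.5/97.5 percentiles
  null_s <- rnorm(10000)
  ci_r <- ci_from_distribution(0.4, NA, null_s, 0.05, "right")
  expect_equal(ci_r[1], 0.4 - quantile(null_s, 0.95, names = FALSE))
})

test_that("complete separation with n = 3 per group gives exhaustive p = 0.1", {
  r <- perm_ttest2(c(5, 6, 7), c(1, 2, 3), seed = 1)
  expect_true(r$exhaustive)
  expect_equal(r$n_resamples, 20)
  expect_equal(r$table$p, 2 / 20)  # only the two extreme assignments tie |t|
})

test_that("exhaustive sign-flip p-values land on the 1/2^n grid", {
  set.seed(21)
  x <- matrix(rnorm(4, 1), 4, 1)
  y <- matrix(rnorm(4), 4, 1)
  r <- perm_ttest(x, y, seed = 1)
  expect_true(r$exhaustive)
  expect_equal(r$n_resamples, 16)
  expect_equal(r$table$p * 16, round(r$table$p * 16))
})

test_that("Monte-Carlo p converges to the exhaustive oracle", {
  set.seed(22)
  for (i in 1:5) {
    x <- rnorm(4, mean = runif(1, 0, 2))
    y <- rnorm(4)
    p_ex <- exhaustive_t2_p(x, y)
    r_mc <- perm_ttest2(x, y, n_resamples = 8000, seed = i,
                        exhaustive = FALSE)
    tol <- 3 * sqrt(p_ex * (1 - p_ex) / 8000) + 1e-9
    expect_lt(abs(r_mc$table$p - p_ex), tol + 2 / 8000)
  }
})

test_that("max correction is monotone in p and CI width, off for 1 variable", {
  syn <- synth_two_sample(synth_spec(seed = 23))
  rmax <- perm_ttest2(syn$x, syn$y, n_resamples = 1000, seed = 5)
  rnone <- perm_ttest2(syn$x, syn$y, n_resamples = 1000, seed = 5,
                       correction = "none")
  expect_true(all(rmax$table$p >= rnone$table$p - 1e-12))
  wmax <- rmax$table$ci_upper - rmax$table$ci_lower
  wnone <- rnone$table$ci_upper - rnone$table$ci_lower
  expect_true(all(wmax >= wnone - 1e-12))
  # true nulls (variables 11-20) must not dominate the corrected tail
  expect_true(all(rmax$table$p[11:20] >= rnone$table$p[11:20] - 1e-12))
  # single-variable input: correction makes no difference
  r1a <- perm_ttest2(syn$x[, 1], syn$y[, 1], n_resamples = 500, seed = 6,
                     correction = "max")
  r1b <- perm_ttest2(syn$x[, 1], syn$y[, 1], n_resamples = 500, seed = 6,
                     correction = "none")
  expect_equal(r1a$table$p, r1b$table$p)
})

test_that("fixed seeds give bit-identical results", {
  syn <- synth_two_sample(synth_spec(n_obs = 15, n_vars = 5, seed = 24))
  r1 <- perm_ttest2(syn$x, syn$y, n_resamples = 500, seed = 7)
  r2 <- perm_ttest2(syn$x, syn$y, n_resamples = 500, seed = 7)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$null_distribution, r2$null_distribution)
  e1 <- boot_effect_size(syn$x, syn$y, "cohen", n_boot = 300, seed = 8)
  e2 <- boot_effect_size(syn$x, syn$y, "cohen", n_boot = 300, seed = 8)
  expect_identical(e1$table, e2$table)
})

test_that("single-variable null p-values are close to uniform", {
  set.seed(25)
  pvals <- replicate(400, {
    x <- rnorm(12); y <- rnorm(12)
    perm_ttest2(x, y, n_resamples = 200, seed = sample.int(1e6, 1),
                exhaustive = FALSE)$table$p
  })
  # stochastically >= uniform (b/m convention is not anti-conservative
  # beyond Monte-Carlo noise): check the rejection rate at 0.05 and the mean
  expect_lt(mean(pvals <= 0.05), 0.05 + 3 * sqrt(0.05 * 0.95 / 400))
  expect_gt(mean(pvals), 0.45)
})

test_that("correlation and variance tests run end to end with sane output", {
  set.seed(26)
  x <- rnorm_mat(25, 3, seed = 27)
  y <- 0.8 * x + rnorm_mat(25, 3, seed = 28, sd = 0.5)
  r <- perm_corr(x, y, n_resamples = 600, seed = 9)
  expect_true(all(r$table$statistic > 0.5))
  expect_true(all(r$table$p <= 0.05))
  expect_true(all(r$table$ci_lower <= r$table$statistic &
                    r$table$statistic <= r$table$ci_upper))
  expect_true(all(r$table$ci_lower >= -1 & r$table$ci_upper <= 1))
  rp <- perm_corr(x, method = "spearman", pairwise = TRUE,
                  n_resamples = 300, seed = 10)
  expect_equal(nrow(rp$table), choose(3, 2))

  v <- perm_vartest2(rnorm_mat(20, 2, 29, sd = 3), rnorm_mat(20, 2, 30),
                     n_resamples = 600, seed = 11)
  expect_true(all(v$table$statistic > 1))
  expect_true(all(v$table$ci_lower <= v$table$statistic &
                    v$table$statistic <= v$table$ci_upper))

  a <- perm_anova1(list(rnorm_mat(8, 2, 31), rnorm_mat(8, 2, 32),
                        rnorm_mat(8, 2, 33, mean = 2)),
                   n_resamples = 600, seed = 12)
  expect_true(all(a$table$p <= 0.05))
  expect_equal(a$tail, "right")

  set.seed(34)
  fa <- gl(2, 12); fb <- rep(gl(2, 6), 2)
  yresp <- rnorm(24) + 2 * (fa == "2")
  a2 <- perm_anova2(yresp, fa, fb, n_resamples = 600, seed = 13)
  expect_equal(a2$table$variable, c("A", "B", "A:B"))
  expect_lt(a2$table$p[1], 0.05)
  expect_gt(a2$table$p[3], 0.05)
})

test_that("undefined variables are excluded from the max, not failed", {
  x <- cbind(rnorm_mat(10, 1, 35), const = rep(1, 10))
  y <- cbind(rnorm_mat(10, 1, 36, mean = 1), const = rep(1, 10))
  r <- perm_ttest2(x, y, n_resamples = 300, seed = 14)
  expect_true(is.na(r$table$p[2]))
  expect_false(is.na(r$table$p[1]))
  expect_true(r$undefined[2])
})

test_that("run_permutation_test dispatches with a shared config", {
  syn <- synth_two_sample(synth_spec(n_obs = 10, n_vars = 3, seed = 37))
  cfg <- perm_config(n_resamples = 400, seed = 15)
  r1 <- run_permutation_test("ttest2", x = syn$x, y = syn$y, config = cfg)
  r2 <- perm_ttest2(syn$x, syn$y, n_resamples = 400, seed = 15)
  expect_identical(r1$table, r2$table)
  rz <- run_permutation_test("ztest", x = syn$x, mu = 0, sigma = 1,
                             config = cfg)
  expect_s3_class(rz, "perm_test")
})
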