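# Effect sizes: closed-form checks, brute-force oracles, bias correction,
# bootstrap interval behaviour.

test_that("Cohen's d and Glass' delta follow their defining formulas", {
  d <- cohens_d_from_summary(-0.06, 0.91, 30, -1.09, 0.86, 30,
                             bias_correction = FALSE)
  expect_equal(d$uncorrected, 1.03 / sqrt((0.91^2 + 0.86^2) / 2),
               tolerance = 1e-12)
  expect_equal(d$uncorrected, 1.1633, tolerance = 1e-3)

  x <- rnorm_mat(40, 3, seed = 40)
  y <- rnorm_mat(40, 3, seed = 41)
  expect_equal(unname(cohens_d(x, x)), rep(0, 3))
  expect_equal(cohens_d(x, y), -cohens_d(y, x))  # antisymmetry
  # equal n: pooled standardiser equals sqrt of average variance
  dp <- cohens_d(x, y, "pooled"); du <- cohens_d(x, y, "unpooled")
  expect_equal(dp, du, tolerance = 1e-12)

  ctrl <- matrix(rep(c(1, 3), 10), ncol = 1)       # sd = 2 (approx), gap 1
  ctrl <- matrix(rnorm(200, 0, 2), ncol = 1)
  trt <- ctrl + 1
  gd <- glass_delta(trt, ctrl)
  expect_equal(unname(gd), 1 / sd(ctrl), tolerance = 1e-12)
  expect_equal(glass_delta(x, x)[[1]], 0)
  # scale invariance
  expect_equal(glass_delta(3 * trt, 3 * ctrl), gd, tolerance = 1e-12)
})

test_that("Cliff's d matches the brute-force pair count, ties included", {
  expect_equal(cliffs_d(c(2, 4), c(1, 3))[[1]], 0.5)
  expect_equal(cliffs_d(c(10, 11, 12), c(1, 2, 3))[[1]], 1)  # dominance
  expect_equal(cliffs_d(c(1, 2, 3), c(1, 2, 3))[[1]], 0)     # same multiset
  set.seed(42)
  for (i in 1:30) {
    x <- sample(1:6, sample(3:12, 1), replace = TRUE)  # heavy ties
    y <- sample(1:6, sample(3:12, 1), replace = TRUE)
    expect_equal(cliffs_d(x, y)[[1]], cliffs_d_brute(x, y),
                 tolerance = 1e-12)
  }
  expect_true(all(abs(cliffs_d(rnorm_mat(20, 4, 43),
                               rnorm_mat(20, 4, 44))) <= 1))
})

test_that("the Hedges factor follows 1 - 3/(4n - 9)", {
  expect_equal(hedges_factor(3), 0)
  expect_equal(hedges_factor(60), 1 - 3 / 231)
  expect_error(hedges_factor(2), "at least 3")
  n <- c(5, 10, 30, 100, 1000)
  f <- hedges_factor(n)
  expect_true(all(diff(f) > 0))      # monotone increasing
  expect_lt(1 - hedges_factor(10000), 1e-4)  # -> 1
})

test_that("unstandardised measures are equivariant and robust as designed", {
  expect_equal(unstandardised_effect(c(1, 2, 9), c(1, 2, 3), "meandiff")[[1]],
               2)
  expect_equal(unstandardised_effect(c(1, 2, 9), c(1, 2, 3),
                                     "mediandiff")[[1]], 0)
  x <- rnorm_mat(10, 2, 45); y <- rnorm_mat(10, 2, 46)
  expect_equal(unstandardised_effect(x + 3, y, "meandiff"),
               unstandardised_effect(x, y, "meandiff") + 3)
  expect_equal(unname(unstandardised_effect(x, x, "meandiff")), rep(0, 2))
})

test_that("bias correction shrinks d toward the truth in small samples", {
  set.seed(47)
  nsim <- 4000; n <- 10
  d_unc <- numeric(nsim)
  for (i in seq_len(nsim)) {
    d_unc[i] <- cohens_d(rnorm(n, 1), rnorm(n))[[1]]
  }
  g <- d_unc * hedges_factor(2 * n)
  expect_gt(mean(d_unc), 1)                        # upward bias
  expect_lt(abs(mean(g) - 1), abs(mean(d_unc) - 1)) # correction helps
  # corrected magnitude never exceeds the uncorrected one
  expect_true(all(abs(g) <= abs(d_unc)))
})

test_that("bootstrap CIs bracket the estimate and degenerate correctly", {
  syn <- synth_two_sample(synth_spec(n_obs = 25, n_vars = 4, seed = 48,
                                     shifted_vars = 1:2))
  for (meas in c("cohen", "glass", "cliff", "meandiff", "mediandiff")) {
    e <- boot_effect_size(syn$x, syn$y, meas, n_boot = 400, seed = 16)
    expect_true(all(e$table$ci_lower <= e$table$effect + 1e-9),
                label = meas)
    expect_true(all(e$table$effect <= e$table$ci_upper + 1e-9),
                label = meas)
    expect_equal(e$bias_corrected, meas %in% c("cohen", "glass"))
  }
  # degenerate data: meandiff CI collapses to [0, 0]
  const <- matrix(2, 10, 1)
  e0 <- boot_effect_size(const, const, "meandiff", n_boot = 100, seed = 17)
  expect_equal(e0$table$effect, 0)
  expect_equal(e0$table$ci_lower, 0)
  expect_equal(e0$table$ci_upper, 0)
  # percentile pair: alpha = 0.05 -> 2.5 and 97.5 percentiles of the
  # bootstrap distribution (checked against a manual bootstrap)
  x1 <- syn$x[, 1]; y1 <- syn$y[, 1]
  e1 <- boot_effect_size(x1, y1, "meandiff", n_boot = 500, seed = 18)
  idx <- maxperm:::with_seed(18, {
    ix <- matrix(sample.int(25, 500 * 25, replace = TRUE), 500)
    iy <- matrix(sample.int(25, 500 * 25, replace = TRUE), 500)
    list(x = ix, y = iy)
  })
  effs <- rowMeans(matrix(x1[idx$x], 500)) - rowMeans(matrix(y1[idx$y], 500))
  expect_equal(c(e1$table$ci_lower, e1$table$ci_upper),
               unname(quantile(effs, c(0.025, 0.975))), tolerance = 1e-12)
})

test_that("bias correction applies inside replicates and flags plumb through", {
  syn <- synth_two_sample(synth_spec(n_obs = 12, n_vars = 2, seed = 49))
  ec <- boot_effect_size(syn$x, syn$y, "cohen", n_boot = 300, seed = 19)
  eu <- boot_effect_size(syn$x, syn$y, "cohen", n_boot = 300, seed = 19,
                         bias_correction = FALSE)
  f <- hedges_factor(24)
  expect_equal(ec$table$effect, eu$table$effect * f, tolerance = 1e-12)
  expect_equal(ec$table$ci_lower, eu$table$ci_lower * f, tolerance = 1e-12)
  expect_equal(ec$correction_factor, f)
  expect_false(eu$bias_corrected)
  expect_identical(ec$measure_name, "hedges_g")
  # cliff is never corrected
  ecl <- boot_effect_size(syn$x, syn$y, "cliff", n_boot = 200, seed = 20)
  expect_false(ecl$bias_corrected)
  expect_true(is.na(ecl$correction_factor))
})

test_that("paired designs resample pairs jointly", {
  set.seed(50)
  x <- matrix(rnorm(30), ncol = 1)
  y <- x + rnorm(30, 0.5, 0.1)   # tight pairing
  ep <- boot_effect_size(x, y, "meandiff", paired = TRUE, n_boot = 400,
                         seed = 21)
  ei <- boot_effect_size(x, y, "meandiff", paired = FALSE, n_boot = 400,
                         seed = 21)
  # joint resampling preserves the pairing: far narrower interval
  expect_lt(ep$table$ci_upper - ep$table$ci_lower,
            (ei$table$ci_upper - ei$table$ci_lower) / 2)
  ed <- boot_effect_size(x, y, "cohen", paired = TRUE, n_boot = 200,
                         seed = 22)
  expect_equal(ed$table$effect[1],
               cohens_d(x, y, paired = TRUE)[[1]] * hedges_factor(30),
               tolerance = 1e-12)
})

test_that("glass control argument can be swapped", {
  x <- rnorm_mat(15, 1, 51, sd = 3); y <- rnorm_mat(15, 1, 52)
  ey <- boot_effect_size(x, y, "glass", n_boot = 100, seed = 23)
  ex <- boot_effect_size(x, y, "glass", n_boot = 100, seed = 23,
                         control = "x")
  expect_equal(ey$table$effect[1],
               glass_delta(x, y)[[1]] * hedges_factor(30), tolerance = 1e-12)
  expect_equal(ex$table$effect[1],
               glass_delta(y, x)[[1]] * hedges_factor(30), tolerance = 1e-12)
})
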