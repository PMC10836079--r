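# User-facing permutation tests. Each function computes the observed
# statistic bundle, generates a shared resampling index table, recomputes the
# kernel on every resample, and assembles a `perm_test` result carrying the
# per-variable statistic, df, empirical p-value, confidence interval, group
# summaries and the (shared or per-variable) permutation null distribution.

#' Run configuration for permutation analyses
#'
#' Bundles the options shared by every test into a single validated list,
#' mirroring the command-line flags. Max correction is applied to
#' multivariate data by default; pass `correction = "none"` to disable it.
#'
#' @param tail `"two"` (default), `"right"` or `"left"`.
#' @param alpha Significance level for confidence intervals (default 0.05).
#' @param correction `"auto"` (max whenever more than one variable is
#'   tested; default), `"max"` or `"none"`.
#' @param n_resamples Number of permutations (default 10000).
#' @param n_boot Number of bootstrap resamples for effect sizes (default
#'   10000).
#' @param seed RNG seed (default 42; fixed so that naive runs reproduce).
#' @param exhaustive `NA` (automatic), `TRUE` or `FALSE`.
#' @param add_one Use the `(b+1)/(m+1)` p-value convention (default `FALSE`,
#'   i.e. the plain proportion `b/m`).
#' @param variance_mode `"pooled"` (Student) or `"unpooled"` (Welch).
#' @return A list of class `"perm_config"`.
#' @export
perm_config <- function(tail = c("two", "right", "left"), alpha = 0.05,
                        correction = c("auto", "max", "none"),
                        n_resamples = 10000, n_boot = 10000, seed = 42,
                        exhaustive = NA, add_one = FALSE,
                        variance_mode = c("pooled", "unpooled")) {
  structure(list(tail = match.arg(tail), alpha = check_alpha(alpha),
                 correction = match.arg(correction),
                 n_resamples = check_count(n_resamples, "n_resamples"),
                 n_boot = check_count(n_boot, "n_boot"),
                 seed = as.integer(seed), exhaustive = exhaustive,
                 add_one = isTRUE(add_one),
                 variance_mode = match.arg(variance_mode)),
            class = "perm_config")
}

#' Two-sample permutation t-test
#'
#' Compares the means of two independent multivariate samples with a
#' permutation test based on the two-sample t-statistic (Student's pooled
#' form by default, Welch's unpooled form on request). Group labels are
#' permuted across the stacked observations; the same permutations are
#' applied to every variable, and with `correction = "max"` a single
#' max-statistic null distribution adjusts all p-values and confidence
#' intervals for multiple comparisons. Confidence intervals are reported on
#' the mean-difference scale (`x - y`).
#'
#' @param x,y Numeric matrices (observations x variables) or vectors with the
#'   same number of columns.
#' @param variance_mode `"pooled"` (Student's t; equal variances assumed) or
#'   `"unpooled"` (Welch's t with Welch-Satterthwaite df).
#' @param tail,alpha,correction,n_resamples,seed,exhaustive,add_one See
#'   [perm_config()].
#' @return A `perm_test` object; `$table` holds variable, statistic, df,
#'   estimate (mean difference), se, p, ci_lower, ci_upper.
#' @examples
#' syn <- synth_two_sample(synth_spec(n_obs = 12, n_vars = 3, seed = 9))
#' perm_ttest2(syn$x, syn$y, n_resamples = 500, seed = 1)
#' @export
perm_ttest2 <- function(x, y, variance_mode = c("pooled", "unpooled"),
                        tail = c("two", "right", "left"), alpha = 0.05,
                        correction = c("auto", "max", "none"),
                        n_resamples = 10000, seed = 42, exhaustive = NA,
                        add_one = FALSE) {
  x <- as_data_matrix(x, "x"); y <- as_data_matrix(y, "y")
  if (ncol(x) != ncol(y))
    stop("'x' and 'y' must have the same number of variables", call. = FALSE)
  variance_mode <- match.arg(variance_mode)
  tail <- match.arg(tail)
  correction <- resolve_correction(match.arg(correction), ncol(x))
  if (variance_mode == "pooled" && nrow(x) != nrow(y))
    warning("pooled variance with unequal sample sizes: the permutation test ",
            "is robust to variance differences mainly for equal n",
            call. = FALSE)
  bundle <- kernel_t2(x, y, variance_mode)
  plan <- resampling_plan("label_permutation", n_resamples, seed, exhaustive)
  perms <- generate_label_permutations(plan, c(nrow(x), nrow(y)))
  resamp <- resample_stats_t2(rbind(x, y), perms, nrow(x), variance_mode)
  make_perm_test("two-sample t-test", bundle, resamp, tail, correction,
                 check_alpha(alpha), isTRUE(add_one), "se",
                 list(var_names = colnames(x), seed = seed,
                      exhaustive = attr(perms, "exhaustive")))
}

#' One-sample and paired-sample permutation t-test
#'
#' Tests the mean of `x` against `mu`, or (when `y` is supplied) the mean of
#' the paired differences `x - y` against zero, by sign-flipping the
#' deviations about the hypothesised mean — the exchangeability-respecting
#' permutation scheme for symmetric one-sample nulls. Confidence intervals
#' are on the mean (or mean-difference) scale.
#'
#' @param x Numeric matrix (observations x variables) or vector.
#' @param y Optional paired partner of the same shape; the test is then run
#'   on the differences with `mu = 0`.
#' @param mu Hypothesised mean (default 0), ignored when `y` is given.
#' @inheritParams perm_ttest2
#' @return A `perm_test` object.
#' @export
perm_ttest <- function(x, y = NULL, mu = 0,
                       tail = c("two", "right", "left"), alpha = 0.05,
                       correction = c("auto", "max", "none"),
                       n_resamples = 10000, seed = 42, exhaustive = NA,
                       add_one = FALSE) {
  x <- as_data_matrix(x, "x")
  label <- "one-sample t-test"
  if (!is.null(y)) {
    y <- as_data_matrix(y, "y")
    if (!all(dim(x) == dim(y)))
      stop("paired samples must have identical dimensions", call. = FALSE)
    pair_ok <- !is.na(x) & !is.na(y)
    d <- x - y                       # NA where either member missing
    d[!pair_ok] <- NA
    mu <- 0
    label <- "paired-sample t-test"
  } else {
    d <- x
  }
  tail <- match.arg(tail)
  correction <- resolve_correction(match.arg(correction), ncol(d))
  bundle <- kernel_t1(d, mu)
  dev <- sweep(d, 2, rep(mu, ncol(d)))
  plan <- resampling_plan("sign_flip", n_resamples, seed, exhaustive)
  flips <- generate_sign_flips(plan, nrow(d))
  resamp <- resample_stats_t1(dev, flips)
  res <- make_perm_test(label, bundle, resamp, tail, correction,
                        check_alpha(alpha), isTRUE(add_one), "se",
                        list(var_names = colnames(d), seed = seed,
                             exhaustive = attr(flips, "exhaustive")))
  # report CI about the mean itself, not the deviation from mu
  res$table$estimate <- res$table$estimate + mu
  res$table$ci_lower <- res$table$ci_lower + mu
  res$table$ci_upper <- res$table$ci_upper + mu
  res
}

#' Two-sample permutation test of variance (F-statistic)
#'
#' Compares the variances of two independent samples using the variance
#' ratio `F = s_x^2 / s_y^2` under group-label permutation. Because F is not
#' sign-symmetric, two-tailed testing (and max correction) operates on the
#' symmetric kernel `|log F|`; the raw F and its degrees of freedom are
#' reported, and confidence intervals are returned on the variance-ratio
#' scale.
#'
#' @inheritParams perm_ttest2
#' @return A `perm_test` object with columns statistic (F), df, df2.
#' @export
perm_vartest2 <- function(x, y, tail = c("two", "right", "left"),
                          alpha = 0.05, correction = c("auto", "max", "none"),
                          n_resamples = 10000, seed = 42, exhaustive = NA,
                          add_one = FALSE) {
  x <- as_data_matrix(x, "x"); y <- as_data_matrix(y, "y")
  if (ncol(x) != ncol(y))
    stop("'x' and 'y' must have the same number of variables", call. = FALSE)
  tail <- match.arg(tail)
  correction <- resolve_correction(match.arg(correction), ncol(x))
  bundle <- kernel_f2(x, y)
  plan <- resampling_plan("label_permutation", n_resamples, seed, exhaustive)
  perms <- generate_label_permutations(plan, c(nrow(x), nrow(y)))
  resamp <- resample_stats_logF(rbind(x, y), perms, nrow(x))
  make_perm_test("two-sample variance test", bundle, resamp, tail, correction,
                 check_alpha(alpha), isTRUE(add_one), "ratio",
                 list(var_names = colnames(x), seed = seed,
                      exhaustive = attr(perms, "exhaustive")))
}

#' One-sample permutation Z-test
#'
#' Tests the mean of `x` against `mu` with a known population standard
#' deviation `sigma`, sign-flipping deviations about `mu`. Confidence
#' intervals are on the mean scale with `se = sigma / sqrt(n)`.
#'
#' @param sigma Known population standard deviation (> 0), recycled across
#'   variables.
#' @inheritParams perm_ttest
#' @return A `perm_test` object (df is reported as `NA`).
#' @export
perm_ztest <- function(x, mu = 0, sigma, tail = c("two", "right", "left"),
                       alpha = 0.05, correction = c("auto", "max", "none"),
                       n_resamples = 10000, seed = 42, exhaustive = NA,
                       add_one = FALSE) {
  x <- as_data_matrix(x, "x")
  tail <- match.arg(tail)
  correction <- resolve_correction(match.arg(correction), ncol(x))
  bundle <- kernel_z(x, mu, sigma)
  dev <- sweep(x, 2, rep(mu, ncol(x)))
  plan <- resampling_plan("sign_flip", n_resamples, seed, exhaustive)
  flips <- generate_sign_flips(plan, nrow(x))
  resamp <- resample_stats_z(dev, flips, sigma)
  res <- make_perm_test("one-sample Z-test", bundle, resamp, tail, correction,
                        check_alpha(alpha), isTRUE(add_one), "se",
                        list(var_names = colnames(x), seed = seed,
                             exhaustive = attr(flips, "exhaustive")))
  res$table$estimate <- res$table$estimate + mu
  res$table$ci_lower <- res$table$ci_lower + mu
  res$table$ci_upper <- res$table$ci_upper + mu
  res
}

#' Permutation correlation test
#'
#' Tests the columnwise (or all-pairs) correlation between matrices by
#' permuting whole rows of the second matrix, which breaks the pairing while
#' preserving each sample's own dependence structure. Methods: `"pearson"`
#' (product-moment), `"spearman"` (Pearson on midranks) and `"rankit"`
#' (Pearson on normal scores `qnorm((rank - 0.5)/n)`, a robust
#' normal-scores correlation). Confidence intervals are re-centred signed
#' percentiles of the permutation distribution, clipped to `[-1, 1]`.
#' Rows with a missing value in either matrix are dropped before testing
#' (shared permutation indices require a common observation set).
#'
#' @param x Numeric matrix (observations x variables).
#' @param y Matrix with the same number of rows; matched to `x` column by
#'   column (same number of columns required). Omitted when
#'   `pairwise = TRUE`.
#' @param method Correlation flavour (see above).
#' @param pairwise If `TRUE`, correlate every pair of columns of `x`
#'   (`choose(p, 2)` results, e.g. a correlation matrix's lower triangle).
#' @inheritParams perm_ttest2
#' @return A `perm_test` object; statistic is the correlation.
#' @export
perm_corr <- function(x, y = NULL, method = c("pearson", "spearman", "rankit"),
                      pairwise = FALSE, tail = c("two", "right", "left"),
                      alpha = 0.05, correction = c("auto", "max", "none"),
                      n_resamples = 10000, seed = 42, exhaustive = NA,
                      add_one = FALSE) {
  method <- match.arg(method)
  tail <- match.arg(tail)
  x <- as_data_matrix(x, "x")
  if (pairwise) {
    if (ncol(x) < 2)
      stop("'pairwise' requires at least 2 columns in 'x'", call. = FALSE)
    pairs <- utils::combn(ncol(x), 2)
    nms <- paste(colnames(x)[pairs[1, ]], colnames(x)[pairs[2, ]], sep = ":")
    y <- x[, pairs[2, ], drop = FALSE]
    x <- x[, pairs[1, ], drop = FALSE]
    colnames(x) <- nms
  } else {
    if (is.null(y)) stop("'y' is required unless pairwise = TRUE", call. = FALSE)
    y <- as_data_matrix(y, "y")
    if (nrow(x) != nrow(y) || ncol(x) != ncol(y))
      stop("'x' and 'y' must have identical dimensions for columnwise ",
           "correlation", call. = FALSE)
  }
  complete <- stats::complete.cases(x) & stats::complete.cases(y)
  if (!all(complete)) {
    message(sprintf("dropping %d incomplete observation(s)", sum(!complete)))
    x <- x[complete, , drop = FALSE]; y <- y[complete, , drop = FALSE]
  }
  if (nrow(x) < 3) stop("need at least 3 complete observations", call. = FALSE)
  correction <- resolve_correction(match.arg(correction), ncol(x))
  bundle <- kernel_corr(x, y, method)
  plan <- resampling_plan("row_permutation", n_resamples, seed, exhaustive)
  perms <- generate_row_permutations(plan, nrow(x))
  resamp <- resample_stats_corr(bundle$zx, bundle$zy, perms)
  make_perm_test(sprintf("correlation test (%s)", method), bundle, resamp,
                 tail, correction, check_alpha(alpha), isTRUE(add_one),
                 "recenter",
                 list(var_names = colnames(x), seed = seed,
                      exhaustive = attr(perms, "exhaustive")),
                 clip = c(-1, 1))
}

#' One-way permutation ANOVA
#'
#' Tests equality of k group means per variable with the classical F
#' statistic under group-label permutation. The test is inherently
#' right-tailed; max correction across variables is applied by default. No
#' confidence interval is reported (F has no unstandardised estimate scale).
#'
#' @param groups A list of numeric matrices (observations x variables), one
#'   per group, all with the same number of variables.
#' @inheritParams perm_ttest2
#' @return A `perm_test` object with statistic F, df (k - 1) and df2 (N - k).
#' @export
perm_anova1 <- function(groups, alpha = 0.05,
                        correction = c("auto", "max", "none"),
                        n_resamples = 10000, seed = 42, exhaustive = NA,
                        add_one = FALSE) {
  if (!is.list(groups) || length(groups) < 2)
    stop("'groups' must be a list of at least 2 matrices", call. = FALSE)
  groups <- lapply(seq_along(groups), function(i)
    as_data_matrix(groups[[i]], paste0("groups[[", i, "]]")))
  p <- ncol(groups[[1]])
  if (any(vapply(groups, ncol, 1L) != p))
    stop("all groups must have the same number of variables", call. = FALSE)
  sizes <- vapply(groups, nrow, 1L)
  if (any(sizes < 2))
    stop("every group needs at least 2 observations", call. = FALSE)
  correction <- resolve_correction(match.arg(correction), p)
  bundle <- kernel_anova1(groups)
  plan <- resampling_plan("label_permutation", n_resamples, seed, exhaustive)
  perms <- generate_label_permutations(plan, sizes)
  resamp <- resample_stats_F1(do.call(rbind, groups), perms, sizes)
  make_perm_test("one-way ANOVA", bundle, resamp, "right", correction,
                 check_alpha(alpha), isTRUE(add_one), "none",
                 list(var_names = colnames(groups[[1]]), seed = seed,
                      exhaustive = attr(perms, "exhaustive")))
}

#' Two-way permutation ANOVA (balanced designs)
#'
#' Tests the two main effects and their interaction for a single response
#' under a balanced crossed design, permuting raw observations across all
#' cells (each effect is referred to the global-null permutation
#' distribution; an approximation, as unrestricted permutation does not
#' condition on the other effects). Unbalanced designs are an explicit
#' error.
#'
#' @param y Numeric response vector.
#' @param factor_a,factor_b Factors (or coercible) of the same length as `y`.
#' @inheritParams perm_ttest2
#' @return A `perm_test` object with rows A, B and A:B. The three effects are
#'   each tested against their own permutation distribution
#'   (`correction = "none"` across effects).
#' @export
perm_anova2 <- function(y, factor_a, factor_b, alpha = 0.05,
                        n_resamples = 10000, seed = 42, add_one = FALSE) {
  y <- as.numeric(y)
  bundle <- kernel_anova2(y, factor_a, factor_b)
  plan <- resampling_plan("row_permutation", n_resamples, seed, FALSE)
  perms <- generate_row_permutations(plan, length(y))
  resamp <- resample_stats_F2(y, perms, bundle$meta)
  bundle$meta <- NULL
  make_perm_test("two-way ANOVA", bundle, resamp, "right", "none",
                 check_alpha(alpha), isTRUE(add_one), "none",
                 list(var_names = c("A", "B", "A:B"), seed = seed,
                      exhaustive = FALSE))
}

#' Dispatch a permutation test by name
#'
#' Thin orchestrator mapping a test name and its options onto the
#' corresponding `perm_*` function, using a [perm_config()] for the shared
#' options. This is the entry point used by the command-line interface.
#'
#' @param test One of `"ttest"`, `"ttest2"`, `"vartest2"`, `"ztest"`,
#'   `"corr"`, `"anova1"`, `"anova2"`.
#' @param ... Data and test-specific arguments passed through (e.g. `x`, `y`,
#'   `mu`, `sigma`, `method`, `pairwise`, `groups`, `factor_a`, `factor_b`).
#' @param config A [perm_config()].
#' @return A `perm_test` object.
#' @export
run_permutation_test <- function(test = c("ttest", "ttest2", "vartest2",
                                          "ztest", "corr", "anova1", "anova2"),
                                 ..., config = perm_config()) {
  test <- match.arg(test)
  shared <- list(alpha = config$alpha, n_resamples = config$n_resamples,
                 seed = config$seed, add_one = config$add_one)
  tailed <- c(shared, list(tail = config$tail, correction = config$correction,
                           exhaustive = config$exhaustive))
  args <- switch(test,
    ttest2 = c(tailed, list(variance_mode = config$variance_mode)),
    vartest2 = , ztest = , corr = , ttest = tailed,
    anova1 = c(shared, list(correction = config$correction,
                            exhaustive = config$exhaustive)),
    anova2 = shared)
  fn <- switch(test, ttest = perm_ttest, ttest2 = perm_ttest2,
               vartest2 = perm_vartest2, ztest = perm_ztest, corr = perm_corr,
               anova1 = perm_anova1, anova2 = perm_anova2)
  do.call(fn, c(list(...), args))
}
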