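# Permutation-distribution machinery: null distributions, empirical p-values
# and percentile-based confidence intervals, with max-statistic correction.

#' Build permutation null distribution(s) from resampled statistics
#'
#' With max correction, a single shared null distribution is formed by taking,
#' on every resample, the maximum absolute statistic (two-tailed), the maximum
#' (right tail) or the minimum (left tail) across variables. Comparing each
#' observed statistic against this shared distribution controls the
#' family-wise error rate strongly: the more variables enter the maximum, the
#' more conservative the distribution becomes. Without correction, each
#' variable keeps its own marginal null distribution.
#'
#' @param resampled_stats Numeric matrix, `n_resamples` rows by `n_vars`
#'   columns, of the statistic recomputed on every resample. Columns for
#'   variables flagged undefined must be excluded by the caller.
#' @param tail `"two"`, `"right"` or `"left"`.
#' @param correction `"max"` or `"none"`.
#' @return For `"max"`, a list with `shared = TRUE` and `null`, a vector of
#'   length `n_resamples` (absolute values when `tail = "two"`). For
#'   `"none"`, `shared = FALSE` and `null` an `n_resamples` x `n_vars`
#'   matrix (absolute values when `tail = "two"`).
#' @export
build_null_distribution <- function(resampled_stats,
                                    tail = c("two", "right", "left"),
                                    correction = c("max", "none")) {
  tail <- match.arg(tail)
  correction <- match.arg(correction)
  resampled_stats <- as.matrix(resampled_stats)
  if (ncol(resampled_stats) == 0)
    stop("all variables are undefined; no null distribution can be built",
         call. = FALSE)
  if (correction == "max") {
    null <- switch(tail,
      two = row_max(abs(resampled_stats)),
      right = row_max(resampled_stats),
      left = row_min(resampled_stats))
    list(shared = TRUE, null = null, tail = tail)
  } else {
    null <- if (tail == "two") abs(resampled_stats) else resampled_stats
    list(shared = FALSE, null = null, tail = tail)
  }
}

#' Empirical p-value from a permutation distribution
#'
#' The p-value is the proportion of the null distribution at least as extreme
#' as the observed statistic; equalities ("ties") count as extreme. By default
#' the plain proportion `b/m` is reported; with `add_one = TRUE` the
#' `(b+1)/(m+1)` convention is used instead, which guarantees a strictly
#' positive p-value in Monte-Carlo mode.
#'
#' @param observed Observed statistic (scalar, on the testing scale).
#' @param null Null distribution vector. For `tail = "two"` this must already
#'   be on the absolute (or max-absolute) scale; `observed` is compared via
#'   its magnitude.
#' @param tail `"two"`, `"right"` or `"left"`.
#' @param add_one Use the `(b+1)/(m+1)` convention (default `FALSE`).
#' @return A p-value in `[0, 1]` lying on the grid `{0, 1/m, ..., 1}`
#'   (or the add-one analogue).
#' @export
p_from_distribution <- function(observed, null,
                                tail = c("two", "right", "left"),
                                add_one = FALSE) {
  tail <- match.arg(tail)
  if (length(null) == 0) stop("empty null distribution", call. = FALSE)
  if (is.na(observed)) return(NA_real_)
  # ties count as extreme; equality is detected up to a small relative
  # tolerance so that analytically tied rearrangements, recomputed through
  # different floating-point paths, are still recognised as ties
  eps <- 1e-8 * (1 + abs(observed))
  b <- switch(tail,
    two = sum(null >= abs(observed) - eps),
    right = sum(null >= observed - eps),
    left = sum(null <= observed + eps))
  m <- length(null)
  if (add_one) (b + 1) / (m + 1) else b / m
}

#' Confidence interval from a permutation distribution
#'
#' For statistics with a standard-error scale (mean and mean-difference
#' tests), the two-tailed interval is `estimate +/- c * se` where `c` is the
#' `(1 - alpha)` percentile of the (max-corrected, if applicable) absolute
#' null distribution of the standardised statistic; one-tailed intervals take
#' the corresponding signed percentile and leave the other side infinite.
#' Max-corrected intervals are therefore simultaneous intervals and at least
#' as wide as their uncorrected counterparts. For scale-free statistics
#' (`se = NA`, e.g. correlations) the signed percentiles of the null are
#' re-centred at the observed statistic.
#'
#' @param estimate Point estimate on the reporting scale.
#' @param se Standard error used for scaling, or `NA` for the re-centred
#'   construction.
#' @param null Null distribution: signed values for the re-centred and
#'   one-tailed constructions; for `tail = "two"` with an `se`, the absolute
#'   (or max-absolute) distribution.
#' @param alpha Significance level in (0, 1); `alpha = 0.05` uses the 2.5 and
#'   97.5 percentiles in the signed construction.
#' @param tail `"two"`, `"right"` or `"left"`.
#' @return `c(lower, upper)`.
#' @export
ci_from_distribution <- function(estimate, se, null, alpha = 0.05,
                                 tail = c("two", "right", "left")) {
  tail <- match.arg(tail)
  check_alpha(alpha)
  if (is.na(estimate)) return(c(NA_real_, NA_real_))
  if (is.na(se)) {
    # re-centred signed-percentile interval on the statistic's own scale
    out <- switch(tail,
      two = {
        c_ <- stats::quantile(abs(null), 1 - alpha, names = FALSE, type = 7)
        c(estimate - c_, estimate + c_)
      },
      right = c(estimate - stats::quantile(null, 1 - alpha, names = FALSE), Inf),
      left = c(-Inf, estimate - stats::quantile(null, alpha, names = FALSE)))
    return(out)
  }
  switch(tail,
    two = {
      c_ <- stats::quantile(null, 1 - alpha, names = FALSE, type = 7)
      c(estimate - c_ * se, estimate + c_ * se)
    },
    right = {
      c_ <- stats::quantile(null, 1 - alpha, names = FALSE, type = 7)
      c(estimate - c_ * se, Inf)
    },
    left = {
      c_ <- stats::quantile(null, alpha, names = FALSE, type = 7)
      c(-Inf, estimate - c_ * se)
    })
}

# ---- result assembly --------------------------------------------------------

# Assemble a perm_test object from an observed bundle and resampled statistics.
# `scale` maps the testing scale back to the reporting scale for CIs:
#   "se"       estimate +/- c * se            (t, Z tests)
#   "recenter" statistic +/- signed pctiles   (correlations; clipped to [-1,1])
#   "ratio"    exp(log F +/- c)               (variance ratio)
#   "none"     no CI (ANOVA F)
make_perm_test <- function(test, bundle, resamp, tail, correction, alpha,
                           add_one, scale, meta, clip = NULL) {
  p_vars <- length(bundle$statistic)
  ok <- !bundle$undefined
  if (!any(ok))
    stop("all variables are undefined for this test", call. = FALSE)
  obs_null_stat <- bundle$null_stat %||% bundle$statistic
  nd <- build_null_distribution(resamp[, ok, drop = FALSE], tail, correction)
  # signed nulls for one-tailed / re-centred CI constructions
  p <- ci_lo <- ci_hi <- rep(NA_real_, p_vars)
  col_of <- cumsum(ok)
  for (j in seq_len(p_vars)) {
    if (!ok[j]) next
    null_j <- if (nd$shared) nd$null else nd$null[, col_of[j]]
    p[j] <- p_from_distribution(obs_null_stat[j], null_j, tail, add_one)
    ci <- switch(scale,
      se = ci_from_distribution(bundle$estimate[j], bundle$se[j], null_j,
                                alpha, tail),
      recenter = ci_from_distribution(bundle$statistic[j], NA_real_,
                                      if (nd$shared) nd$null else resamp[, j],
                                      alpha, tail),
      ratio = {
        logci <- ci_from_distribution(log(bundle$statistic[j]), 1, null_j,
                                      alpha, tail)
        exp(logci)
      },
      none = c(NA_real_, NA_real_))
    ci_lo[j] <- ci[1]; ci_hi[j] <- ci[2]
  }
  if (!is.null(clip)) {
    ci_lo <- pmax(ci_lo, clip[1]); ci_hi <- pmin(ci_hi, clip[2])
  }
  var_names <- meta$var_names %||% paste0("V", seq_len(p_vars))
  tab <- data.frame(variable = var_names,
                    statistic = unname(bundle$statistic),
                    df = unname(bundle$df),
                    stringsAsFactors = FALSE)
  if (!is.null(bundle$df2)) tab$df2 <- unname(bundle$df2)
  tab$estimate <- unname(bundle$estimate)
  tab$se <- unname(bundle$se)
  tab$p <- p
  tab$ci_lower <- ci_lo
  tab$ci_upper <- ci_hi
  structure(list(test = test, table = tab,
                 null_distribution = nd$null, shared_null = nd$shared,
                 correction = correction, tail = tail, alpha = alpha,
                 n_resamples = nrow(resamp), exhaustive = meta$exhaustive %||% FALSE,
                 seed = meta$seed, add_one = add_one,
                 groups = group_summary_table(bundle, var_names),
                 undefined = bundle$undefined),
            class = "perm_test")
}

group_summary_table <- function(bundle, var_names) {
  if (is.null(bundle$groups) || length(bundle$groups) == 0) return(NULL)
  out <- lapply(seq_along(bundle$groups), function(g) {
    m <- bundle$groups[[g]]
    data.frame(group = names(bundle$groups)[g] %||% as.character(g),
               variable = var_names, n = m$n, M = m$mean, SD = m$sd,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' @export
print.perm_test <- function(x, ...) {
  cat(sprintf("Permutation %s (tail = %s, correction = %s)\n",
              x$test, x$tail, x$correction))
  cat(sprintf("%s resamples%s, seed = %s, alpha = %g\n",
              format(x$n_resamples, big.mark = ","),
              if (x$exhaustive) " (exhaustive)" else "", x$seed, x$alpha))
  tab <- x$table
  num <- vapply(tab, is.numeric, logical(1))
  tab[num] <- lapply(tab[num], function(v) signif(v, 4))
  print(utils::head(tab, 25), row.names = FALSE)
  if (nrow(x$table) > 25) cat(sprintf("... %d more rows\n", nrow(x$table) - 25))
  invisible(x)
}

# Resolve 'auto' correction: max whenever more than one variable is tested.
resolve_correction <- function(correction, n_vars) {
  correction <- match.arg(correction, c("auto", "max", "none"))
  if (correction == "auto") {
    if (n_vars > 1) "max" else "none"
  } else correction
}
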