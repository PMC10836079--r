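# Resampling engine: reproducible permutation, sign-flip and bootstrap index
# streams shared across all variables of a multivariate dataset.

#' Describe a resampling scheme
#'
#' A resampling plan fixes the scheme, the number of resamples, the RNG seed
#' and whether the scheme should be enumerated exhaustively. A single plan is
#' generated once per analysis and its index table is shared by every variable
#' of the data matrix, which both preserves the dependence structure across
#' variables and makes multivariate runs cheap.
#'
#' @param scheme One of `"label_permutation"` (reassign observations to
#'   groups; two-sample and ANOVA designs), `"sign_flip"` (flip the sign of
#'   deviations about the hypothesised mean; one-sample and paired designs),
#'   `"row_permutation"` (permute whole rows of the second sample;
#'   correlation designs) or `"bootstrap"` (draw rows with replacement;
#'   effect-size confidence intervals).
#' @param n_resamples Number of Monte-Carlo resamples (default 10000, which
#'   gives p-values reliable to a few parts in a thousand).
#' @param seed Non-negative integer seed; identical plans yield bit-identical
#'   index tables.
#' @param exhaustive `TRUE` to enumerate every distinct rearrangement, `FALSE`
#'   to force Monte-Carlo, or `NA` (default) to enumerate automatically
#'   whenever the exact count does not exceed `n_resamples`.
#' @return An object of class `"resampling_plan"`.
#' @examples
#' resampling_plan("sign_flip", n_resamples = 5000, seed = 1)
#' @export
resampling_plan <- function(scheme = c("label_permutation", "sign_flip",
                                       "row_permutation", "bootstrap"),
                            n_resamples = 10000, seed = 42,
                            exhaustive = NA) {
  scheme <- match.arg(scheme)
  n_resamples <- check_count(n_resamples, "n_resamples")
  if (!is.numeric(seed) || length(seed) != 1 || is.na(seed) || seed < 0)
    stop("'seed' must be a single non-negative integer", call. = FALSE)
  if (!is.logical(exhaustive) || length(exhaustive) != 1)
    stop("'exhaustive' must be TRUE, FALSE or NA", call. = FALSE)
  if (isTRUE(exhaustive) && scheme == "bootstrap")
    stop("exhaustive enumeration is not defined for the bootstrap", call. = FALSE)
  structure(list(scheme = scheme, n_resamples = n_resamples,
                 seed = as.integer(seed), exhaustive = exhaustive),
            class = "resampling_plan")
}

#' @export
print.resampling_plan <- function(x, ...) {
  cat(sprintf("Resampling plan: %s, n_resamples = %d, seed = %d, exhaustive = %s\n",
              x$scheme, x$n_resamples, x$seed, as.character(x$exhaustive)))
  invisible(x)
}

#' Count distinct rearrangements of a resampling scheme
#'
#' Number of distinct resamples available to an exhaustive enumeration:
#' the multinomial coefficient for group-label permutation, `2^n` for sign
#' flips and `n!` for row permutations. Counts above `2^63 - 1` are reported
#' as `Inf` (an explicit overflow sentinel) rather than wrapping.
#'
#' @param scheme Scheme name (see [resampling_plan()]); the bootstrap has no
#'   meaningful distinct count and is an error.
#' @param sizes Integer vector of sample sizes: group sizes for
#'   `label_permutation`, a single `n` for `sign_flip`/`row_permutation`.
#' @return A double: the exact count, or `Inf` on overflow.
#' @examples
#' count_exact_resamples("label_permutation", c(3, 3)) # choose(6, 3) = 20
#' count_exact_resamples("sign_flip", 12)              # 2^12 = 4096
#' @export
count_exact_resamples <- function(scheme, sizes) {
  if (length(sizes) == 0 || any(sizes < 1) || any(sizes != floor(sizes)))
    stop("'sizes' must be a nonempty vector of positive integers", call. = FALSE)
  log2count <- switch(scheme,
    label_permutation = {
      n <- sum(sizes)
      (lgamma(n + 1) - sum(lgamma(sizes + 1))) / log(2)
    },
    sign_flip = sum(sizes),
    row_permutation = lgamma(sum(sizes) + 1) / log(2),
    bootstrap = stop("distinct-resample count is not meaningful for the bootstrap",
                     call. = FALSE),
    stop(sprintf("unsupported scheme '%s'", scheme), call. = FALSE)
  )
  if (log2count > 63) return(Inf)
  round(2^log2count)
}

# Decide whether a plan should run exhaustively for the given sizes.
resolve_exhaustive <- function(plan, sizes) {
  if (plan$scheme == "bootstrap") return(list(exhaustive = FALSE, m = plan$n_resamples))
  count <- count_exact_resamples(plan$scheme, sizes)
  if (isTRUE(plan$exhaustive)) {
    if (count > .EXHAUSTIVE_CAP)
      stop(sprintf(paste0("exhaustive enumeration needs %s resamples, above the ",
                          "cap of %d; use Monte-Carlo (exhaustive = FALSE)"),
                   format(count, big.mark = ","), as.integer(.EXHAUSTIVE_CAP)),
           call. = FALSE)
    return(list(exhaustive = TRUE, m = as.integer(count)))
  }
  if (is.na(plan$exhaustive) && count <= plan$n_resamples)
    return(list(exhaustive = TRUE, m = as.integer(count)))
  list(exhaustive = FALSE, m = plan$n_resamples)
}

# All permutations of 1..n as an n! x n matrix (small n only).
all_row_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_row_permutations(n - 1L)
  out <- vector("list", n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out[[k]] <- cbind(k, matrix(rest[sub], nrow(sub)))
  }
  do.call(rbind, out)
}

#' Generate group-label permutation indices
#'
#' Each row of the returned table is a permutation of `1..n` whose first
#' `group_sizes[1]` entries are the observations assigned to group 1, the next
#' `group_sizes[2]` to group 2, and so on. In exhaustive mode (two groups) the
#' rows enumerate every distinct group assignment exactly once; in Monte-Carlo
#' mode they are independent uniform permutations. The identity assignment is
#' not implicitly prepended.
#'
#' @param plan A [resampling_plan()] with scheme `"label_permutation"`.
#' @param group_sizes Integer vector of per-group sample sizes (each >= 2).
#' @return Integer matrix, `m` rows by `sum(group_sizes)` columns, with
#'   attribute `"exhaustive"`.
#' @examples
#' p <- resampling_plan("label_permutation", n_resamples = 100, seed = 7)
#' generate_label_permutations(p, c(2, 2)) # all choose(4,2) = 6 assignments
#' @export
generate_label_permutations <- function(plan, group_sizes) {
  stopifnot(inherits(plan, "resampling_plan"))
  if (plan$scheme != "label_permutation")
    stop("plan scheme must be 'label_permutation'", call. = FALSE)
  if (any(group_sizes < 2))
    stop("every group must have at least 2 observations", call. = FALSE)
  n <- sum(group_sizes)
  res <- resolve_exhaustive(plan, group_sizes)
  if (res$exhaustive && length(group_sizes) == 2) {
    sel <- utils::combn(n, group_sizes[1])
    idx <- t(apply(sel, 2, function(g) c(g, setdiff(seq_len(n), g))))
    storage.mode(idx) <- "integer"
  } else {
    idx <- with_seed(plan$seed, {
      t(replicate(res$m, sample.int(n)))
    })
    res$exhaustive <- FALSE  # k > 2 exhaustive not enumerated
  }
  structure(idx, exhaustive = res$exhaustive)
}

#' Generate sign-flip tables
#'
#' Rows of +/-1 used to flip deviations about the hypothesised mean in
#' one-sample and paired designs. Exhaustive mode enumerates all `2^n` rows;
#' Monte-Carlo rows are independent fair coins.
#'
#' @param plan A [resampling_plan()] with scheme `"sign_flip"`.
#' @param n Number of observations (>= 2).
#' @return Numeric matrix of +/-1, `m` rows by `n` columns, with attribute
#'   `"exhaustive"`.
#' @export
generate_sign_flips <- function(plan, n) {
  stopifnot(inherits(plan, "resampling_plan"))
  if (plan$scheme != "sign_flip")
    stop("plan scheme must be 'sign_flip'", call. = FALSE)
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  res <- resolve_exhaustive(plan, n)
  if (res$exhaustive) {
    flips <- as.matrix(expand.grid(rep(list(c(1, -1)), n), KEEP.OUT.ATTRS = FALSE))
    dimnames(flips) <- NULL
  } else {
    flips <- with_seed(plan$seed, {
      matrix(sample(c(-1, 1), res$m * n, replace = TRUE), res$m, n)
    })
  }
  structure(flips, exhaustive = res$exhaustive)
}

#' Generate row-permutation indices
#'
#' Whole-row permutations of `1..n`, used to break the pairing between two
#' matrices in correlation tests. Exhaustive mode enumerates all `n!` orders
#' (only feasible for small `n`).
#'
#' @param plan A [resampling_plan()] with scheme `"row_permutation"`.
#' @param n Number of observations (>= 2).
#' @return Integer matrix, `m` rows by `n` columns, with attribute
#'   `"exhaustive"`.
#' @export
generate_row_permutations <- function(plan, n) {
  stopifnot(inherits(plan, "resampling_plan"))
  if (plan$scheme != "row_permutation")
    stop("plan scheme must be 'row_permutation'", call. = FALSE)
  if (n < 2) stop("'n' must be at least 2", call. = FALSE)
  res <- resolve_exhaustive(plan, n)
  if (res$exhaustive) {
    idx <- all_row_permutations(as.integer(n))
  } else {
    idx <- with_seed(plan$seed, t(replicate(res$m, sample.int(n))))
  }
  structure(idx, exhaustive = res$exhaustive)
}

#' Generate bootstrap index tables
#'
#' Rows of indices drawn uniformly with replacement from `1..n`. On each
#' bootstrap replicate one shared index row is applied to every variable of
#' the same sample, preserving the dependence between variables — the
#' contract that makes the multivariate bootstrap efficient and valid for
#' correlated outcome measures.
#'
#' @param plan A [resampling_plan()] with scheme `"bootstrap"`.
#' @param n Number of observations (>= 2).
#' @return Integer matrix, `n_resamples` rows by `n` columns.
#' @export
generate_bootstrap_indices <- function(plan, n) {
  stopifnot(inherits(plan, "resampling_plan"))
  if (plan$scheme != "bootstrap")
    stop("plan scheme must be 'bootstrap'", call. = FALSE)
  if (n < 2) stop("'n' must be at least 2 for the bootstrap", call. = FALSE)
  with_seed(plan$seed, {
    matrix(sample.int(n, plan$n_resamples * n, replace = TRUE),
           plan$n_resamples, n)
  })
}
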