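# Synthetic data generator: two-sample Gaussian-shift designs (the package's
# reference worked example), global/correlated nulls, and ordinal data for
# dominance statistics.

#' Specification for a synthetic two-sample dataset
#'
#' Defaults describe the package's reference design: two independent samples
#' of 30 observations by 20 standard-normal variables, with the first 10
#' variables of the second sample shifted by -1 — i.e. ten true effects of
#' one pooled SD and ten true nulls.
#'
#' @param n_obs Observations per sample (default 30).
#' @param n_vars Variables per sample (default 20).
#' @param shifted_vars Indices of the variables of `y` that receive the mean
#'   shift; defaults to the first half of the variables, at most ten
#'   (`1:10` under the default dimensions).
#' @param shift Mean shift added to the shifted variables of `y`
#'   (default -1).
#' @param sigma Common SD of every variable (default 1).
#' @param rho Equicorrelation between variables (default 0); must satisfy
#'   `rho >= -1/(n_vars - 1)` for a positive-semidefinite correlation.
#' @param seed RNG seed (default 42).
#' @param kind `"gaussian_shift"` (default), `"global_null"` (shift forced to
#'   0), or `"correlated_null"` (shift 0, equicorrelated variables).
#' @return A list of class `"synth_spec"`.
#' @export
synth_spec <- function(n_obs = 30, n_vars = 20, shifted_vars = NULL,
                       shift = -1, sigma = 1, rho = 0, seed = 42,
                       kind = c("gaussian_shift", "global_null",
                                "correlated_null")) {
  kind <- match.arg(kind)
  n_obs <- check_count(n_obs, "n_obs")
  n_vars <- check_count(n_vars, "n_vars")
  # default: shift the first half of the variables, at most ten of them
  if (is.null(shifted_vars)) shifted_vars <- seq_len(min(10, ceiling(n_vars / 2)))
  if (length(shifted_vars) > 0 &&
      (any(shifted_vars < 1) || any(shifted_vars > n_vars)))
    stop("'shifted_vars' must index variables 1..n_vars", call. = FALSE)
  if (sigma <= 0) stop("'sigma' must be positive", call. = FALSE)
  if (n_vars > 1 && (rho < -1 / (n_vars - 1) || rho > 1))
    stop(sprintf("'rho' must lie in [%.4f, 1] for %d variables",
                 -1 / (n_vars - 1), n_vars), call. = FALSE)
  if (kind != "gaussian_shift") shift <- 0
  structure(list(n_obs = n_obs, n_vars = n_vars,
                 shifted_vars = as.integer(shifted_vars), shift = shift,
                 sigma = sigma, rho = rho, seed = as.integer(seed),
                 kind = kind),
            class = "synth_spec")
}

# n x p matrix with equicorrelation rho and SD sigma
equicorr_normal <- function(n, p, rho, sigma) {
  e <- matrix(stats::rnorm(n * p), n, p)
  if (rho == 0 || p == 1) return(sigma * e)
  # factor form for rho >= 0; general case via Cholesky of the equicorrelation
  if (rho >= 0) {
    g <- stats::rnorm(n)
    return(sigma * (sqrt(rho) * g + sqrt(1 - rho) * e))
  }
  cmat <- matrix(rho, p, p); diag(cmat) <- 1
  sigma * (e %*% chol(cmat))
}

#' Generate a synthetic two-sample dataset
#'
#' Draws two independent Gaussian samples according to a [synth_spec()]:
#' `x` has mean 0 in every variable; `y` is identical except that the
#' variables listed in `shifted_vars` have mean `shift`. Fixed seeds give
#' reproducible matrices.
#'
#' @param spec A [synth_spec()].
#' @return List with matrices `x` and `y` (`n_obs` x `n_vars`, named
#'   `V1..Vp`) and the `spec`.
#' @examples
#' syn <- synth_two_sample(synth_spec())
#' round(colMeans(syn$y)[1:3], 2)  # shifted variables sit near -1
#' @export
synth_two_sample <- function(spec = synth_spec()) {
  stopifnot(inherits(spec, "synth_spec"))
  with_seed(spec$seed, {
    x <- equicorr_normal(spec$n_obs, spec$n_vars, spec$rho, spec$sigma)
    y <- equicorr_normal(spec$n_obs, spec$n_vars, spec$rho, spec$sigma)
    if (length(spec$shifted_vars) > 0 && spec$shift != 0)
      y[, spec$shifted_vars] <- y[, spec$shifted_vars] + spec$shift
    colnames(x) <- colnames(y) <- paste0("V", seq_len(spec$n_vars))
    list(x = x, y = y, spec = spec)
  })
}

#' Generate ordinal two-sample data
#'
#' Discretises the latent Gaussian design of [synth_two_sample()] into
#' `n_levels` ordered categories (equiprobable cuts of the null marginal),
#' producing integer-valued data with ties — the natural fixture for Cliff's
#' d and other rank-based procedures.
#'
#' @param spec A [synth_spec()].
#' @param n_levels Number of ordinal levels (>= 2).
#' @return List with integer matrices `x` and `y` (levels `1..n_levels`) and
#'   the `spec`.
#' @export
synth_ordinal <- function(spec = synth_spec(), n_levels = 5) {
  stopifnot(inherits(spec, "synth_spec"))
  if (n_levels < 2) stop("'n_levels' must be at least 2", call. = FALSE)
  latent <- synth_two_sample(spec)
  cuts <- stats::qnorm(seq_len(n_levels - 1) / n_levels, sd = spec$sigma)
  bins <- c(-Inf, cuts, Inf)
  disc <- function(m) {
    out <- matrix(as.integer(cut(m, bins, labels = FALSE)),
                  nrow(m), ncol(m))
    colnames(out) <- colnames(m)
    out
  }
  list(x = disc(latent$x), y = disc(latent$y), spec = spec,
       n_levels = as.integer(n_levels))
}
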