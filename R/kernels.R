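# Vectorised test-statistic kernels. Each kernel is computed identically on
# the observed data and on every resample; the observed path returns a
# "statistic bundle" (statistic, df, se, estimate, group summaries, undefined
# flags), while resample_* counterparts return an n_resamples x n_vars matrix
# on the testing scale.

.ZERO_TOL <- .Machine$double.eps^0.75

# ---- observed kernels -------------------------------------------------------

kernel_t2 <- function(x, y, variance_mode = c("pooled", "unpooled")) {
  variance_mode <- match.arg(variance_mode)
  mx <- col_moments(x); my <- col_moments(y)
  if (any(mx$n < 2) || any(my$n < 2))
    stop("each variable needs at least 2 non-missing observations per group",
         call. = FALSE)
  est <- mx$mean - my$mean
  if (variance_mode == "pooled") {
    df <- mx$n + my$n - 2
    sp2 <- ((mx$n - 1) * mx$var + (my$n - 1) * my$var) / df
    se <- sqrt(sp2 * (1 / mx$n + 1 / my$n))
  } else {
    a <- mx$var / mx$n; b <- my$var / my$n
    se <- sqrt(a + b)
    df <- (a + b)^2 / (a^2 / (mx$n - 1) + b^2 / (my$n - 1))
  }
  undefined <- se <= .ZERO_TOL | !is.finite(se)
  stat <- ifelse(undefined, NA_real_, est / se)
  list(statistic = stat, df = df, se = se, estimate = est,
       undefined = undefined,
       groups = list(x = mx, y = my))
}

kernel_t1 <- function(x, mu = 0) {
  m <- col_moments(x)
  if (any(m$n < 2))
    stop("each variable needs at least 2 non-missing observations", call. = FALSE)
  est <- m$mean - mu
  se <- m$sd / sqrt(m$n)
  undefined <- se <= .ZERO_TOL | !is.finite(se)
  stat <- ifelse(undefined, NA_real_, est / se)
  list(statistic = stat, df = m$n - 1, se = se, estimate = est,
       undefined = undefined, groups = list(x = m))
}

kernel_z <- function(x, mu = 0, sigma) {
  if (!is.numeric(sigma) || any(sigma <= 0))
    stop("'sigma' must be positive", call. = FALSE)
  m <- col_moments(x)
  est <- m$mean - mu
  se <- sigma / sqrt(m$n)
  stat <- est / se
  list(statistic = stat, df = rep(NA_real_, length(stat)), se = se,
       estimate = est, undefined = rep(FALSE, length(stat)),
       groups = list(x = m))
}

kernel_f2 <- function(x, y) {
  mx <- col_moments(x); my <- col_moments(y)
  f <- mx$var / my$var
  undefined <- mx$var <= .ZERO_TOL | my$var <= .ZERO_TOL |
    !is.finite(mx$var) | !is.finite(my$var)
  f[undefined] <- NA_real_
  list(statistic = f, df = mx$n - 1, df2 = my$n - 1,
       se = rep(NA_real_, length(f)), estimate = f,
       null_stat = log(f),  # symmetric testing scale: two-tailed uses |log F|
       undefined = undefined, groups = list(x = mx, y = my))
}

# method-specific column transform for correlation kernels
corr_transform <- function(m, method) {
  switch(method,
    pearson = m,
    spearman = apply(m, 2, rank, ties.method = "average"),
    rankit = apply(m, 2, function(col) {
      stats::qnorm((rank(col, ties.method = "average") - 0.5) / length(col))
    })
  )
}

# standardise columns to mean 0, unit sum of squares/(n-1)
standardise_cols <- function(m) {
  mu <- colMeans(m)
  cent <- sweep(m, 2, mu)
  s <- sqrt(colSums(cent^2) / (nrow(m) - 1))
  list(z = sweep(cent, 2, ifelse(s > 0, s, 1), "/"), sd = s)
}

kernel_corr <- function(x, y, method = c("pearson", "spearman", "rankit")) {
  method <- match.arg(method)
  xt <- corr_transform(x, method)
  yt <- corr_transform(y, method)
  sx <- standardise_cols(xt); sy <- standardise_cols(yt)
  n <- nrow(x)
  r <- unname(colSums(sx$z * sy$z) / (n - 1))
  undefined <- sx$sd <= .ZERO_TOL | sy$sd <= .ZERO_TOL
  r[undefined] <- NA_real_
  r <- pmin(1, pmax(-1, r))
  list(statistic = r, df = rep(n - 2, length(r)),
       se = rep(NA_real_, length(r)), estimate = r, undefined = undefined,
       groups = list(x = col_moments(x), y = col_moments(y)),
       zx = sx$z, zy = sy$z)
}

kernel_anova1 <- function(groups) {
  k <- length(groups)
  moms <- lapply(groups, col_moments)
  N <- Reduce(`+`, lapply(moms, `[[`, "n"))
  gsum <- Reduce(`+`, lapply(moms, function(m) m$n * m$mean))
  grand <- gsum / N
  ssb <- Reduce(`+`, lapply(moms, function(m) m$n * (m$mean - grand)^2))
  ssw <- Reduce(`+`, lapply(moms, function(m) (m$n - 1) * m$var))
  msb <- ssb / (k - 1)
  msw <- ssw / (N - k)
  undefined <- msw <= .ZERO_TOL & ssb <= .ZERO_TOL
  f <- ifelse(ssb <= .ZERO_TOL, 0, msb / msw)
  f[undefined] <- NA_real_
  list(statistic = f, df = rep(k - 1, length(f)), df2 = N - k,
       se = rep(NA_real_, length(f)), estimate = f, undefined = undefined,
       groups = moms)
}

# Balanced two-way ANOVA on a single response vector; returns the three
# effect F statistics (A, B, A:B) from the standard decomposition.
anova2_f <- function(y, fa, fb, cell, na_, nb_, r_) {
  cell_sum <- rowsum(y, cell, reorder = TRUE)          # (na*nb) x 1
  a_sum <- rowsum(y, fa, reorder = TRUE)
  b_sum <- rowsum(y, fb, reorder = TRUE)
  n <- length(y)
  g2 <- sum(y)^2 / n
  ssa <- sum(a_sum^2) / (nb_ * r_) - g2
  ssb <- sum(b_sum^2) / (na_ * r_) - g2
  sscell <- sum(cell_sum^2) / r_ - g2
  ssab <- sscell - ssa - ssb
  sse <- sum(y^2) - g2 - sscell
  dfa <- na_ - 1; dfb <- nb_ - 1; dfab <- dfa * dfb; dfe <- n - na_ * nb_
  mse <- sse / dfe
  fs <- c(A = ssa / dfa, B = ssb / dfb, `A:B` = ssab / dfab)
  ss <- c(ssa, ssb, ssab)
  out <- ifelse(ss <= .ZERO_TOL, 0, fs / mse)
  names(out) <- c("A", "B", "A:B")
  out
}

kernel_anova2 <- function(y, fa, fb) {
  fa <- as.factor(fa); fb <- as.factor(fb)
  if (anyNA(y)) stop("two-way ANOVA requires complete responses", call. = FALSE)
  tab <- table(fa, fb)
  if (length(unique(as.vector(tab))) != 1)
    stop("two-way ANOVA requires a balanced design (equal cell counts)",
         call. = FALSE)
  r_ <- as.vector(tab)[1]
  if (r_ < 2) stop("at least 2 replicates per cell are required", call. = FALSE)
  na_ <- nlevels(fa); nb_ <- nlevels(fb)
  cell <- interaction(fa, fb, drop = FALSE)
  f <- anova2_f(y, fa, fb, cell, na_, nb_, r_)
  n <- length(y)
  list(statistic = f,
       df = c(na_ - 1, nb_ - 1, (na_ - 1) * (nb_ - 1)),
       df2 = rep(n - na_ * nb_, 3),
       se = rep(NA_real_, 3), estimate = f,
       undefined = rep(FALSE, 3),
       groups = list(), meta = list(fa = fa, fb = fb, cell = cell,
                                    na_ = na_, nb_ = nb_, r_ = r_))
}

# ---- resampled kernels ------------------------------------------------------

# Two-group moments for every resample row via indicator-matrix algebra.
# z: stacked (n1+n2) x p data (NA allowed); perms: m x n index rows whose
# first n1 entries form group 1. Returns list of m x p matrices.
resample_two_group_moments <- function(z, perms, n1) {
  present <- !is.na(z)
  z0 <- z; z0[!present] <- 0
  # centre columns globally (t and log-F are shift-invariant; improves stability)
  z0 <- sweep(z0, 2, colSums(z0) / colSums(present))
  z0[!present] <- 0
  tot_n <- colSums(present); tot_s <- colSums(z0); tot_q <- colSums(z0^2)
  m <- nrow(perms); n <- ncol(perms); p <- ncol(z)
  cnt1 <- s1 <- q1 <- matrix(0, m, p)
  for (rows in chunk_rows(m)) {
    a <- indicator_matrix(perms[rows, seq_len(n1), drop = FALSE], n)
    cnt1[rows, ] <- a %*% present
    s1[rows, ] <- a %*% z0
    q1[rows, ] <- a %*% (z0^2)
  }
  cnt2 <- sweep(-cnt1, 2, tot_n, `+`)
  s2 <- sweep(-s1, 2, tot_s, `+`)
  q2 <- sweep(-q1, 2, tot_q, `+`)
  mean1 <- s1 / cnt1; mean2 <- s2 / cnt2
  v1 <- (q1 - cnt1 * mean1^2) / (cnt1 - 1)
  v2 <- (q2 - cnt2 * mean2^2) / (cnt2 - 1)
  v1[v1 < 0] <- 0; v2[v2 < 0] <- 0
  list(n1 = cnt1, n2 = cnt2, mean1 = mean1, mean2 = mean2, v1 = v1, v2 = v2)
}

resample_stats_t2 <- function(z, perms, n1, variance_mode) {
  mm <- resample_two_group_moments(z, perms, n1)
  if (variance_mode == "pooled") {
    sp2 <- ((mm$n1 - 1) * mm$v1 + (mm$n2 - 1) * mm$v2) / (mm$n1 + mm$n2 - 2)
    den <- sqrt(sp2 * (1 / mm$n1 + 1 / mm$n2))
  } else {
    den <- sqrt(mm$v1 / mm$n1 + mm$v2 / mm$n2)
  }
  (mm$mean1 - mm$mean2) / den
}

resample_stats_logF <- function(z, perms, n1) {
  mm <- resample_two_group_moments(z, perms, n1)
  log(mm$v1) - log(mm$v2)
}

# Sign-flip t statistics: d = deviations about mu (n x p), flips m x n.
resample_stats_t1 <- function(d, flips) {
  present <- !is.na(d)
  d0 <- d; d0[!present] <- 0
  nvec <- colSums(present)
  ssq <- colSums(d0^2)
  s <- flips %*% d0                       # m x p sums (sign pattern applied)
  meanr <- sweep(s, 2, nvec, "/")
  # var_r = (ssq - n * mean_r^2) / (n - 1): squares are flip-invariant
  varr <- sweep(-sweep(meanr^2, 2, nvec, `*`), 2, ssq, `+`)
  varr <- sweep(varr, 2, pmax(nvec - 1, 1), "/")
  varr[varr < 0] <- 0
  meanr / sqrt(sweep(varr, 2, nvec, "/"))
}

resample_stats_z <- function(d, flips, sigma) {
  present <- !is.na(d)
  d0 <- d; d0[!present] <- 0
  nvec <- colSums(present)
  meanr <- sweep(flips %*% d0, 2, nvec, "/")
  sweep(meanr, 2, sigma / sqrt(nvec), "/")
}

# Correlation under row permutation of y; zx, zy standardised columns.
resample_stats_corr <- function(zx, zy, perms) {
  m <- nrow(perms); p <- ncol(zx); n <- nrow(zx)
  out <- matrix(0, m, p)
  for (i in seq_len(m)) {
    out[i, ] <- colSums(zx * zy[perms[i, ], , drop = FALSE])
  }
  out / (n - 1)
}

# One-way ANOVA F under label permutation for k groups.
resample_stats_F1 <- function(z, perms, sizes) {
  k <- length(sizes)
  present <- !is.na(z)
  z0 <- z; z0[!present] <- 0
  z0 <- sweep(z0, 2, colSums(z0) / colSums(present))
  z0[!present] <- 0
  tot_q <- colSums(z0^2); tot_s <- colSums(z0); tot_n <- colSums(present)
  m <- nrow(perms); p <- ncol(z); n <- ncol(perms)
  ssb <- matrix(0, m, p)
  cum <- c(0, cumsum(sizes))
  for (rows in chunk_rows(m)) {
    ssb_c <- matrix(0, length(rows), p)
    sum_all <- matrix(0, length(rows), p)
    cnt_all <- matrix(0, length(rows), p)
    for (g in seq_len(k)) {
      cols <- (cum[g] + 1):cum[g + 1]
      a <- indicator_matrix(perms[rows, cols, drop = FALSE], n)
      sg <- a %*% z0
      cg <- a %*% present
      ssb_c <- ssb_c + sg^2 / cg
      sum_all <- sum_all + sg
      cnt_all <- cnt_all + cg
    }
    ssb[rows, ] <- ssb_c - sum_all^2 / cnt_all
  }
  sst <- sweep(matrix(0, m, p), 2, tot_q - tot_s^2 / tot_n, `+`)
  ssw <- sst - ssb
  ssw[ssw < 0] <- 0
  (ssb / (k - 1)) / (ssw / sweep(matrix(0, m, p), 2, tot_n - k, `+`))
}

# Two-way balanced ANOVA F's under unrestricted row permutation of y.
resample_stats_F2 <- function(y, perms, meta) {
  m <- nrow(perms)
  out <- matrix(0, m, 3)
  for (i in seq_len(m)) {
    out[i, ] <- anova2_f(y[perms[i, ]], meta$fa, meta$fb, meta$cell,
                         meta$na_, meta$nb_, meta$r_)
  }
  out
}
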