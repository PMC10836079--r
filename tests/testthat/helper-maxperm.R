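# Shared fixtures, built in code.

rnorm_mat <- function(n, p, seed, mean = 0, sd = 1) {
  set.seed(seed)
  matrix(rnorm(n * p, mean, sd), n, p,
         dimnames = list(NULL, paste0("V", seq_len(p))))
}

# brute-force Cliff's d over all cross-sample pairs (O(n^2) oracle)
cliffs_d_brute <- function(x, y) {
  cmp <- outer(x, y, function(a, b) sign(a - b))
  sum(cmp) / (length(x) * length(y))
}

# exhaustive two-sample pooled-t p-value by direct enumeration (oracle)
exhaustive_t2_p <- function(x, y) {
  z <- c(x, y)
  n1 <- length(x)
  sel <- utils::combn(length(z), n1)
  tstat <- function(a, b) {
    sp2 <- ((length(a) - 1) * var(a) + (length(b) - 1) * var(b)) /
      (length(a) + length(b) - 2)
    (mean(a) - mean(b)) / sqrt(sp2 * (1 / length(a) + 1 / length(b)))
  }
  obs <- abs(tstat(x, y))
  ts <- apply(sel, 2, function(g) abs(tstat(z[g], z[-g])))
  mean(ts >= obs - 1e-12)
}
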