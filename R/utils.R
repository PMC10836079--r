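# Internal helpers shared across modules.

# Hard cap on exhaustive enumeration (rows); above this Monte-Carlo is used.
.EXHAUSTIVE_CAP <- 1e6

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate `code` under a fixed seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  force(code)
}

# Coerce vector/data.frame input to a numeric observations x variables matrix
# with unique column names (the universal DataMatrix container).
as_data_matrix <- function(x, arg = "x") {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.vector(x) && is.numeric(x)) x <- matrix(x, ncol = 1)
  if (!is.matrix(x) || !is.numeric(x))
    stop(sprintf("'%s' must be a numeric matrix, data frame or vector", arg),
         call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- paste0("V", seq_len(ncol(x)))
  if (anyDuplicated(colnames(x)))
    colnames(x) <- make.unique(colnames(x))
  x
}

check_alpha <- function(alpha) {
  if (!is.numeric(alpha) || length(alpha) != 1 || alpha <= 0 || alpha >= 1)
    stop("'alpha' must be a single number in (0, 1)", call. = FALSE)
  alpha
}

check_count <- function(n, arg) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n < 1 || n != floor(n))
    stop(sprintf("'%s' must be a positive integer", arg), call. = FALSE)
  as.integer(n)
}

# Column-wise moments with per-variable listwise deletion of missing values.
col_moments <- function(m) {
  present <- !is.na(m)
  n <- unname(colSums(present))
  m0 <- m
  m0[!present] <- 0
  s <- unname(colSums(m0))
  mu <- s / n
  # centre before squaring for numerical stability
  cent <- sweep(m0, 2, mu)
  cent[!present] <- 0
  v <- unname(colSums(cent^2)) / pmax(n - 1, 1)
  v[n < 2] <- NA_real_
  list(n = n, mean = mu, sd = sqrt(v), var = v)
}

# Row-wise maximum of a matrix (NA-tolerant), used for the max null.
row_max <- function(m) do.call(pmax, c(as.data.frame(m), list(na.rm = TRUE)))
row_min <- function(m) do.call(pmin, c(as.data.frame(m), list(na.rm = TRUE)))

# Split 1..n into chunks to bound memory of indicator matrices.
chunk_rows <- function(n, size = 20000L) {
  split(seq_len(n), ceiling(seq_len(n) / size))
}

# 0/1 indicator matrix: row r selects columns idx[r, ].
indicator_matrix <- function(idx, n) {
  r <- nrow(idx)
  a <- matrix(0, r, n)
  a[cbind(rep(seq_len(r), ncol(idx)), as.vector(idx))] <- 1
  a
}
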