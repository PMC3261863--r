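# Independent brute-force oracles used across the test files.  These are
# deliberately naive (loops, enumeration, quadrature) and never call the
# package's own kernels.

# subgraph-product statistics by explicit loops over vertex tuples
brute_stats <- function(m, names) {
  diag(m) <- 0
  n <- nrow(m)
  out <- numeric(length(names))
  for (s in seq_along(names)) {
    v <- 0
    if (names[s] == "edge_sum") {
      for (i in 1:n) for (j in 1:n) if (i != j) v <- v + m[i, j]
    } else if (names[s] == "reciprocity") {
      for (i in 1:n) for (j in 1:n) if (i < j) v <- v + m[i, j] * m[j, i]
    } else if (names[s] == "transitive_triads") {
      for (i in 1:n) for (j in 1:n) for (k in 1:n)
        if (i != j && j != k && i != k)
          v <- v + m[i, j] * m[j, k] * m[i, k]
    } else if (names[s] == "cyclic_triads") {
      # both directed 3-cycles per unordered triple
      if (n >= 3) {
        trip <- utils::combn(n, 3)
        for (t in seq_len(ncol(trip))) {
          i <- trip[1, t]; j <- trip[2, t]; k <- trip[3, t]
          v <- v + m[i, j] * m[j, k] * m[k, i] +
               m[i, k] * m[k, j] * m[j, i]
        }
      }
    } else if (names[s] == "in_two_stars") {
      for (j in 1:n) for (i in 1:n) for (k in 1:n)
        if (i < k && i != j && k != j) v <- v + m[i, j] * m[k, j]
    } else if (names[s] == "out_two_stars") {
      for (i in 1:n) for (j in 1:n) for (k in 1:n)
        if (j < k && j != i && k != i) v <- v + m[i, j] * m[i, k]
    } else stop("oracle: unknown statistic")
    out[s] <- v
  }
  names(out) <- names
  out
}

# finite-difference edge delta via full re-evaluation
brute_delta <- function(m, names, i, j) {
  m1 <- m; m1[i, j] <- 1
  m0 <- m; m0[i, j] <- 0
  brute_stats(m1, names) - brute_stats(m0, names)
}

# random restricted network (plain matrix, zero diagonal)
rand_restricted <- function(n) {
  m <- matrix(runif(n * n), n, n)
  diag(m) <- 0
  m
}

# inverse CDF of the truncated exponential by bisection on the analytic
# CDF; the comparison F(x) < u is done in log space for large positive a
# so the oracle also covers the overflow regime
bisect_trunc_exp <- function(a, u, tol = 1e-12) {
  log_expm1 <- function(z) if (z > 30) z + log1p(-exp(-z)) else log(expm1(z))
  below <- function(x) {
    if (a > 0) log_expm1(a * x) < log(u) + log_expm1(a)
    else expm1(a * x) / expm1(a) < u
  }
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (below(mid)) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

# truncated-exponential CDF (uniform at a = 0)
trunc_exp_cdf <- function(x, a) {
  if (abs(a) < 1e-12) return(x)
  expm1(a * x) / expm1(a)
}

# Kolmogorov-Smirnov sup distance of draws against a CDF
ks_sup <- function(draws, cdf) {
  x <- sort(draws)
  N <- length(x)
  Fx <- cdf(x)
  max(abs(Fx - seq_len(N) / N), abs(Fx - (seq_len(N) - 1) / N))
}
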