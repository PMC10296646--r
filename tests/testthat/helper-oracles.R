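# Brute-force reference implementations, written as literal loops over the
# defining formulas, kept independent of the package's vectorized paths.

oracle_mean_image <- function(flux_list, mask_list) {
  d <- dim(flux_list[[1]])
  M <- array(0, dim = d)
  cov <- matrix(0, d[1], d[2])
  for (i in seq_len(d[1])) for (j in seq_len(d[2])) {
    denom <- 0
    for (h in seq_along(flux_list)) denom <- denom + mask_list[[h]][i, j]
    cov[i, j] <- denom
    for (k in seq_len(d[3])) {
      num <- 0
      for (h in seq_along(flux_list)) {
        num <- num + mask_list[[h]][i, j] * flux_list[[h]][i, j, k]
      }
      M[i, j, k] <- if (denom > 0) num / denom else 0
    }
  }
  list(values = M, coverage = cov)
}

oracle_layer_mean <- function(values) {
  d <- dim(values)
  out <- numeric(d[3])
  for (k in seq_len(d[3])) {
    s <- 0
    for (i in seq_len(d[1])) for (j in seq_len(d[2])) s <- s + values[i, j, k]
    out[k] <- s / (d[1] * d[2])
  }
  out
}

oracle_amplitudes <- function(X) {
  d <- dim(X)
  grand <- 0
  for (n in seq_len(d[1])) for (m in seq_len(d[2])) for (r in seq_len(d[3]))
    for (k in seq_len(d[4])) grand <- grand + X[n, m, r, k]
  grand <- grand / prod(d)
  a <- array(0, dim = d[1:3])
  for (n in seq_len(d[1])) for (m in seq_len(d[2])) for (r in seq_len(d[3])) {
    s <- 0
    for (k in seq_len(d[4])) s <- s + X[n, m, r, k]
    a[n, m, r] <- (s / d[4]) / grand
  }
  a
}

oracle_layer_std <- function(X) {
  d <- dim(X)
  out <- numeric(d[4])
  for (k in seq_len(d[4])) {
    vals <- c()
    for (n in seq_len(d[1])) for (m in seq_len(d[2])) for (r in seq_len(d[3]))
      vals <- c(vals, X[n, m, r, k])
    out[k] <- sd(vals)
  }
  out
}

oracle_covariance <- function(X) {
  d <- dim(X)
  N <- d[1]; M <- d[2]; R <- d[3]; K <- d[4]
  mu <- matrix(0, M, K)
  for (m in seq_len(M)) for (k in seq_len(K)) {
    s <- 0
    for (n in seq_len(N)) for (r in seq_len(R)) s <- s + X[n, m, r, k]
    mu[m, k] <- s / (N * R)
  }
  sigma <- matrix(0, K, K)
  for (k1 in seq_len(K)) for (k2 in seq_len(K)) {
    s <- 0
    for (n in seq_len(N)) for (m in seq_len(M)) for (r in seq_len(R)) {
      s <- s + (X[n, m, r, k1] - mu[m, k1]) * (X[n, m, r, k2] - mu[m, k2])
    }
    sigma[k1, k2] <- s / (N * M * R)
  }
  sigma
}

# Exhaustive Otsu: for integer counts in 0..65535, try every cut c
# (background = value <= c) and minimize the summed within-class squared
# error; returns the first minimizing cut.
oracle_otsu_cut <- function(v) {
  tab <- tabulate(v + 1L, nbins = 65536L)
  vals <- 0:65535
  n1 <- cumsum(tab)
  s1 <- cumsum(tab * vals)
  q1 <- cumsum(tab * vals^2)
  ntot <- n1[65536]; stot <- s1[65536]; qtot <- q1[65536]
  n2 <- ntot - n1; s2 <- stot - s1; q2 <- qtot - q1
  sse <- rep(Inf, 65536)
  ok <- n1 > 0 & n2 > 0
  sse[ok] <- (q1[ok] - s1[ok]^2 / n1[ok]) + (q2[ok] - s2[ok]^2 / n2[ok])
  if (all(!is.finite(sse))) return(NA_integer_)
  which.min(sse) - 1L   # cut value c: background iff v <= c
}

oracle_choose <- function(n, k) {
  if (k == 0L || k == n) return(1)
  if (k < 0L || k > n) return(0)
  oracle_choose(n - 1L, k - 1L) + oracle_choose(n - 1L, k)
}

# exhaustive grid search over the non-negative quadrant for 2-component NNLS
oracle_nnls_grid <- function(A, b, upper, steps = 200L) {
  g <- seq(0, upper, length.out = steps + 1L)
  best <- c(0, 0); best_r <- sum(b^2)
  for (x1 in g) for (x2 in g) {
    r <- sum((A %*% c(x1, x2) - b)^2)
    if (r < best_r) { best_r <- r; best <- c(x1, x2) }
  }
  list(x = best, resid = best_r)
}
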