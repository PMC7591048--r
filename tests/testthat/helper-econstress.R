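# Shared fixtures and independent oracles for the test suite.

# Small, fast generator configuration (overridable).
small_config <- function(..., seed = 1L) {
  survey_config(n_per_country = c(IT = 600L, ES = 600L, UK = 600L),
                seed = seed, ...)
}

# Equicorrelated Gaussian items via a common factor:
# x_j = sqrt(rho) F + sqrt(1 - rho) e_j, so cor(x_i, x_j) = rho.
r_equicorrelated <- function(n, p, rho) {
  f <- rnorm(n)
  sapply(seq_len(p), function(j) sqrt(rho) * f + sqrt(1 - rho) * rnorm(n))
}

# Brute-force KMO: partial correlations computed from regression residuals
# (each pair residualized on all remaining variables), independent of the
# inverse-correlation-matrix route used by the implementation.
kmo_bruteforce <- function(m) {
  m <- scale(m)
  p <- ncol(m)
  R <- cor(m)
  Q <- diag(p)
  for (i in seq_len(p - 1)) {
    for (j in (i + 1):p) {
      others <- m[, -c(i, j), drop = FALSE]
      ri <- lm.fit(cbind(1, others), m[, i])$residuals
      rj <- lm.fit(cbind(1, others), m[, j])$residuals
      Q[i, j] <- Q[j, i] <- cor(ri, rj)
    }
  }
  off <- row(R) != col(R)
  sum(R[off]^2) / (sum(R[off]^2) + sum(Q[off]^2))
}

# Brute-force leading eigenpairs by power iteration with deflation.
eigen_power_iteration <- function(A, k = ncol(A), iters = 10000, tol = 1e-14) {
  vals <- numeric(k)
  vecs <- matrix(0, ncol(A), k)
  B <- A
  for (m in seq_len(k)) {
    v <- rep(1, ncol(A)) / sqrt(ncol(A))
    for (it in seq_len(iters)) {
      w <- B %*% v
      nw <- sqrt(sum(w^2))
      if (nw < tol) break
      w <- w / nw
      if (max(abs(w - v)) < tol || max(abs(w + v)) < tol) { v <- w; break }
      v <- w
    }
    lam <- drop(t(v) %*% B %*% v)
    vals[m] <- lam
    vecs[, m] <- v
    B <- B - lam * tcrossprod(v)
  }
  list(values = vals, vectors = vecs)
}

# Brute-force FOSD verdict on a dense uniform grid.
fosd_bruteforce <- function(a, b, eps = 0.01, lo = 0, hi = 1, k = 10000) {
  grid <- seq(lo, hi, length.out = k)
  Fa <- sapply(grid, function(x) mean(a <= x))
  Fb <- sapply(grid, function(x) mean(b <= x))
  max(c(0, (Fa - Fb)[Fa > Fb])) <= eps
}

# Minimal list-experiment dataset built by hand (control/treatment counts).
manual_list_data <- function(control_counts, t1_counts,
                             country = "IT") {
  n <- length(control_counts) + length(t1_counts)
  data.frame(
    id = seq_len(n),
    country = country,
    arm = rep(c("control", "T1"), c(length(control_counts), length(t1_counts))),
    item_count = c(control_counts, t1_counts),
    stringsAsFactors = FALSE
  )
}
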