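# Independent oracles used across the suite. Each deliberately re-derives
# the target quantity by brute force or closed form, never by calling the
# implementation path it checks.

# Shortest Beta(a, b) interval with the given mass, by grid search over the
# lower tail probability.
oracle_hpd_grid <- function(a, b, mass = 0.95, ngrid = 20000L) {
  p <- seq(0, 1 - mass, length.out = ngrid + 1L)
  lo <- qbeta(p, a, b)
  hi <- qbeta(p + mass, a, b)
  i <- which.min(hi - lo)
  c(lo[i], hi[i])
}

# Posterior mean of a Bernoulli likelihood x Beta prior by numerical
# normalization on a fine grid.
oracle_beta_posterior_mean <- function(y, a0 = 1, b0 = 1, ngrid = 200000L) {
  th <- seq(1 / (2 * ngrid), 1 - 1 / (2 * ngrid), length.out = ngrid)
  logw <- dbeta(th, a0, b0, log = TRUE) +
    sum(y) * log(th) + (length(y) - sum(y)) * log(1 - th)
  w <- exp(logw - max(logw))
  sum(th * w) / sum(w)
}

# Area between two step functions on the milestone axis by numerical
# integration (midpoint rule; exact for step functions), rescaled by w.
oracle_area_integral <- function(child, ref, dx = 1e-3) {
  n <- length(child)
  t <- seq(1 + dx / 2, n + 1 - dx / 2, by = dx)
  i <- pmin(floor(t), n)
  sum(abs(ref[i] - child[i])) * dx / n
}

# Pairwise co-clustering proportions by an explicit double loop.
oracle_psm <- function(zlist) {
  n <- length(zlist[[1L]])
  S <- matrix(0, n, n)
  for (z in zlist)
    for (i in seq_len(n))
      for (j in seq_len(n))
        S[i, j] <- S[i, j] + (z[i] == z[j])
  S <- S / length(zlist)
  diag(S) <- 1
  S
}

# Globally optimal k-medoids objective by exhaustive search (small n only).
oracle_pam_exhaustive <- function(D, k) {
  n <- nrow(D)
  best <- Inf
  combos <- utils::combn(n, k)
  for (c_i in seq_len(ncol(combos))) {
    med <- combos[, c_i]
    obj <- sum(apply(D[, med, drop = FALSE], 1L, min))
    if (obj < best) best <- obj
  }
  best
}

# Textbook silhouette: s_i = (b_i - a_i) / max(a_i, b_i), singletons 0.
oracle_silhouette <- function(D, cl) {
  n <- nrow(D)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(cl == cl[i] & seq_len(n) != i)
    if (!length(own)) { s[i] <- 0; next }
    a <- mean(D[i, own])
    b <- min(vapply(setdiff(unique(cl), cl[i]),
                    function(g) mean(D[i, cl == g]), 0))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

# Posterior mean of the DP concentration parameter given the occupied
# cluster count, p(alpha | K, n) proportional to
# prior(alpha) * alpha^(K-1) * (alpha + n) * B(alpha + 1, n),
# by 1-D quadrature.
oracle_alpha_posterior_mean <- function(K, n, eta1 = 1, eta2 = 1,
                                        upper = 60, ngrid = 200000L) {
  a <- seq(upper / ngrid / 2, upper, length.out = ngrid)
  logw <- dgamma(a, eta1, rate = eta2, log = TRUE) +
    (K - 1) * log(a) + log(a + n) + lbeta(a + 1, n)
  w <- exp(logw - max(logw))
  sum(a * w) / sum(w)
}

# Gelman-Rubin by direct evaluation of the variance decomposition.
oracle_gelman_rubin <- function(chains) {
  n <- length(chains[[1L]])
  W <- mean(sapply(chains, var))
  B <- n * var(sapply(chains, mean))
  sqrt(((n - 1) / n * W + B / n) / W)
}

# Sample skewness.
sample_skewness <- function(x) {
  m <- mean(x)
  mean((x - m)^3) / (mean((x - m)^2))^1.5
}

statistical_mode <- function(x) as.integer(names(which.max(table(x))))
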