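make_state <- function(z, V, mu, Sigma, alpha = 1, priors = NULL,
                       likelihood_off = FALSE) {
  if (is.null(priors))
    priors <- dpmm_priors(b0 = rep(0, length(mu[[1]])), N0 = 0.1,
                          c0 = length(mu[[1]]) + 1,
                          C0 = diag(length(mu[[1]])))
  devtraj:::new_dpmm_state(z, V, mu, Sigma, alpha, priors, likelihood_off)
}

test_that("stick-breaking weights follow the sequential-break construction", {
  expect_equal(stick_weights(c(0.5, 0.5, 0.5)), c(0.5, 0.25, 0.125))
  expect_equal(stick_weights(1), 1)
  expect_equal(stick_weights(c(0.2, 0.3)), c(0.2, 0.24))
  set.seed(1)
  V <- runif(30)
  expect_true(all(cumsum(stick_weights(V)) <= 1 + 1e-12))
  expect_error(stick_weights(c(0.5, 1.2)), "\\(0, 1\\]")
})

test_that("stick posteriors use Beta(1 + n_k, alpha + n beyond k)", {
  set.seed(2)
  # z = (1,1,2), alpha = 1: V1 ~ Beta(3, 2), V2 ~ Beta(2, 1)
  draws <- replicate(4000, sample_sticks(c(1L, 1L, 2L), 1, 2L))
  expect_equal(mean(draws[1, ]), 3/5, tolerance = 0.02)
  expect_equal(mean(draws[2, ]), 2/3, tolerance = 0.02)
  # all n observations in one component: V1 ~ Beta(1 + n, alpha)
  n <- 12; al <- 2
  d1 <- replicate(4000, sample_sticks(rep(1L, n), al, 1L))
  expect_equal(mean(d1), (1 + n) / (1 + n + al), tolerance = 0.02)
  # no observations: prior Beta(1, alpha)
  d0 <- replicate(4000, sample_sticks(integer(0), al, 3L)[2])
  expect_equal(mean(d0), 1 / (1 + al), tolerance = 0.02)
  expect_error(sample_sticks(c(1L, 2L), -1, 2L), "alpha")
})

test_that("normal-inverse-Wishart posterior matches a sequential one-at-a-time oracle", {
  set.seed(3)
  p <- 3
  priors <- dpmm_priors(b0 = c(1, -1, 0.5), N0 = 0.4, c0 = p + 2,
                        C0 = diag(p) + 0.2)
  y <- matrix(rnorm(6 * p), 6, p)
  z <- rep(1L, 6)
  post <- niw_posterior(y, z, 1L, priors)
  # oracle: fold observations in one at a time with the rank-one update
  b <- priors$b0; N <- priors$N0; cc <- priors$c0; C <- priors$C0
  for (i in 1:6) {
    d <- y[i, ] - b
    C <- C + (N / (N + 1)) * tcrossprod(d)
    b <- (N * b + y[i, ]) / (N + 1)
    N <- N + 1
    cc <- cc + 1
  }
  expect_equal(post$b_n, b, tolerance = 1e-10)
  expect_equal(post$N_n, N)
  expect_equal(post$c_n, cc)
  expect_equal(post$C_n, C, tolerance = 1e-10)
  # empty component returns the prior untouched
  e <- niw_posterior(y, z, 2L, priors)
  expect_equal(e$b_n, priors$b0)
  expect_equal(e$C_n, priors$C0)
  expect_equal(e$c_n, priors$c0)
  # single member equal to b0: location is the shrinkage fixed point
  one <- niw_posterior(matrix(priors$b0, 1, p, byrow = TRUE), 1L, 1L, priors)
  expect_equal(one$b_n, priors$b0)
  expect_equal(one$c_n, priors$c0 + 1)
})

test_that("component-parameter draws are centred on the conjugate posterior", {
  set.seed(4)
  p <- 2
  priors <- dpmm_priors(b0 = c(0, 0), N0 = 0.5, c0 = 6, C0 = diag(p))
  y <- MASS::mvrnorm(40, c(2, -1), diag(p))
  z <- rep(1L, 40)
  post <- niw_posterior(y, z, 1L, priors)
  draws <- replicate(800, sample_component_params(y, z, 1L, priors)$mu)
  expect_equal(rowMeans(draws), post$b_n, tolerance = 0.05)
  sig <- replicate(400, sample_component_params(y, z, 1L, priors)$Sigma)
  # E[Sigma] = C_n / (c_n - p - 1) for the inverse-Wishart
  expect_equal(apply(sig, 1:2, mean), post$C_n / (post$c_n - p - 1),
               tolerance = 0.12)
})

test_that("concentration-parameter sampler matches the quadrature posterior", {
  set.seed(5)
  K <- 5; n <- 50
  a <- 1
  draws <- numeric(30000)
  for (i in seq_along(draws)) { a <- sample_alpha(a, K, n); draws[i] <- a }
  want <- oracle_alpha_posterior_mean(K, n)
  expect_equal(mean(draws), want, tolerance = 0.02 * want)
  # stochastically larger alpha when every observation is a singleton
  a <- 1; hiK <- numeric(4000)
  for (i in seq_along(hiK)) { a <- sample_alpha(a, 20, 20); hiK[i] <- a }
  a <- 1; loK <- numeric(4000)
  for (i in seq_along(loK)) { a <- sample_alpha(a, 1, 20); loK[i] <- a }
  expect_gt(mean(hiK), mean(loK))
  expect_gt(quantile(hiK, 0.5), quantile(loK, 0.5))
  # a dominant prior rate pins alpha near zero
  a <- 1; tiny <- numeric(2000)
  for (i in seq_along(tiny)) { a <- sample_alpha(a, 3, 20, 1, 500); tiny[i] <- a }
  expect_lt(mean(tiny), 0.05)
  expect_error(sample_alpha(-1, 2, 10), "invalid")
})

test_that("slice update keeps allocations fixed when one stick covers everything", {
  set.seed(6)
  y <- matrix(rnorm(10), 5, 2)
  st <- make_state(z = rep(1L, 5), V = 1,
                   mu = list(c(0, 0)), Sigma = list(diag(2)))
  out <- sample_slice_and_labels(y, st)
  expect_equal(out$z, rep(1L, 5))
  expect_true(all(out$u < 1))
})

test_that("slice allocation probabilities match the marginal enumeration oracle", {
  set.seed(7)
  # two components exhausting the stick: C = (0.6, 0.4), rest = 0
  mu <- list(c(0, 0), c(1, 1))
  Sig <- list(diag(2), diag(2))
  y <- matrix(c(0.5, 0.5), 1, 2)  # equidistant from both means
  f <- mvtnorm::dmvnorm(y, mu[[1]], Sig[[1]])
  # from z = 1: both allowed iff u < C2, i.e. with probability C2/C1
  p12 <- (0.4 / 0.6) * (f / (f + f))
  hits <- 0L
  for (r in 1:4000) {
    st <- make_state(z = 1L, V = c(0.6, 1), mu = mu, Sigma = Sig)
    hits <- hits + (sample_slice_and_labels(y, st)$z == 2L)
  }
  expect_equal(hits / 4000, p12, tolerance = 0.035)
  # equal weights, equal densities: allocation is a fair coin
  hits <- 0L
  for (r in 1:4000) {
    st <- make_state(z = 1L, V = c(0.5, 1), mu = list(c(0, 0), c(0, 0)),
                     Sigma = Sig)
    hits <- hits + (sample_slice_and_labels(y, st)$z == 2L)
  }
  expect_equal(hits / 4000, 0.5, tolerance = 0.035)
})

test_that("label-switch moves accept symmetric states with probability 1", {
  set.seed(8)
  mu <- list(c(0, 0), c(0, 0)); Sig <- list(diag(2), diag(2))
  for (r in 1:20) {
    # equal occupancy makes move 1 free; equal sticks make move 2 free
    st <- make_state(z = c(1L, 2L), V = c(0.5, 0.5), mu = mu, Sigma = Sig)
    out <- label_switch_moves(st)
    expect_equal(unname(attr(out, "accepted")), c(1L, 1L))
  }
  # fewer than two components: a no-op
  st1 <- make_state(z = c(1L, 1L), V = 0.9, mu = mu[1], Sigma = Sig[1])
  out1 <- label_switch_moves(st1)
  expect_equal(sum(attr(out1, "attempted")), 0L)
})

test_that("member-swap move satisfies detailed balance on a toy posterior", {
  set.seed(9)
  # 2 observations, 2 components with fixed weights; the move swaps the
  # members and parameters, so the acceptance odds are the weight odds
  V <- c(0.7, 1)           # C = (0.7, 0.3)
  C <- stick_weights(V)
  mu <- list(c(0, 0), c(2, 2)); Sig <- list(diag(2), diag(2))
  y <- rbind(c(0.2, 0), c(1.8, 2))
  pi_state <- function(z) prod(C[z]) *
    prod(vapply(1:2, function(i) mvtnorm::dmvnorm(y[i, ], mu[[z[i]]],
                                                  Sig[[z[i]]]), 0))
  states <- list(c(1L, 1L), c(1L, 2L), c(2L, 1L), c(2L, 2L))
  for (z in states) {
    zs <- 3L - z  # the swap image
    # likelihood terms travel with the members: only weights change
    want <- min(1, prod(C[zs]) / prod(C[z]))
    acc <- 0L; ntry <- 3000L
    for (r in seq_len(ntry)) {
      st <- make_state(z = z, V = V, mu = mu, Sigma = Sig)
      out <- label_switch_moves(st, which = 1L)
      acc <- acc + attr(out, "accepted")[1L]
    }
    rate <- unname(acc / ntry)
    expect_equal(rate, want, tolerance = 0.04)
    # detailed balance: pi(s) a(s -> s') = pi(s') a(s' -> s) reduces to
    # min(pi(s), pi(s')) on both sides because the weight ratio IS the
    # posterior ratio under the member-and-parameter swap
    expect_equal(pi_state(z) * want,
                 min(pi_state(z), pi_state(zs) *
                       prod(vapply(1:2, function(i)
                         mvtnorm::dmvnorm(y[i, ], mu[[z[i]]], Sig[[z[i]]]), 0)) /
                       prod(vapply(1:2, function(i)
                         mvtnorm::dmvnorm(y[i, ], mu[[zs[i]]], Sig[[zs[i]]]), 0))))
  }
})

test_that("label moves change mixing, not the posterior of K", {
  set.seed(10)
  sim <- generate_gaussian_clusters(15, "separated", seed = 99)
  pr <- dpmm_priors(sim$y)
  with_moves <- run_chain(sim$y, pr, n_iter = 1500, init_K = 5, seed = 31)
  no_moves <- run_chain(sim$y, pr, n_iter = 1500, init_K = 5, seed = 32,
                        label_moves = FALSE)
  keep <- 501:1500
  expect_equal(statistical_mode(with_moves$K[keep]),
               statistical_mode(no_moves$K[keep]))
  expect_lt(abs(mean(with_moves$K[keep]) - mean(no_moves$K[keep])), 0.5)
})

test_that("chains are bit-reproducible and recover planted structure", {
  sim <- generate_gaussian_clusters(15, "separated", seed = 17)
  pr <- dpmm_priors(sim$y)
  ch1 <- run_chain(sim$y, pr, n_iter = 400, init_K = 5, seed = 77)
  ch2 <- run_chain(sim$y, pr, n_iter = 400, init_K = 5, seed = 77)
  expect_identical(ch1$K, ch2$K)
  expect_identical(ch1$alpha, ch2$alpha)
  expect_identical(ch1$z, ch2$z)
  # well-separated clusters: modal K is 3 and the modal partition is true
  ch <- run_chain(sim$y, pr, n_iter = 1500, init_K = 5, seed = 78)
  keep <- 501:1500
  expect_equal(statistical_mode(ch$K[keep]), 3L)
  final <- ch$z[nrow(ch$z), ]
  expect_equal(classification_accuracy(sim$labels, final), 100)
})

test_that("two identical observations collapse to a single component", {
  y <- rbind(c(0, 0), c(0, 0))
  pr <- dpmm_priors(b0 = c(0, 0), N0 = 0.1, c0 = 3, C0 = diag(2))
  expect_warning(ch <- run_chain(y, pr, n_iter = 600, init_K = 5, seed = 5),
                 "init_K reduced")
  expect_equal(statistical_mode(ch$K[201:600]), 1L)
})

test_that("with the likelihood switched off the sampler reproduces the prior", {
  # marginally alpha ~ Gamma(1, 1) and V1 | alpha ~ Beta(1, alpha)
  y <- matrix(0, 30, 2)
  pr <- dpmm_priors(b0 = c(0, 0), N0 = 0.1, c0 = 3, C0 = diag(2))
  ch <- run_chain(y, pr, n_iter = 6000, init_K = 1, seed = 123,
                  likelihood_off = TRUE, alloc_thin = 6000)
  keep <- 1001:6000
  a <- ch$alpha[keep]
  expect_equal(mean(a), 1, tolerance = 0.12)
  expect_equal(var(a), 1, tolerance = 0.25)
  expect_equal(unname(quantile(a, 0.5)), qgamma(0.5, 1, 1), tolerance = 0.1)
  # E[V1] = integral of 1/(1+alpha) against the Gamma(1, 1) prior
  want_v1 <- integrate(function(al) dgamma(al, 1, 1) / (1 + al), 0, Inf)$value
  expect_equal(mean(ch$V1[keep]), want_v1, tolerance = 0.05)
})

test_that("occupied-component means recover planted cluster means", {
  set.seed(12)
  sim <- generate_gaussian_clusters(20, "separated", seed = 55)
  pr <- dpmm_priors(sim$y)
  ch <- run_chain(sim$y, pr, n_iter = 1200, init_K = 5, seed = 56,
                  alloc_thin = 4, keep_params = TRUE)
  kept <- which(ch$alloc_iters > 600)
  truth <- t(sapply(1:3, function(g) colMeans(sim$y[sim$labels == g, ])))
  for (g in 1:3) {
    members <- which(sim$labels == g)
    draws <- t(sapply(kept, function(r) {
      z <- ch$z[r, ]
      lab <- statistical_mode(z[members])
      ch$params[[r]]$mu[[match(lab, ch$params[[r]]$labels)]]
    }))
    post_mean <- colMeans(draws)
    post_sd <- apply(draws, 2, sd)
    expect_true(all(abs(post_mean - truth[g, ]) <= 3 * post_sd))
  }
})

test_that("row permutation permutes the consensus partition identically", {
  sim <- generate_gaussian_clusters(15, "separated", seed = 60)
  res1 <- dpmm_consensus(sim$y, n_iter = 1200, init_K = c(4L, 8L), seed = 9,
                         k_max = 8)
  perm <- sample(nrow(sim$y))
  res2 <- dpmm_consensus(sim$y[perm, ], n_iter = 1200, init_K = c(4L, 8L),
                         seed = 9, k_max = 8)
  expect_equal(res1$clustering$k, res2$clustering$k)
  expect_equal(classification_accuracy(res1$clustering$assignment[perm],
                                       res2$clustering$assignment), 100)
})
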