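#' Prior specification for the Dirichlet process mixture model
#'
#' The mixture components are multivariate normal with a conjugate
#' normal-inverse-Wishart base distribution:
#' `Sigma_k ~ IW(c0, C0)` and `mu_k | Sigma_k ~ MVN(b0, Sigma_k / N0)`.
#' The Dirichlet process concentration parameter `alpha` has a
#' `Gamma(eta1, eta2)` hyperprior.
#'
#' Defaults follow common empirical-Bayes practice for this model: `b0` is
#' the column mean of the features, `C0` their sample covariance,
#' `N0 = 0.1`, `c0 = p + 1` degrees of freedom (7 in the six-domain
#' application) and `eta = c(1, 1)`.
#'
#' @param y Feature matrix (used for data-driven defaults); may be omitted
#'   if `b0` and `C0` are given explicitly.
#' @param b0 Prior location of the component means (p-vector).
#' @param N0 Prior precision scale (> 0).
#' @param c0 Inverse-Wishart degrees of freedom (> p - 1).
#' @param C0 Inverse-Wishart scale matrix (p x p, positive definite).
#' @param eta Length-2 vector `c(eta1, eta2)` of Gamma hyperparameters for
#'   `alpha`.
#' @return Object of class `dpmm_priors`.
#' @export
dpmm_priors <- function(y = NULL, b0 = NULL, N0 = 0.1, c0 = NULL, C0 = NULL,
                        eta = c(1, 1)) {
  if (!is.null(y)) y <- as.matrix(y)
  if (is.null(b0)) {
    if (is.null(y)) stop("give 'y' or an explicit 'b0'", call. = FALSE)
    b0 <- colMeans(y)
  }
  p <- length(b0)
  if (is.null(C0)) {
    if (is.null(y)) stop("give 'y' or an explicit 'C0'", call. = FALSE)
    C0 <- stats::cov(y)
    if (inherits(try(chol(C0), silent = TRUE), "try-error")) {
      # (near-)constant feature columns make the sample covariance
      # singular; ridge the data-driven default so the prior stays proper
      ridge <- 1e-6 * mean(diag(C0)) + 1e-12
      C0 <- C0 + diag(ridge, ncol(C0))
      message("dpmm_priors: sample covariance singular; added ridge ", ridge)
    }
  }
  C0 <- as.matrix(C0)
  if (is.null(c0)) c0 <- p + 1
  if (!isTRUE(N0 > 0)) stop("'N0' must be > 0", call. = FALSE)
  if (!isTRUE(c0 > p - 1)) stop("'c0' must exceed p - 1", call. = FALSE)
  if (!identical(dim(C0), c(p, p)) || !isSymmetric(unname(C0), tol = 1e-8))
    stop("'C0' must be a symmetric p x p matrix", call. = FALSE)
  if (inherits(try(chol(C0), silent = TRUE), "try-error"))
    stop("'C0' must be positive definite", call. = FALSE)
  if (length(eta) != 2L || any(eta <= 0))
    stop("'eta' must be two positive numbers", call. = FALSE)
  structure(list(b0 = as.numeric(b0), N0 = N0, c0 = c0,
                 C0 = unname((C0 + t(C0)) / 2),
                 eta1 = eta[1], eta2 = eta[2], p = p),
            class = "dpmm_priors")
}

#' @export
print.dpmm_priors <- function(x, ...) {
  cat(sprintf("DPMM priors (p = %d): N0 = %g, c0 = %g, alpha ~ Gamma(%g, %g)\n",
              x$p, x$N0, x$c0, x$eta1, x$eta2))
  invisible(x)
}

#' Stick-breaking weights
#'
#' Converts stick fractions `V_k` into mixture weights
#' `C_1 = V_1`, `C_k = V_k * prod_{j<k} (1 - V_j)`.
#'
#' @param V Numeric vector of stick fractions in (0, 1].
#' @return Numeric vector of weights; partial sums never exceed 1.
#' @examples
#' stick_weights(c(0.5, 0.5, 0.5))  # 0.5 0.25 0.125
#' @export
stick_weights <- function(V) {
  if (length(V) == 0L) return(numeric(0))
  if (any(V <= 0 | V > 1)) stop("stick fractions must lie in (0, 1]", call. = FALSE)
  V * c(1, cumprod(1 - V)[-length(V)])
}

#' Posterior draw of the stick fractions given allocations
#'
#' Conditional on the allocations, stick `k` has the Beta posterior
#' `V_k ~ Beta(1 + n_k, alpha + sum_{j>k} n_j)`, where `n_k` counts the
#' observations allocated to component `k`. Unoccupied represented
#' components use `n_k = 0`, i.e. the `Beta(1, alpha)` prior tilted only by
#' the observations beyond them.
#'
#' @param z Integer allocation vector (labels in `1..K_rep`).
#' @param alpha Concentration parameter (> 0).
#' @param K_rep Number of represented components (>= `max(z)`).
#' @return Numeric vector of `K_rep` stick fractions.
#' @export
sample_sticks <- function(z, alpha, K_rep = max(z, 1L)) {
  if (!isTRUE(alpha > 0)) stop("'alpha' must be > 0", call. = FALSE)
  if (length(z) && K_rep < max(z)) stop("'K_rep' below max label", call. = FALSE)
  nk <- tabulate(z, nbins = K_rep)
  beyond <- sum(nk) - cumsum(nk)
  stats::rbeta(K_rep, 1 + nk, alpha + beyond)
}

# ---- normal-inverse-Wishart machinery ---------------------------------

#' Conjugate normal-inverse-Wishart posterior parameters for one component
#'
#' With `n_k` member observations of mean `ybar_k` and scatter matrix
#' `S_k`, the posterior is
#' `Sigma_k ~ IW(c0 + n_k, C0 + S_k + N0 n_k / (N0 + n_k) (ybar_k - b0)(ybar_k - b0)')`
#' and `mu_k | Sigma_k ~ MVN((N0 b0 + n_k ybar_k) / (N0 + n_k), Sigma_k / (N0 + n_k))`.
#' An empty component returns the prior unchanged.
#'
#' @param y Feature matrix.
#' @param z Allocation vector.
#' @param k Component label.
#' @param priors A [dpmm_priors()].
#' @return List with `b_n`, `N_n`, `c_n`, `C_n` and member count `n_k`.
#' @export
niw_posterior <- function(y, z, k, priors) {
  y <- as.matrix(y)
  members <- which(z == k)
  nk <- length(members)
  if (nk == 0L)
    return(list(b_n = priors$b0, N_n = priors$N0, c_n = priors$c0,
                C_n = priors$C0, n_k = 0L))
  yk <- y[members, , drop = FALSE]
  ybar <- colMeans(yk)
  centred <- sweep(yk, 2L, ybar)
  S <- crossprod(centred)
  d <- ybar - priors$b0
  N_n <- priors$N0 + nk
  C_n <- priors$C0 + S + (priors$N0 * nk / N_n) * tcrossprod(d)
  list(b_n = (priors$N0 * priors$b0 + nk * ybar) / N_n,
       N_n = N_n, c_n = priors$c0 + nk,
       C_n = (C_n + t(C_n)) / 2, n_k = nk)
}

# Inverse-Wishart draw: Sigma ~ IW(nu, S)  <=>  Sigma^-1 ~ Wishart(nu, S^-1).
# Draws are symmetrized; a Cholesky failure triggers a 1e-10 diagonal jitter.
rinvwishart <- function(nu, S) {
  W <- stats::rWishart(1L, nu, chol2inv(jitter_chol(S)))[, , 1L]
  Sig <- chol2inv(jitter_chol(W))
  (Sig + t(Sig)) / 2
}

jitter_chol <- function(S) {
  ch <- try(chol(S), silent = TRUE)
  if (inherits(ch, "try-error")) {
    ch <- try(chol(S + diag(1e-10, nrow(S))), silent = TRUE)
    if (inherits(ch, "try-error"))
      stop("matrix not positive definite even after jitter", call. = FALSE)
    message("dpmm: applied 1e-10 diagonal jitter to a covariance factorization")
  }
  ch
}

#' Draw a component's mean and covariance from their conjugate posterior
#'
#' @inheritParams niw_posterior
#' @return List with elements `mu` (p-vector) and `Sigma` (p x p).
#' @export
sample_component_params <- function(y, z, k, priors) {
  post <- niw_posterior(y, z, k, priors)
  Sigma <- rinvwishart(post$c_n, post$C_n)
  mu <- as.numeric(MASS::mvrnorm(1L, post$b_n, Sigma / post$N_n))
  list(mu = mu, Sigma = Sigma)
}

#' Resample the Dirichlet process concentration parameter
#'
#' One sweep of the Escobar-West auxiliary-variable update targeting
#' `p(alpha | K, n)` under the `Gamma(eta1, eta2)` prior, where `K` is the
#' number of occupied components: draw `x ~ Beta(alpha + 1, n)`, then draw
#' `alpha` from a two-component mixture of Gamma distributions
#' `Gamma(eta1 + K, eta2 - log x)` and `Gamma(eta1 + K - 1, eta2 - log x)`.
#'
#' @param alpha Current value (> 0).
#' @param K Number of occupied components (>= 1).
#' @param n Number of observations (>= 1).
#' @param eta1,eta2 Gamma prior hyperparameters (> 0).
#' @return A new draw of `alpha`.
#' @export
sample_alpha <- function(alpha, K, n, eta1 = 1, eta2 = 1) {
  if (!isTRUE(alpha > 0) || !isTRUE(K >= 1) || !isTRUE(n >= 1) ||
      !isTRUE(eta1 > 0) || !isTRUE(eta2 > 0))
    stop("invalid arguments to sample_alpha", call. = FALSE)
  x <- stats::rbeta(1L, alpha + 1, n)
  rate <- eta2 - log(x)
  odds <- (eta1 + K - 1) / (n * rate)
  shape <- if (stats::runif(1L) < odds / (1 + odds)) eta1 + K else eta1 + K - 1
  stats::rgamma(1L, shape = shape, rate = rate)
}

#' Conjugate update of the concentration parameter given the sticks
#'
#' Within the stick-breaking representation the full conditional of
#' `alpha` given the instantiated stick fractions is available in closed
#' form: with `V_k ~ Beta(1, alpha)` a priori,
#' `alpha | V ~ Gamma(eta1 + K_rep, eta2 - sum_k log(1 - V_k))`.
#' This is the update used inside [run_chain()]; [sample_alpha()] targets
#' the collapsed posterior `p(alpha | K, n)` instead, which conditions on
#' less than the slice sampler's state retains.
#'
#' @param V Stick fractions currently represented.
#' @param eta1,eta2 Gamma prior hyperparameters (> 0).
#' @return A draw of `alpha`.
#' @export
sample_alpha_sticks <- function(V, eta1 = 1, eta2 = 1) {
  if (!length(V) || any(V <= 0 | V > 1))
    stop("'V' must be non-empty with entries in (0, 1]", call. = FALSE)
  if (!isTRUE(eta1 > 0) || !isTRUE(eta2 > 0))
    stop("invalid hyperparameters", call. = FALSE)
  # sticks can round to exactly 1 when alpha is very small; clamp so the
  # rate stays finite and the chain can escape the small-alpha region
  rate <- eta2 - sum(log1p(-pmin(V, 1 - 1e-12)))
  max(stats::rgamma(1L, shape = eta1 + length(V), rate = rate), 1e-12)
}

# ---- sampler state ----------------------------------------------------

new_dpmm_state <- function(z, V, mu, Sigma, alpha, priors,
                           likelihood_off = FALSE, u = NULL) {
  structure(list(z = as.integer(z), V = V, mu = mu, Sigma = Sigma,
                 alpha = alpha, u = u, priors = priors,
                 likelihood_off = isTRUE(likelihood_off)),
            class = "dpmm_state")
}

component_logdens <- function(y, state) {
  n <- nrow(y)
  K <- length(state$V)
  if (state$likelihood_off) return(matrix(0, n, K))
  out <- matrix(NA_real_, n, K)
  for (k in seq_len(K))
    out[, k] <- mvtnorm::dmvnorm(y, state$mu[[k]], state$Sigma[[k]],
                                 log = TRUE, checkSymmetry = FALSE)
  out
}

#' Slice-and-allocation update of the mixture state
#'
#' One Walker slice update: draw the slice variables
#' `u_i ~ Uniform(0, C_{z_i})`, lazily extend the stick representation with
#' prior draws until the unbroken stick mass falls below `min(u)` (which
#' makes the set of admissible components finite), then resample each
#' allocation from
#' `P(z_i = k) proportional to 1{C_k > u_i} * MVN(y_i; mu_k, Sigma_k)`.
#'
#' @param y Feature matrix.
#' @param state A `dpmm_state` (as held inside [run_chain()]).
#' @param max_sticks Safety cap on the represented components.
#' @return The updated `dpmm_state` (new `u`, possibly longer `V`/params,
#'   new `z`).
#' @export
sample_slice_and_labels <- function(y, state, max_sticks = 10000L) {
  y <- as.matrix(y)
  n <- nrow(y)
  C <- stick_weights(state$V)
  u <- C[state$z] * stats::runif(n)
  minu <- min(u)
  rest <- prod(1 - state$V)
  while (rest >= minu) {
    if (length(state$V) >= max_sticks)
      stop("slice sampler exceeded ", max_sticks, " represented sticks",
           call. = FALSE)
    vnew <- stats::rbeta(1L, 1, state$alpha)
    state$V <- c(state$V, vnew)
    C <- c(C, vnew * rest)
    rest <- rest * (1 - vnew)
    pr <- sample_component_params(y, state$z, k = length(state$V), state$priors)
    state$mu[[length(state$V)]] <- pr$mu
    state$Sigma[[length(state$V)]] <- pr$Sigma
  }
  K <- length(C)
  logf <- component_logdens(y, state)
  allowed <- outer(u, C, FUN = "<")
  logf[!allowed] <- -Inf
  mx <- logf[, 1L]
  if (K > 1L) for (k in 2L:K) mx <- pmax(mx, logf[, k])
  W <- exp(logf - mx)
  r <- stats::runif(n) * rowSums(W)
  acc <- numeric(n)
  pick <- integer(n)
  for (k in seq_len(K)) {
    acc <- acc + W[, k]
    pick <- pick + (r > acc)
  }
  state$z <- pmin(pick + 1L, K)
  state$u <- u
  state
}

#' Metropolis-Hastings label-switching moves
#'
#' Two moves that improve mixing over the size-biased ordering of the
#' stick-breaking weights while leaving the joint posterior invariant:
#'
#' * Move 1 picks two represented components at random and proposes
#'   swapping their parameters and member allocations while keeping the
#'   weights; accepted with probability
#'   `min(1, (C_l / C_k)^(n_k - n_l))`.
#' * Move 2 picks an adjacent pair `(k, k + 1)` and proposes swapping the
#'   components together with their stick fractions; accepted with
#'   probability `min(1, (1 - V_{k+1})^{n_k} / (1 - V_k)^{n_{k+1}})`.
#'
#' Degenerate states (fewer than two represented components) are no-ops.
#'
#' @param state A `dpmm_state`.
#' @param which Integer subset of `c(1, 2)` selecting which moves to
#'   attempt (both by default).
#' @return The (possibly) updated state; attributes `accepted` and
#'   `attempted` count move outcomes.
#' @export
label_switch_moves <- function(state, which = c(1L, 2L)) {
  K <- length(state$V)
  accepted <- attempted <- c(swap_members = 0L, swap_sticks = 0L)
  if (K >= 2L) {
    if (1L %in% which) {
      attempted[1L] <- 1L
      C <- stick_weights(state$V)
      kl <- sample.int(K, 2L)
      k <- kl[1L]; l <- kl[2L]
      nk <- sum(state$z == k); nl <- sum(state$z == l)
      logr <- if (nk == nl) 0 else (nk - nl) * (log(C[l]) - log(C[k]))
      if (isTRUE(log(stats::runif(1L)) < logr)) {
        accepted[1L] <- 1L
        state <- swap_components(state, k, l, swap_sticks = FALSE)
      }
    }
    if (2L %in% which) {
      attempted[2L] <- 1L
      k <- if (K == 2L) 1L else sample.int(K - 1L, 1L)
      nk <- sum(state$z == k); nk1 <- sum(state$z == k + 1L)
      # 0 * -Inf (an empty component next to a full stick) counts as 0
      t1 <- if (nk == 0L) 0 else nk * log1p(-state$V[k + 1L])
      t2 <- if (nk1 == 0L) 0 else nk1 * log1p(-state$V[k])
      logr <- t1 - t2
      if (isTRUE(log(stats::runif(1L)) < logr)) {
        accepted[2L] <- 1L
        state <- swap_components(state, k, k + 1L, swap_sticks = TRUE)
      }
    }
  }
  attr(state, "accepted") <- accepted
  attr(state, "attempted") <- attempted
  state
}

swap_components <- function(state, k, l, swap_sticks) {
  tmp <- state$mu[[k]]; state$mu[[k]] <- state$mu[[l]]; state$mu[[l]] <- tmp
  tmp <- state$Sigma[[k]]; state$Sigma[[k]] <- state$Sigma[[l]]; state$Sigma[[l]] <- tmp
  ink <- state$z == k
  state$z[state$z == l] <- k
  state$z[ink] <- l
  if (swap_sticks) {
    tmp <- state$V[k]; state$V[k] <- state$V[l]; state$V[l] <- tmp
  }
  state
}

# ---- chain driver -----------------------------------------------------

dpmm_init <- function(y, priors, init_K, likelihood_off = FALSE) {
  n <- nrow(y)
  distinct <- nrow(unique(as.data.frame(y)))
  if (init_K > distinct) {
    warning("init_K reduced from ", init_K, " to ", distinct,
            " (distinct observations)", call. = FALSE)
    init_K <- distinct
  }
  z <- if (init_K == 1L || likelihood_off) rep(1L, n)
       else stats::kmeans(y, centers = init_K, nstart = 5L,
                          iter.max = 50L)$cluster
  alpha <- priors$eta1 / priors$eta2
  V <- sample_sticks(z, alpha, max(z))
  mu <- vector("list", max(z)); Sigma <- vector("list", max(z))
  for (k in seq_len(max(z))) {
    pr <- sample_component_params(y, z, k, priors)
    mu[[k]] <- pr$mu; Sigma[[k]] <- pr$Sigma
  }
  new_dpmm_state(z, V, mu, Sigma, alpha, priors, likelihood_off)
}

#' Run one chain of the DPMM slice sampler
#'
#' Initialises the allocations with K-means (`init_K` centres), then
#' iterates: conjugate component-parameter draws for every represented
#' component, posterior stick draws, the Walker slice-and-allocation
#' update, a conjugate refresh of `alpha` given the sticks
#' ([sample_alpha_sticks()]), and the two label-switching moves. Per iteration the trace records the number of *occupied*
#' components `K` (components holding at least one observation) and
#' `alpha`; allocation vectors are stored every `alloc_thin` iterations.
#'
#' @param y Numeric feature matrix (n x p).
#' @param priors A [dpmm_priors()]; defaults to `dpmm_priors(y)`.
#' @param n_iter Number of iterations.
#' @param init_K K-means initialisation size (reduced with a warning if it
#'   exceeds the number of distinct observations).
#' @param seed Optional integer seed; a seeded run is bit-reproducible.
#' @param alloc_thin Store the allocation vector every `alloc_thin`-th
#'   iteration (default 1 = every iteration).
#' @param keep_params Also store the occupied components' means at the
#'   stored iterations (used for parameter-recovery checks).
#' @param likelihood_off Replace all component log-densities by a constant;
#'   the sampler then explores the prior (used for validation).
#' @param label_moves Set `FALSE` to disable the label-switching moves.
#' @param init_state Resume from the `final_state` of a previous chain
#'   segment instead of K-means initialisation.
#' @return Object of class `dpmm_chain`: per-iteration `K` and `alpha`,
#'   stored allocation matrix `z` (rows = stored iterations), the stored
#'   iteration indices, label-move acceptance counts, and `final_state`
#'   for segment-and-resume runs.
#' @export
run_chain <- function(y, priors = NULL, n_iter = 1000L, init_K = 5L,
                      seed = NULL, alloc_thin = 1L, keep_params = FALSE,
                      likelihood_off = FALSE, label_moves = TRUE,
                      init_state = NULL) {
  y <- as.matrix(y)
  n <- nrow(y)
  if (n < 2L) stop("need at least 2 observations", call. = FALSE)
  if (n_iter < 1L) stop("'n_iter' must be >= 1", call. = FALSE)
  if (is.null(priors)) priors <- dpmm_priors(y)
  if (!is.null(seed)) set.seed(as.integer(seed))
  state <- if (is.null(init_state))
    dpmm_init(y, priors, init_K, likelihood_off)
  else init_state
  state$likelihood_off <- isTRUE(likelihood_off)

  K_trace <- integer(n_iter)
  a_trace <- numeric(n_iter)
  keep_flag <- seq_len(n_iter) %% alloc_thin == 0L
  keep <- which(keep_flag)
  z_store <- matrix(NA_integer_, length(keep), n)
  mu_store <- if (keep_params) vector("list", length(keep)) else NULL
  V1_trace <- numeric(n_iter)
  acc <- att <- c(swap_members = 0L, swap_sticks = 0L)
  row <- 0L

  for (it in seq_len(n_iter)) {
    Krep <- length(state$V)
    for (k in seq_len(Krep)) {
      pr <- sample_component_params(y, state$z, k, state$priors)
      state$mu[[k]] <- pr$mu; state$Sigma[[k]] <- pr$Sigma
    }
    state$V <- sample_sticks(state$z, state$alpha, Krep)
    state <- sample_slice_and_labels(y, state)
    state$alpha <- sample_alpha_sticks(state$V, state$priors$eta1,
                                       state$priors$eta2)
    if (label_moves) {
      state <- label_switch_moves(state)
      acc <- acc + attr(state, "accepted")
      att <- att + attr(state, "attempted")
    }
    # drop represented components beyond the last occupied label; they are
    # regenerated on demand by the slice extension
    Kmax <- max(state$z)
    state$V <- state$V[seq_len(Kmax)]
    state$mu <- state$mu[seq_len(Kmax)]
    state$Sigma <- state$Sigma[seq_len(Kmax)]

    K_trace[it] <- length(unique(state$z))
    a_trace[it] <- state$alpha
    V1_trace[it] <- state$V[1L]
    if (keep_flag[it]) {
      row <- row + 1L
      z_store[row, ] <- state$z
      if (keep_params) {
        occ <- sort(unique(state$z))
        mu_store[[row]] <- list(labels = occ, mu = state$mu[occ])
      }
    }
  }
  structure(list(K = K_trace, alpha = a_trace, V1 = V1_trace,
                 z = z_store, alloc_iters = keep, params = mu_store,
                 n_iter = n_iter, init_K = init_K, seed = seed,
                 accept = acc, attempted = att,
                 n = n, p = ncol(y), final_state = state),
            class = "dpmm_chain")
}

#' @export
print.dpmm_chain <- function(x, ...) {
  cat(sprintf("DPMM slice-sampler chain: %d iterations, n = %d, p = %d\n",
              x$n_iter, x$n, x$p))
  cat(sprintf("  occupied K: median %g (range %d-%d); mean alpha %.3f\n",
              stats::median(x$K), min(x$K), max(x$K), mean(x$alpha)))
  invisible(x)
}

#' Run several independently initialised chains
#'
#' Chain `j` is seeded with `seed + 1000 * (j - 1)` and initialised from a
#' K-means partition of size `init_K[j]` (the application default mirrors
#' three chains at K = 5, 10, 15).
#'
#' @inheritParams run_chain
#' @param init_K Integer vector, one K-means initialisation per chain.
#' @param seed Master seed; per-chain seeds are derived by fixed offsets.
#' @return List of `dpmm_chain` objects.
#' @export
run_chains <- function(y, priors = NULL, n_iter = 1000L,
                       init_K = c(5L, 10L, 15L), seed = 1L,
                       alloc_thin = 1L, keep_params = FALSE) {
  y <- as.matrix(y)
  if (is.null(priors)) priors <- dpmm_priors(y)
  lapply(seq_along(init_K), function(j)
    run_chain(y, priors, n_iter = n_iter, init_K = init_K[j],
              seed = seed + 1000L * (j - 1L), alloc_thin = alloc_thin,
              keep_params = keep_params))
}
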