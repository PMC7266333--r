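#' Beta distribution state for sequential updating
#'
#' A `beta_state` carries the pseudo-counts of a Beta distribution through a
#' child's milestone sequence. Under the beta-Bernoulli model the posterior
#' after observing `z` successes in `N` trials from a `Beta(a, b)` prior is
#' `Beta(z + a, N - z + b)`, so sequential updating reduces to adding 1 to
#' `a` for each success and 1 to `b` for each failure.
#'
#' @param a Positive real; success pseudo-count.
#' @param b Positive real; failure pseudo-count.
#' @return An object of class `beta_state`: a named numeric vector with
#'   elements `a` and `b`.
#' @examples
#' beta_state(1, 1)            # the uniform starting prior
#' update_beta(beta_state(1, 1), 1)
#' @export
beta_state <- function(a = 1, b = 1) {
  if (!is.numeric(a) || !is.numeric(b) || length(a) != 1L || length(b) != 1L)
    stop("'a' and 'b' must be scalar numerics", call. = FALSE)
  if (!is.finite(a) || !is.finite(b) || a <= 0 || b <= 0)
    stop("'a' and 'b' must be finite and > 0", call. = FALSE)
  structure(c(a = as.numeric(a), b = as.numeric(b)), class = "beta_state")
}

#' @export
print.beta_state <- function(x, ...) {
  cat(sprintf("Beta(a = %g, b = %g), mean = %.4f\n",
              x[["a"]], x[["b"]], x[["a"]] / (x[["a"]] + x[["b"]])))
  invisible(x)
}

#' Conjugate update of a beta state with one Bernoulli observation
#'
#' @param state A [beta_state()].
#' @param y A single binary observation (0 = milestone not achieved,
#'   1 = achieved).
#' @return A new `beta_state`; the input is unmodified.
#' @examples
#' update_beta(beta_state(1, 1), 1)  # Beta(2, 1)
#' update_beta(beta_state(1, 1), 0)  # Beta(1, 2)
#' @export
update_beta <- function(state, y) {
  if (!inherits(state, "beta_state")) state <- beta_state(state[[1]], state[[2]])
  if (length(y) != 1L || !is.numeric(y) || !(y %in% c(0, 1)))
    stop("'y' must be a single binary value (0 or 1)", call. = FALSE)
  if (y == 1) beta_state(state[["a"]] + 1, state[["b"]])
  else        beta_state(state[["a"]], state[["b"]] + 1)
}

#' Highest posterior density interval of a Beta distribution
#'
#' Returns the shortest interval carrying `mass` posterior probability of a
#' `Beta(a, b)` distribution. For monotone densities (`a > 1, b <= 1` or
#' `a <= 1, b > 1`) one endpoint is 1 or 0 respectively. When both shape
#' parameters are at most 1 the density is flat or U-shaped and the HPD
#' interval is not unique; the equal-tailed interval is returned instead.
#' Only the uniform starting prior `Beta(1, 1)` hits this fallback in the
#' sequential-updating path.
#'
#' @param a,b Positive shape parameters.
#' @param mass Probability mass to cover, in (0, 1). Default 0.95.
#' @return Numeric vector `c(low, high)`.
#' @examples
#' hpd_interval(2, 1)        # (sqrt(0.05), 1): increasing density
#' hpd_interval(5, 5)        # symmetric, equals the equal-tailed interval
#' @export
hpd_interval <- function(a, b, mass = 0.95) {
  if (!is.numeric(mass) || length(mass) != 1L || mass <= 0 || mass >= 1)
    stop("'mass' must be a single number in (0, 1)", call. = FALSE)
  if (a <= 0 || b <= 0) stop("'a' and 'b' must be > 0", call. = FALSE)
  tail <- 1 - mass
  if (a <= 1 && b <= 1) {
    # flat or U-shaped density: HPD is non-unique, use equal tails
    return(c(stats::qbeta(tail / 2, a, b), stats::qbeta(1 - tail / 2, a, b)))
  }
  if (b <= 1) return(c(stats::qbeta(tail, a, b), 1))   # increasing density
  if (a <= 1) return(c(0, stats::qbeta(mass, a, b)))   # decreasing density
  # unimodal interior mode: minimise width over the lower tail probability
  width <- function(p) stats::qbeta(p + mass, a, b) - stats::qbeta(p, a, b)
  opt <- stats::optimize(width, interval = c(0, tail), tol = 1e-10)
  p <- opt$minimum
  c(stats::qbeta(p, a, b), stats::qbeta(p + mass, a, b))
}

#' Posterior-mean trace of a milestone sequence
#'
#' Runs beta-Bernoulli sequential updating along one child's ordered
#' milestone observations for one functional domain. Entry `i` of the trace
#' holds the posterior mean and HPD interval of the Beta state *after*
#' incorporating observation `i`, so a child who achieves its first
#' milestones has exactly the gold-standard means there.
#'
#' @param x Either a binary vector of achievements in milestone order, or a
#'   data frame with columns `milestone_index` and `achieved` (and
#'   optionally `child_id`, `domain`, `month`) for a single child x domain.
#' @param prior Starting [beta_state()]; default `Beta(1, 1)`.
#' @param mass HPD mass, default 0.95.
#' @param allow_gaps If `FALSE` (default) a data-frame input whose
#'   milestone indices are not the contiguous run `1, 2, ...` is rejected;
#'   the model is developed for complete sequences. Set `TRUE` to update
#'   through the observed milestones only, skipping gaps.
#' @return A data frame of class `posterior_trace` with columns
#'   `milestone_index`, `post_mean`, `hpd_low`, `hpd_high` and attributes
#'   `child_id` and `domain` when available.
#' @examples
#' posterior_trace(c(1, 1, 1))$post_mean  # 2/3, 3/4, 4/5
#' posterior_trace(c(1, 0))$post_mean     # 2/3, 1/2
#' @export
posterior_trace <- function(x, prior = beta_state(1, 1), mass = 0.95,
                            allow_gaps = FALSE) {
  child_id <- NA_character_; domain <- NA_character_
  if (is.data.frame(x)) {
    if (!all(c("milestone_index", "achieved") %in% names(x)))
      stop("data-frame input needs columns 'milestone_index' and 'achieved'",
           call. = FALSE)
    x <- x[order(x$milestone_index), , drop = FALSE]
    idx <- as.integer(x$milestone_index)
    if (anyDuplicated(idx))
      stop("duplicated milestone_index in sequence", call. = FALSE)
    if (!allow_gaps && !identical(idx, seq_along(idx)))
      stop("incomplete milestone sequence (gaps); use allow_gaps = TRUE to skip",
           call. = FALSE)
    if ("child_id" %in% names(x)) child_id <- as.character(x$child_id[1])
    if ("domain" %in% names(x)) domain <- as.character(x$domain[1])
    y <- x$achieved
  } else {
    y <- x
    idx <- seq_along(y)
  }
  if (length(y) == 0L) stop("empty milestone sequence", call. = FALSE)
  if (!all(y %in% c(0, 1))) stop("'achieved' must be binary 0/1", call. = FALSE)
  n <- length(y)
  st <- prior
  out <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    st <- update_beta(st, y[i])
    hpd <- hpd_interval(st[["a"]], st[["b"]], mass)
    out[i, ] <- c(st[["a"]] / (st[["a"]] + st[["b"]]), hpd)
  }
  res <- data.frame(milestone_index = idx,
                    post_mean = out[, 1],
                    hpd_low = out[, 2],
                    hpd_high = out[, 3])
  attr(res, "child_id") <- child_id
  attr(res, "domain") <- domain
  class(res) <- c("posterior_trace", "data.frame")
  res
}

#' Posterior traces for a whole cohort
#'
#' Applies [posterior_trace()] to every child x domain combination of a
#' cohort table.
#'
#' @param cohort Data frame with columns `child_id`, `domain`,
#'   `milestone_index`, `month`, `achieved` (the cohort CSV layout).
#' @param mass HPD mass.
#' @param allow_gaps Passed to [posterior_trace()].
#' @return One data frame with columns `child_id`, `domain`,
#'   `milestone_index`, `post_mean`, `hpd_low`, `hpd_high`.
#' @export
trace_cohort <- function(cohort, mass = 0.95, allow_gaps = FALSE) {
  validate_cohort(cohort)
  parts <- split(cohort, list(cohort$child_id, cohort$domain), drop = TRUE)
  out <- lapply(parts, function(d) {
    tr <- posterior_trace(d, mass = mass, allow_gaps = allow_gaps)
    data.frame(child_id = as.character(d$child_id[1]),
               domain = as.character(d$domain[1]),
               tr, row.names = NULL)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$child_id, res$domain, res$milestone_index), , drop = FALSE]
}

#' Read a cohort milestone CSV
#'
#' Expects the header `child_id,domain,milestone_index,month,achieved` with
#' one row per measurement and binary `achieved`.
#'
#' @param path Path to a CSV file.
#' @return A validated cohort data frame.
#' @export
read_cohort <- function(path) {
  cohort <- utils::read.csv(path, stringsAsFactors = FALSE)
  validate_cohort(cohort)
  cohort
}

validate_cohort <- function(cohort) {
  need <- c("child_id", "domain", "milestone_index", "month", "achieved")
  miss <- setdiff(need, names(cohort))
  if (length(miss))
    stop("cohort is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (!all(cohort$achieved %in% c(0, 1)))
    stop("'achieved' must be binary 0/1", call. = FALSE)
  if (any(cohort$milestone_index < 1) || any(cohort$month < 1))
    stop("'milestone_index' and 'month' must be >= 1", call. = FALSE)
  invisible(cohort)
}
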