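#' The milestone assessment schedule
#'
#' Deterministic schedule of the milestone programme: within each of the
#' six functional domains there are three ordered milestones per month for
#' months 1-12, two per month for months 13-18, one per month for months
#' 19-25, and single milestones at months 28, 31 and 34 - 58 milestones
#' per domain, 348 in total.
#'
#' @return Data frame with columns `domain`, `milestone_index` (1-58) and
#'   `month`.
#' @examples
#' nrow(milestone_schedule())  # 348
#' @export
milestone_schedule <- function() {
  months <- c(rep(1:12, each = 3L), rep(13:18, each = 2L), 19:25,
              c(28L, 31L, 34L))
  per_domain <- data.frame(milestone_index = seq_along(months),
                           month = as.integer(months))
  out <- do.call(rbind, lapply(domain_names(), function(d)
    data.frame(domain = d, per_domain)))
  rownames(out) <- NULL
  out
}

#' Change-point delay profile for cohort simulation
#'
#' A child archetype: within each domain, milestones are achieved
#' independently with probability `p_before` up to (not including) the
#' onset milestone and `p_after` from the onset onwards. A domain with no
#' onset uses `p_before` throughout. This is the simplest generator able to
#' produce domain-specific deficits (e.g. an isolated speech delay) and
#' the right-skewed area distributions seen in practice.
#'
#' @param name Profile label carried into the ground truth.
#' @param p_before Achievement probability before the delay onset; scalar,
#'   length-6, or named vector over [domain_names()].
#' @param onset Onset milestone index (1-58); scalar or named vector;
#'   `NA` = no delay onset in that domain.
#' @param p_after Achievement probability from the onset onwards (same
#'   shapes as `p_before`; domains left `NA` keep `p_before`). Must satisfy
#'   `0 <= p_after <= p_before <= 1` per domain.
#' @return Object of class `delay_profile`: data frame with one row per
#'   domain.
#' @examples
#' delay_profile("speech_delay", p_before = 0.97,
#'               onset = c(speech = 10), p_after = c(speech = 0.2))
#' @export
delay_profile <- function(name, p_before = 0.97, onset = NA_integer_,
                          p_after = NA_real_) {
  expand <- function(x, default) {
    out <- rep(default, 6L)
    names(out) <- domain_names()
    if (!is.null(names(x)) && any(nzchar(names(x)))) {
      bad <- setdiff(names(x), domain_names())
      if (length(bad)) stop("unknown domain(s): ", paste(bad, collapse = ", "),
                            call. = FALSE)
      out[names(x)] <- x
    } else if (length(x) == 1L) {
      out[] <- x
    } else if (length(x) == 6L) {
      out[] <- x
    } else stop("per-domain values must be scalar, length 6, or named",
                call. = FALSE)
    out
  }
  pb <- expand(p_before, 0.97)
  pa <- expand(p_after, NA_real_)
  on <- expand(onset, NA_integer_)
  # domains without an explicit post-onset probability keep p_before
  pa[is.na(pa)] <- pb[is.na(pa)]
  if (any(pb < 0 | pb > 1 | pa < 0 | pa > 1))
    stop("probabilities must lie in [0, 1]", call. = FALSE)
  if (any(pa > pb + 1e-12))
    stop("'p_after' may not exceed 'p_before'", call. = FALSE)
  if (any(!is.na(on) & (on < 1 | on > 58)))
    stop("'onset' must lie in 1..58", call. = FALSE)
  structure(data.frame(domain = domain_names(), onset = as.integer(on),
                       p_before = pb, p_after = pa, row.names = NULL),
            class = c("delay_profile", "data.frame"), name = name)
}

#' Example delay-profile archetypes
#'
#' A small library of archetypes mirroring the qualitative subgroup
#' portraits of delayed development: typical achievers, global delay,
#' an isolated severe speech deficit, and a motor (hands + movement)
#' delay.
#'
#' @return Named list of [delay_profile()] objects.
#' @export
example_profiles <- function() {
  list(
    typical = delay_profile("typical", p_before = 0.97),
    global_delay = delay_profile("global_delay", p_before = 0.9,
                                 onset = 12, p_after = 0.35),
    speech_delay = delay_profile("speech_delay", p_before = 0.97,
                                 onset = c(speech = 8),
                                 p_after = c(speech = 0.15)),
    motor_delay = delay_profile("motor_delay", p_before = 0.97,
                                onset = c(hands = 12, movement = 12),
                                p_after = c(hands = 0.3, movement = 0.3))
  )
}

#' Simulate a milestone cohort
#'
#' Draws every scheduled milestone of every child as an independent
#' Bernoulli trial with the probability dictated by the child's
#' [delay_profile()]. Ground-truth profile labels are recorded for
#' recovery testing.
#'
#' @param profiles List of [delay_profile()] objects.
#' @param n_children Integer vector: children per profile.
#' @param seed Optional integer seed (generation is bit-reproducible).
#' @return List with `cohort` (the standard cohort data frame) and
#'   `truth` (data frame `child_id`, `profile`).
#' @export
generate_cohort <- function(profiles, n_children, seed = NULL) {
  if (inherits(profiles, "delay_profile")) profiles <- list(profiles)
  if (length(n_children) == 1L) n_children <- rep(n_children, length(profiles))
  if (length(n_children) != length(profiles))
    stop("'n_children' must match 'profiles' in length", call. = FALSE)
  if (any(n_children < 1L)) stop("need at least one child per profile",
                                 call. = FALSE)
  if (!is.null(seed)) set.seed(as.integer(seed))
  sched <- milestone_schedule()
  cohort <- vector("list", sum(n_children))
  truth <- character(sum(n_children))
  child <- 0L
  for (gi in seq_along(profiles)) {
    prof <- profiles[[gi]]
    pname <- attr(prof, "name")
    # per-domain probability vector along the 58-milestone schedule
    probs <- lapply(seq_len(nrow(prof)), function(r) {
      p <- rep(prof$p_before[r], 58L)
      if (!is.na(prof$onset[r])) p[prof$onset[r]:58L] <- prof$p_after[r]
      p
    })
    names(probs) <- prof$domain
    for (ci in seq_len(n_children[gi])) {
      child <- child + 1L
      id <- sprintf("child%03d", child)
      ach <- unlist(lapply(domain_names(), function(d)
        stats::rbinom(58L, 1L, probs[[d]])), use.names = FALSE)
      cohort[[child]] <- data.frame(child_id = id, sched,
                                    achieved = ach, row.names = NULL)
      truth[child] <- pname
    }
  }
  cohort <- do.call(rbind, cohort)
  cohort <- cohort[, c("child_id", "domain", "milestone_index", "month",
                       "achieved")]
  list(cohort = cohort,
       truth = data.frame(child_id = sprintf("child%03d", seq_along(truth)),
                          profile = truth))
}

#' Randomly permute milestone responses within each month
#'
#' Used by the independence sensitivity analysis: within every
#' child x domain x month cell, the achieved/not-achieved responses are
#' shuffled across that month's milestone slots, leaving the schedule
#' itself fixed.
#'
#' @param cohort Cohort data frame.
#' @param seed Optional seed.
#' @return A cohort data frame with permuted `achieved` values.
#' @export
reorder_within_month <- function(cohort, seed = NULL) {
  validate_cohort(cohort)
  if (!is.null(seed)) set.seed(as.integer(seed))
  key <- interaction(cohort$child_id, cohort$domain, cohort$month, drop = TRUE)
  idx <- unsplit(lapply(split(seq_len(nrow(cohort)), key), function(i)
    if (length(i) > 1L) sample(i) else i), key)
  cohort$achieved <- cohort$achieved[idx]
  cohort
}

#' Simulate Gaussian cluster benchmarks
#'
#' Draws `k` isotropic Gaussian clusters in the plane with means at the
#' vertices of a regular polygon (equilateral triangle for `k = 3`).
#' The presets emulate the three separation conditions of the sensitivity
#' benchmark: pairwise mean distance 8 ("separated"), 6 ("adjacent") and
#' 4 ("overlapping"), each with unit isotropic covariance.
#'
#' @param n_per_cluster Observations per cluster (50, 500 and 5000 mirror
#'   the small/medium/large sample-size conditions).
#' @param preset One of `"separated"`, `"adjacent"`, `"overlapping"`;
#'   ignored when `means` is given.
#' @param means Optional k x p matrix of cluster means (rows pairwise
#'   distinct).
#' @param sd Isotropic standard deviation of each cluster (default 1).
#' @param seed Optional seed.
#' @return List with `y` (numeric matrix) and `labels` (integer vector of
#'   true cluster memberships).
#' @export
generate_gaussian_clusters <- function(n_per_cluster = 50L,
                                       preset = c("overlapping", "adjacent",
                                                  "separated"),
                                       means = NULL, sd = 1, seed = NULL) {
  if (is.null(means)) {
    preset <- match.arg(preset)
    d <- switch(preset, separated = 8, adjacent = 6, overlapping = 4)
    r <- d / sqrt(3)  # circumradius of an equilateral triangle of side d
    ang <- pi / 2 + 2 * pi * (0:2) / 3
    means <- cbind(r * cos(ang), r * sin(ang))
  }
  means <- as.matrix(means)
  if (anyDuplicated(as.data.frame(means)))
    stop("cluster means must be pairwise distinct", call. = FALSE)
  k <- nrow(means)
  p <- ncol(means)
  if (length(n_per_cluster) == 1L) n_per_cluster <- rep(n_per_cluster, k)
  if (!is.null(seed)) set.seed(as.integer(seed))
  y <- do.call(rbind, lapply(seq_len(k), function(j)
    matrix(stats::rnorm(n_per_cluster[j] * p, sd = sd), ncol = p,
           byrow = TRUE) + matrix(means[j, ], n_per_cluster[j], p,
                                  byrow = TRUE)))
  list(y = y, labels = rep(seq_len(k), n_per_cluster))
}

#' Classification accuracy under optimal label matching
#'
#' Percentage of observations whose estimated cluster agrees with the true
#' label after the estimated labels have been mapped to the true ones by
#' the best injective matching (the smaller label set is matched into the
#' larger; clusters in excess of the truth count as errors).
#'
#' @param truth,estimate Equal-length label vectors (any atomic type).
#' @return Accuracy as a percentage in `[0, 100]`.
#' @examples
#' classification_accuracy(c(1, 1, 2, 2), c(2, 2, 1, 1))  # 100
#' classification_accuracy(c(1, 1, 2, 2), c(1, 2, 2, 2))  # 75
#' @export
classification_accuracy <- function(truth, estimate) {
  if (length(truth) != length(estimate))
    stop("label vectors differ in length", call. = FALSE)
  t_f <- as.integer(factor(truth))
  e_f <- as.integer(factor(estimate))
  tab <- table(t_f, e_f)
  nr <- nrow(tab); nc <- ncol(tab)
  # match the smaller side into the larger by exhaustive injective search
  M <- if (nr <= nc) tab else t(tab)
  small <- nrow(M); large <- ncol(M)
  if (small > 9L)
    stop("too many clusters for exhaustive matching (> 9 on the smaller side)",
         call. = FALSE)
  best <- 0
  assign_next <- function(row, used, matched) {
    if (row > small) {
      best <<- max(best, matched)
      return(invisible())
    }
    # upper bound prune: remaining rows can add at most their row maxima
    bound <- matched + sum(apply(M[row:small, , drop = FALSE], 1L, max))
    if (bound <= best) return(invisible())
    for (j in seq_len(large)) {
      if (!used[j]) {
        used[j] <- TRUE
        assign_next(row + 1L, used, matched + M[row, j])
        used[j] <- FALSE
      }
    }
  }
  assign_next(1L, rep(FALSE, large), 0)
  100 * best / length(truth)
}
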