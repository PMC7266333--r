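#' Domain names used throughout the package
#'
#' The six functional domains of the milestone programme, in the fixed
#' column order used by [logit_areas()] and the pipeline outputs.
#' @return Character vector of length 6.
#' @export
domain_names <- function() {
  c("auditory", "hands", "movement", "speech", "tactile", "vision")
}

#' Gold-standard reference trace
#'
#' Posterior-mean sequence of a hypothetical child who achieves every
#' milestone, starting from the uniform `Beta(1, 1)` prior: entry `i`
#' equals `(i + 1) / (i + 2)`, increasing towards 1.
#'
#' @param n Number of milestones (>= 1).
#' @return Numeric vector of length `n`.
#' @examples
#' reference_trace(3)  # 2/3, 3/4, 4/5
#' @export
reference_trace <- function(n) {
  if (!is.numeric(n) || length(n) != 1L || n < 1 || n != round(n))
    stop("'n' must be a positive integer", call. = FALSE)
  i <- seq_len(n)
  (i + 1) / (i + 2)
}

#' Rescaled area between a child's trace and the reference
#'
#' Both traces are step functions over the milestone axis, constant on unit
#' intervals between consecutive milestone indices. With unit spacing
#' `t_i = i` and rescaling by the number of observed milestones `w = n`,
#' the area between the two step functions reduces to the mean absolute
#' difference of the posterior means:
#' `area = (1/w) * sum_i |F2(t_i) - F1(t_i)|`.
#' The result lies in `[0, 1]`; 0 means the child matched the gold standard
#' at every observed milestone.
#'
#' @param child Numeric vector of the child's posterior means, or a
#'   [posterior_trace()] data frame.
#' @param ref Reference posterior means. Defaults to
#'   `reference_trace(length(child))`; a longer reference is truncated to
#'   the child's length.
#' @return A single number in `[0, 1]`.
#' @examples
#' area_between(posterior_trace(c(1, 1, 1)))      # 0
#' area_between(c(1/3, 1/4), c(2/3, 3/4))         # 5/12
#' @export
area_between <- function(child, ref = NULL) {
  if (inherits(child, "posterior_trace") || is.data.frame(child))
    child <- child$post_mean
  n <- length(child)
  if (n == 0L) stop("empty child trace", call. = FALSE)
  if (is.null(ref)) ref <- reference_trace(n)
  if (inherits(ref, "posterior_trace") || is.data.frame(ref)) ref <- ref$post_mean
  if (length(ref) < n)
    stop("reference trace shorter than child trace", call. = FALSE)
  ref <- ref[seq_len(n)]
  mean(abs(ref - child))
}

#' Per-domain areas for a cohort
#'
#' Computes, for every child x domain, the rescaled area between the
#' child's posterior-mean trace and a gold-standard reference of matching
#' length.
#'
#' @param cohort Cohort data frame (see [read_cohort()]).
#' @param allow_gaps Passed to [posterior_trace()].
#' @return Data frame with columns `child_id`, `domain`, `w` (number of
#'   observed milestones) and `area`.
#' @export
cohort_areas <- function(cohort, allow_gaps = FALSE) {
  validate_cohort(cohort)
  parts <- split(cohort, list(cohort$child_id, cohort$domain), drop = TRUE)
  out <- lapply(parts, function(d) {
    tr <- posterior_trace(d, allow_gaps = allow_gaps)
    data.frame(child_id = as.character(d$child_id[1]),
               domain = as.character(d$domain[1]),
               w = nrow(tr),
               area = area_between(tr))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res[order(res$child_id, res$domain), , drop = FALSE]
}

#' Logit-transformed feature matrix of domain areas
#'
#' The raw areas live on `[0, 1]` and are typically highly positively
#' skewed, with many values at or near 0. For clustering they are mapped to
#' the real line with the logit transform after clamping to
#' `[eps, 1 - eps]` so that exact zeros (children matching the gold
#' standard) stay finite.
#'
#' @param areas Either the long data frame produced by [cohort_areas()]
#'   (columns `child_id`, `domain`, `area`) or a numeric matrix/data frame
#'   of areas with one column per domain.
#' @param eps Clamp width in `(0, 0.5)`; default `1e-3`.
#' @return Numeric matrix, one row per child (rownames = child ids), one
#'   column per domain in the fixed order of [domain_names()] (long input)
#'   or the input's column order (wide input).
#' @examples
#' logit_areas(matrix(c(0.5, 5/12), 1, 2,
#'                    dimnames = list("c1", c("speech", "vision"))))
#' @export
logit_areas <- function(areas, eps = 1e-3) {
  if (!is.numeric(eps) || length(eps) != 1L || eps <= 0 || eps >= 0.5)
    stop("'eps' must be in (0, 0.5)", call. = FALSE)
  if (is.data.frame(areas) && all(c("child_id", "domain", "area") %in% names(areas))) {
    doms <- sort(unique(as.character(areas$domain)))
    if (all(doms %in% domain_names())) doms <- intersect(domain_names(), doms)
    ids <- unique(as.character(areas$child_id))
    m <- matrix(NA_real_, length(ids), length(doms),
                dimnames = list(ids, doms))
    m[cbind(as.character(areas$child_id), as.character(areas$domain))] <- areas$area
    if (anyNA(m))
      stop("missing child x domain area(s); complete sequences are required",
           call. = FALSE)
  } else {
    m <- as.matrix(areas)
  }
  if (any(m < 0 | m > 1)) stop("areas must lie in [0, 1]", call. = FALSE)
  m <- pmin(pmax(m, eps), 1 - eps)
  log(m / (1 - m))
}
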