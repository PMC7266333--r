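#' Posterior similarity matrix
#'
#' Because the label-switching moves deliberately shuffle component labels
#' across iterations, the most frequent label per observation is
#' meaningless; only co-membership is identifiable. The posterior
#' similarity matrix `S[i, j]` records the proportion of pooled
#' post-burn-in iterations in which observations `i` and `j` carried the
#' same allocation label.
#'
#' @param traces A `dpmm_chain` or list of them (all on the same
#'   observations).
#' @param burn_in Fraction of each chain's stored allocations to discard
#'   from the front; default 0.5.
#' @return Symmetric n x n matrix with unit diagonal, entries in
#'   `[0, 1]`.
#' @export
psm <- function(traces, burn_in = 0.5) {
  if (inherits(traces, "dpmm_chain")) traces <- list(traces)
  if (!length(traces)) stop("no chains supplied", call. = FALSE)
  if (!is.numeric(burn_in) || burn_in < 0 || burn_in >= 1)
    stop("'burn_in' must be in [0, 1)", call. = FALSE)
  n <- ncol(traces[[1L]]$z)
  if (any(vapply(traces, function(tr) ncol(tr$z), 0L) != n))
    stop("chains cover different numbers of observations", call. = FALSE)
  S <- matrix(0, n, n)
  total <- 0L
  for (tr in traces) {
    m <- nrow(tr$z)
    drop <- floor(burn_in * m)
    if (m - drop < 1L)
      stop("no post-burn-in iterations left in a chain", call. = FALSE)
    for (r in (drop + 1L):m) {
      zt <- tr$z[r, ]
      S <- S + outer(zt, zt, FUN = "==")
      total <- total + 1L
    }
  }
  S <- S / total
  diag(S) <- 1
  S
}

#' Partitioning around medoids on a dissimilarity matrix
#'
#' Thin wrapper around [cluster::pam()] (BUILD + SWAP phases run to
#' convergence) returning the pieces the consensus pipeline needs. The
#' returned partition is locally optimal: no single medoid swap lowers the
#' total dissimilarity of objects to their nearest medoid.
#'
#' @param D Symmetric dissimilarity matrix with zero diagonal.
#' @param k Number of medoids, `2 <= k < n`.
#' @return Object of class `consensus_clustering`: list with `k`,
#'   `medoids` (indices), `assignment`, `objective` (sum of
#'   dissimilarities to assigned medoids) and `avg_silhouette`.
#' @export
pam_medoids <- function(D, k) {
  D <- as.matrix(D)
  n <- nrow(D)
  if (!isSymmetric(unname(D), tol = 1e-8) || any(abs(diag(D)) > 1e-12))
    stop("'D' must be symmetric with zero diagonal", call. = FALSE)
  if (k < 2L || k >= n) stop("'k' must satisfy 2 <= k < n", call. = FALSE)
  fit <- cluster::pam(D, k = k, diss = TRUE, cluster.only = FALSE)
  medoids <- as.integer(fit$id.med)
  assignment <- as.integer(fit$clustering)
  structure(list(k = k, medoids = medoids, assignment = assignment,
                 objective = sum(D[cbind(seq_len(n), medoids[assignment])]),
                 avg_silhouette = avg_silhouette(D, assignment)),
            class = "consensus_clustering")
}

#' @export
print.consensus_clustering <- function(x, ...) {
  cat(sprintf("Consensus clustering: k = %d, average silhouette %.3f\n",
              x$k, x$avg_silhouette))
  cat("  cluster sizes:", paste(tabulate(x$assignment, x$k), collapse = " "),
      "\n")
  invisible(x)
}

#' Average silhouette width of a partition
#'
#' Mean over observations of `s_i = (b_i - a_i) / max(a_i, b_i)`, where
#' `a_i` is the mean dissimilarity to the observation's own cluster and
#' `b_i` the smallest mean dissimilarity to another cluster. Observations
#' in singleton clusters contribute `s_i = 0` (Rousseeuw's convention).
#'
#' @param D Symmetric dissimilarity matrix.
#' @param assignment Integer cluster labels; at least two non-empty
#'   clusters.
#' @return A number in `[-1, 1]`.
#' @export
avg_silhouette <- function(D, assignment) {
  D <- as.matrix(D)
  assignment <- as.integer(factor(assignment))
  if (length(unique(assignment)) < 2L)
    stop("silhouette needs at least two clusters", call. = FALSE)
  sil <- cluster::silhouette(assignment, dmatrix = D)
  mean(sil[, "sil_width"])
}

#' Select the consensus clustering from a posterior similarity matrix
#'
#' Runs PAM on the dissimilarity `1 - S` for each `k` in
#' `k_min..min(k_max, n - 1)` and returns the clustering with the largest
#' average silhouette width; ties are broken towards smaller `k`
#' (parsimony).
#'
#' @param S Posterior similarity matrix from [psm()].
#' @param k_min,k_max Range of cluster counts to scan (defaults 2 and 20).
#' @return A `consensus_clustering` with an extra element
#'   `silhouette_by_k` (named numeric vector over the scanned `k`).
#' @export
select_clustering <- function(S, k_min = 2L, k_max = 20L) {
  S <- as.matrix(S)
  n <- nrow(S)
  if (n <= k_min) stop("need more observations than 'k_min'", call. = FALSE)
  D <- 1 - S
  diag(D) <- 0
  ks <- seq.int(k_min, min(k_max, n - 1L))
  fits <- lapply(ks, function(k) pam_medoids(D, k))
  sil <- vapply(fits, function(f) f$avg_silhouette, 0)
  names(sil) <- ks
  best <- fits[[which.max(sil)]]   # which.max takes the first (smallest k)
  best$silhouette_by_k <- sil
  best
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `sqrt(((n - 1) / n * W + B / n) / W)` with `W` the mean within-chain
#' variance and `B` `n` times the variance of the chain means. Values below
#' 1.1 are conventionally taken as converged; the statistic is applied to
#' the discrete occupied-component count `K` as if continuous. Identical
#' constant chains return 1 by convention.
#'
#' @param chains List (or matrix columns) of at least two equal-length
#'   scalar traces with at least two iterations each.
#' @return The PSRF (a single number >= sqrt((n - 1) / n)).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- lapply(seq_len(ncol(chains)),
                                          function(j) chains[, j])
  m <- length(chains)
  if (m < 2L) stop("need at least two chains", call. = FALSE)
  len <- lengths(chains)
  if (length(unique(len)) != 1L) stop("chains have unequal lengths", call. = FALSE)
  n <- len[1L]
  if (n < 2L) stop("chains need at least two iterations", call. = FALSE)
  W <- mean(vapply(chains, stats::var, 0))
  B <- n * stats::var(vapply(chains, mean, 0))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence diagnostics for a set of DPMM chains
#'
#' Applies [gelman_rubin()] to the post-burn-in traces of the occupied
#' component count `K` and the concentration parameter `alpha`.
#'
#' @param chains List of `dpmm_chain` objects (>= 2).
#' @param burn_in Fraction of each chain discarded from the front.
#' @return Named numeric vector `c(K = ..., alpha = ...)`.
#' @export
gr_diagnostics <- function(chains, burn_in = 0.5) {
  post <- function(x) x[(floor(burn_in * length(x)) + 1L):length(x)]
  c(K = gelman_rubin(lapply(chains, function(ch) post(ch$K))),
    alpha = gelman_rubin(lapply(chains, function(ch) post(ch$alpha))))
}
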