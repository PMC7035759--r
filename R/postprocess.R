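#' Merge illumination-split clusters
#'
#' Under varied illumination a single physical class (typically
#' leaves) can split into several mixture components with nearby
#' means. Components `i` and `j` are merged when the Euclidean
#' distance between their means is below `eps_m`; merging is closed
#' transitively (connected components of the under-threshold graph),
#' so the result does not depend on comparison order. A merged
#' cluster's mean is the weighted average of its members' means.
#'
#' @param mu k x p matrix of component means.
#' @param weights length-k non-negative weights (posterior mass or
#'   pixel counts), not all zero.
#' @param eps_m non-negative merge threshold (default 0.1).
#' @return An object of class `cluster_graph`: a list with
#'   `merge_map` (length-k integer map from original to merged index,
#'   surjective onto `1..k'`), `merged_means` (k' x p),
#'   `merged_weights` (length k'), `n_merged` (`k'`), and the inputs
#'   `component_means`, `component_weights`.
#' @export
merge_clusters <- function(mu, weights, eps_m = 0.1) {
  if (is.list(mu)) mu <- do.call(rbind, mu)
  k <- nrow(mu)
  weights <- as.numeric(weights)
  if (length(weights) != k) stop("one weight per component is required")
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be non-negative and not all zero")
  if (eps_m < 0) stop("eps_m must be non-negative")

  # union-find over the under-threshold graph
  parent <- seq_len(k)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (k > 1L && eps_m > 0) {
    d <- as.matrix(stats::dist(mu))
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      if (d[i, j] < eps_m) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      }
    }
  }
  roots <- vapply(seq_len(k), find, integer(1))
  merge_map <- match(roots, sort(unique(roots)))
  kp <- max(merge_map)

  merged_means <- matrix(NA_real_, kp, ncol(mu))
  merged_weights <- numeric(kp)
  for (g in seq_len(kp)) {
    members <- which(merge_map == g)
    w <- weights[members]
    if (sum(w) == 0) w <- rep(1, length(members))  # unweighted fallback
    merged_weights[g] <- sum(weights[members])
    merged_means[g, ] <- colSums(mu[members, , drop = FALSE] * w) / sum(w)
  }
  structure(list(merge_map = merge_map, merged_means = merged_means,
                 merged_weights = merged_weights, n_merged = kp,
                 component_means = mu, component_weights = weights),
            class = "cluster_graph")
}

#' @export
print.cluster_graph <- function(x, ...) {
  cat("cluster_graph:", length(x$merge_map), "components ->", x$n_merged,
      "merged clusters\n")
  cat("merge map:", paste(x$merge_map, collapse = " "), "\n")
  invisible(x)
}

#' Collapse posterior columns of merged clusters
#'
#' Sums the posterior membership columns of components that were
#' merged, conserving each pixel's total posterior mass.
#'
#' @param posteriors n x k posterior matrix.
#' @param graph a `cluster_graph` from [merge_clusters()].
#' @return n x k' posterior matrix over the merged clusters.
#' @export
merge_posteriors <- function(posteriors, graph) {
  posteriors <- as.matrix(posteriors)
  if (ncol(posteriors) != length(graph$merge_map))
    stop("posterior columns do not match the merge map")
  out <- matrix(0, nrow(posteriors), graph$n_merged)
  for (j in seq_along(graph$merge_map))
    out[, graph$merge_map[j]] <- out[, graph$merge_map[j]] + posteriors[, j]
  out
}

#' Flag anomaly clusters by total channel mean
#'
#' A cluster is an anomaly (e.g. a white field marker) when its
#' [total_channel_mean()] is at least `eps_a`. Anomaly clusters are
#' excluded from the candidate set before the panicle component is
#' identified, so in an image with a bright marker the panicle is the
#' component with the second-highest total mean.
#'
#' @param mu k' x p matrix of (merged) cluster means.
#' @param eps_a non-negative anomaly threshold (default 0.9).
#' @return Length-k' logical flags.
#' @export
detect_anomalies <- function(mu, eps_a = 0.9) {
  if (is.list(mu)) mu <- do.call(rbind, mu)
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1L)
  if (eps_a < 0) stop("eps_a must be non-negative")
  total_channel_mean(mu) >= eps_a
}
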