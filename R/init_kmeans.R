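# k-means++ center seeding: first center uniform, subsequent centers
# sampled with probability proportional to squared distance from the
# nearest chosen center.
.kmeanspp_centers <- function(X, k) {
  n <- nrow(X)
  centers <- matrix(NA_real_, k, ncol(X))
  centers[1L, ] <- X[sample.int(n, 1L), ]
  if (k == 1L) return(centers)
  d2 <- rowSums(sweep(X, 2L, centers[1L, ], "-")^2)
  for (j in 2L:k) {
    idx <- if (sum(d2) > 0) sample.int(n, 1L, prob = d2) else sample.int(n, 1L)
    centers[j, ] <- X[idx, ]
    d2 <- pmin(d2, rowSums(sweep(X, 2L, centers[j, ], "-")^2))
  }
  centers
}

# Nearest-center hard assignment (fallback path for degenerate inputs
# where stats::kmeans refuses the seeded centers).
.assign_nearest <- function(X, centers) {
  d <- vapply(seq_len(nrow(centers)),
              function(j) rowSums(sweep(X, 2L, centers[j, ], "-")^2),
              numeric(nrow(X)))
  max.col(-d, ties.method = "first")
}

# Run k-means with plus-plus seeding and a few restarts, keeping the
# lowest within-cluster sum of squares. Empty clusters are re-seeded at
# the point farthest from its assigned center.
.run_kmeans <- function(X, k, seed, restarts = 3L, iter_max = 100L) {
  set.seed(seed)
  best <- NULL
  for (r in seq_len(restarts)) {
    centers <- .kmeanspp_centers(X, k)
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(X, centers, iter.max = iter_max)),
      error = function(e) NULL)
    if (is.null(fit)) {
      # degenerate data (e.g. duplicated seeded centers): one nearest-
      # center pass, re-seeding empty clusters at the farthest point
      z <- .assign_nearest(X, centers)
      for (j in seq_len(k)) {
        if (!any(z == j)) {
          dmin <- rowSums((X - centers[z, , drop = FALSE])^2)
          far <- which.max(dmin)
          centers[j, ] <- X[far, ]
          z <- .assign_nearest(X, centers)
        }
      }
      cen <- t(vapply(seq_len(k), function(j) {
        if (any(z == j)) colMeans(X[z == j, , drop = FALSE]) else centers[j, ]
      }, numeric(ncol(X))))
      wss <- sum((X - cen[z, , drop = FALSE])^2)
      fit <- list(cluster = z, centers = cen, tot.withinss = wss)
    }
    if (is.null(best) || fit$tot.withinss < best$tot.withinss) best <- fit
  }
  best
}

#' k-means initialization of the Gibbs sampler
#'
#' Clusters the pixels with Euclidean k-means (k-means++ seeding, a
#' small number of restarts keeping the lowest within-cluster sum of
#' squares) and converts the partition into the sampler's initial
#' state: initial weights are the cluster frequencies
#' `q_j = n_j / n`, initial means the within-cluster sample means, and
#' initial precisions the inverses of the within-cluster maximum
#' likelihood covariances (ridge-regularized when near-singular).
#'
#' @param X a [pixel_matrix()] (or a plain numeric matrix in \[0,1\]).
#' @param k number of clusters, at least 2.
#' @param seed integer RNG seed for the seeding and restarts.
#' @param ridge non-negative scalar added to a scatter matrix whose
#'   condition number exceeds `1e12` (or which has too few members to
#'   be full rank). With `ridge = 0` such a cluster is an error.
#' @param restarts number of k-means++ restarts.
#' @return A list of class `init_state` with elements `z0` (length-n
#'   labels), `q0`, `mu0` (k x p matrix), `phi0` (list of k precision
#'   matrices), `cluster_sizes`.
#' @export
kmeans_init <- function(X, k, seed = 1L, ridge = 1e-6, restarts = 3L) {
  dat <- if (inherits(X, "pixel_matrix")) X$data else as.matrix(X)
  n <- nrow(dat); p <- ncol(dat)
  k <- as.integer(k)
  if (k < 2L) stop("kmeans_init requires k >= 2")
  if (n < k) stop("need at least k pixels")
  fit <- .run_kmeans(dat, k, seed, restarts = restarts)
  z0 <- as.integer(fit$cluster)
  sizes <- tabulate(z0, nbins = k)
  q0 <- sizes / n
  mu0 <- matrix(NA_real_, k, p)
  phi0 <- vector("list", k)
  for (j in seq_len(k)) {
    idx <- which(z0 == j)
    nj <- length(idx)
    if (nj == 0L) {
      mu0[j, ] <- colMeans(dat)
      if (ridge <= 0)
        stop("cluster ", j, " is empty and ridge is zero: singular scatter")
      phi0[[j]] <- diag(1 / ridge, p)
      next
    }
    Xj <- dat[idx, , drop = FALSE]
    mu0[j, ] <- colMeans(Xj)
    C <- crossprod(sweep(Xj, 2L, mu0[j, ], "-")) / nj  # ML covariance
    if (nj < p + 1L && ridge <= 0)
      stop("cluster ", j, " has ", nj, " members (< p + 1 = ", p + 1L,
           ") and ridge is zero: singular scatter")
    phi0[[j]] <- tryCatch(.invert_spd(C, ridge),
                          error = function(e)
                            stop("cluster ", j, ": ", conditionMessage(e),
                                 call. = FALSE))
  }
  structure(list(z0 = z0, q0 = q0, mu0 = mu0, phi0 = phi0,
                 cluster_sizes = sizes),
            class = "init_state")
}

# Invert a symmetric PSD matrix, adding ridge * I when ill-conditioned.
.invert_spd <- function(C, ridge) {
  C <- (C + t(C)) / 2
  bad <- tryCatch(kappa(C, exact = TRUE) > 1e12, error = function(e) TRUE,
                  warning = function(w) TRUE)
  if (is.na(bad) || bad) {
    if (ridge <= 0) stop("singular scatter matrix with zero ridge")
    C <- C + diag(ridge, nrow(C))
  }
  ch <- tryCatch(chol(C), error = function(e) NULL)
  if (is.null(ch)) {
    if (ridge <= 0) stop("singular scatter matrix with zero ridge")
    ch <- chol(C + diag(ridge, nrow(C)))
  }
  chol2inv(ch)
}

#' k-means baseline segmentation
#'
#' Hard k-means labels for the pixels, used as the unsupervised
#' baseline segmenter; the panicle cluster is identified downstream by
#' [total_channel_mean()] ordering of the cluster centers. Shares its
#' seeding and restarts with [kmeans_init()], so for equal seeds the
#' labels coincide.
#'
#' @inheritParams kmeans_init
#' @param k number of clusters (k = 1 gives a single all-ones label).
#' @return Integer vector of length n with entries in `1..k`.
#' @export
kmeans_segment <- function(X, k, seed = 1L, restarts = 3L) {
  dat <- if (inherits(X, "pixel_matrix")) X$data else as.matrix(X)
  if (k == 1L) return(rep(1L, nrow(dat)))
  as.integer(.run_kmeans(dat, as.integer(k), seed, restarts = restarts)$cluster)
}
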