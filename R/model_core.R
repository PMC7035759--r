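#' paniclebayes: unsupervised Bayesian panicle segmentation
#'
#' Pixel-level rice panicle segmentation by a per-image multivariate
#' Gaussian mixture model learned with Gibbs sampling. See
#' [panicle_segment()] for the full pipeline and the package vignette
#' for the model.
#'
#' @keywords internal
"_PACKAGE"

#' Construct a pixel matrix
#'
#' A pixel matrix holds an image flattened row-major (top-left first)
#' into an `n x p` matrix of channel intensities normalized to
#' \[0, 1\], together with the image shape needed to fold labels and
#' masks back into two dimensions.
#'
#' @param data numeric matrix, `n x p`, all entries in \[0, 1\].
#'   Columns are channels (red, green, blue for RGB).
#' @param height,width positive integers with `height * width == nrow(data)`.
#' @param channel_names character vector of length `p`.
#' @return An object of class `pixel_matrix`: a list with elements
#'   `data`, `height`, `width`, `channel_names`.
#' @examples
#' px <- pixel_matrix(matrix(runif(12), 4, 3), height = 2, width = 2)
#' dim(px$data)
#' @export
pixel_matrix <- function(data, height, width,
                         channel_names = c("red", "green", "blue")[seq_len(ncol(data))]) {
  data <- as.matrix(data)
  storage.mode(data) <- "double"
  if (ncol(data) < 1L) stop("pixel matrix needs at least one channel")
  if (anyNA(data)) stop("pixel intensities must not contain NA")
  if (min(data) < 0 || max(data) > 1)
    stop("pixel intensities must lie in [0, 1]; got range [",
         signif(min(data), 4), ", ", signif(max(data), 4), "]")
  height <- as.integer(height); width <- as.integer(width)
  if (height < 1L || width < 1L || height * width != nrow(data))
    stop("height * width (", height * width, ") must equal the number of pixels (",
         nrow(data), ")")
  if (length(channel_names) != ncol(data))
    stop("channel_names must have one entry per column")
  structure(list(data = data, height = height, width = width,
                 channel_names = as.character(channel_names)),
            class = "pixel_matrix")
}

#' @export
print.pixel_matrix <- function(x, ...) {
  cat("pixel_matrix: ", x$height, " x ", x$width, " image, ",
      ncol(x$data), " channel(s) [", paste(x$channel_names, collapse = ", "),
      "], intensities in [", signif(min(x$data), 3), ", ",
      signif(max(x$data), 3), "]\n", sep = "")
  invisible(x)
}

#' Run configuration for the Gibbs sampler
#'
#' Bundles the sampler and pipeline settings. Defaults are the
#' published operating point: `k = 3` components, `n_iter = 150`
#' sweeps with burn-in `burn_in = 75` (iterations `burn_in..n_iter`
#' inclusive are retained), panicle posterior threshold
#' `p_th = 0.9990`, merge threshold `eps_m = 0.1` and anomaly
#' threshold `eps_a = 0.9` on the total-channel-mean scale.
#'
#' @param k number of mixture components, at least 2.
#' @param n_iter total Gibbs sweeps (the chain length `T`).
#' @param burn_in first retained iteration `T0`; samples from
#'   iterations `< burn_in` are discarded, so `n_iter - burn_in + 1`
#'   sweeps contribute to the posterior averages.
#' @param p_th panicle posterior threshold in \[0, 1\].
#' @param eps_m cluster-merge threshold on the Euclidean distance
#'   between component means.
#' @param eps_a anomaly threshold on the total channel mean (the sum
#'   of a component's per-channel means).
#' @param seed integer RNG seed; every random draw in a run consumes
#'   from the single stream this seeds.
#' @param ridge small non-negative scalar added to near-singular
#'   scatter matrices.
#' @return A list of class `run_config`.
#' @export
run_config <- function(k = 3L, n_iter = 150L, burn_in = 75L, p_th = 0.999,
                       eps_m = 0.1, eps_a = 0.9, seed = 1L, ridge = 1e-6) {
  k <- as.integer(k); n_iter <- as.integer(n_iter); burn_in <- as.integer(burn_in)
  if (k < 2L) stop("k must be at least 2")
  if (burn_in < 1L || burn_in > n_iter)
    stop("burn_in must satisfy 1 <= burn_in <= n_iter (got burn_in = ",
         burn_in, ", n_iter = ", n_iter, ")")
  if (p_th < 0 || p_th > 1) stop("p_th must lie in [0, 1]")
  if (eps_m < 0) stop("eps_m must be non-negative")
  if (eps_a < 0) stop("eps_a must be non-negative")
  if (ridge < 0) stop("ridge must be non-negative")
  structure(list(k = k, n_iter = n_iter, burn_in = burn_in, p_th = p_th,
                 eps_m = eps_m, eps_a = eps_a, seed = as.integer(seed),
                 ridge = ridge),
            class = "run_config")
}

#' Conjugate priors for the mixture
#'
#' The mixture weights carry a Dirichlet(`alpha`) prior; each
#' component mean a Gaussian prior with mean `tau` and precision
#' `omega`; the precision matrices carry the non-informative prior
#' proportional to `|Phi|^((p+1)/2)`. Defaults are the published
#' settings: `alpha_j = 1`, `tau_j = 0`, `omega_j = 1e-3 * I`.
#'
#' @param k number of components.
#' @param p number of channels.
#' @param alpha Dirichlet parameter; scalar (recycled) or length-k
#'   positive vector.
#' @param tau prior mean; scalar (recycled), length-p vector shared by
#'   all components, or a list of k length-p vectors.
#' @param omega prior precision of the mean; scalar `s` meaning
#'   `s * I`, a single p x p matrix shared by all components, or a
#'   list of k matrices. Must be symmetric positive definite.
#' @return A list of class `panicle_priors` with elements `alpha`
#'   (length k), `tau` (list of k vectors), `omega` (list of k
#'   matrices), and `precision_prior = "non-informative"`.
#' @export
panicle_priors <- function(k, p, alpha = 1, tau = 0, omega = 1e-3) {
  k <- as.integer(k); p <- as.integer(p)
  alpha <- rep_len(as.numeric(alpha), k)
  if (any(alpha <= 0)) stop("alpha entries must be positive")
  if (!is.list(tau)) tau <- rep(list(rep_len(as.numeric(tau), p)), k)
  if (length(tau) != k || any(lengths(tau) != p))
    stop("tau must give a length-", p, " prior mean for each of the ", k, " components")
  if (!is.list(omega)) {
    omega <- if (is.matrix(omega)) rep(list(omega), k)
             else rep(list(diag(as.numeric(omega), p)), k)
  }
  if (length(omega) != k) stop("omega must give one prior precision per component")
  for (j in seq_len(k)) {
    om <- as.matrix(omega[[j]])
    if (!isTRUE(all.equal(om, t(om), tolerance = 1e-10)))
      stop("omega[[", j, "]] is not symmetric")
    ch <- tryCatch(chol(om), error = function(e) NULL)
    if (is.null(ch)) stop("omega[[", j, "]] is not positive definite")
    omega[[j]] <- om
  }
  structure(list(alpha = alpha, tau = lapply(tau, as.numeric), omega = omega,
                 precision_prior = "non-informative"),
            class = "panicle_priors")
}

#' Multivariate Gaussian log-density in the precision parameterization
#'
#' Evaluates `log N_p(x; mu, phi^{-1})` directly from the precision
#' matrix `phi` — via its Cholesky factor for the log-determinant and
#' quadratic form — without ever inverting `phi`.
#'
#' @param x,mu numeric vectors of length p.
#' @param phi p x p symmetric positive definite precision matrix.
#' @return The log density (scalar).
#' @examples
#' gaussian_logpdf(c(0, 0, 0), c(0, 0, 0), diag(3)) # -(3/2) log(2 pi)
#' @export
gaussian_logpdf <- function(x, mu, phi) {
  R <- .chol_precision(phi)
  p <- length(x)
  if (length(mu) != p || nrow(R) != p)
    stop("x, mu and phi must share dimension p")
  u <- R %*% (x - mu)
  sum(log(diag(R))) - 0.5 * p * log(2 * pi) - 0.5 * sum(u * u)
}

# Cholesky of a precision matrix with an explicit parameterization error.
# Returns upper-triangular R with phi = t(R) %*% R.
.chol_precision <- function(phi) {
  phi <- as.matrix(phi)
  if (!isTRUE(all.equal(phi, t(phi), tolerance = 1e-8)))
    stop("precision matrix is not symmetric")
  tryCatch(chol(phi),
           error = function(e) stop("precision matrix is not positive definite",
                                    call. = FALSE))
}

# Vectorized log N_p(x_i; mu, phi^{-1}) for all rows of an n x p matrix.
.gaussian_logpdf_rows <- function(X, mu, phi) {
  R <- .chol_precision(phi)
  Xc <- sweep(X, 2L, mu, "-")
  U <- Xc %*% t(R)
  sum(log(diag(R))) - 0.5 * ncol(X) * log(2 * pi) - 0.5 * rowSums(U * U)
}

# Row-wise log-sum-exp of an n x k matrix.
.row_logsumexp <- function(L) {
  m <- L[cbind(seq_len(nrow(L)), max.col(L, ties.method = "first"))]
  m + log(rowSums(exp(L - m)))
}

#' Mixture log-density
#'
#' Evaluates `log sum_j q_j N_p(x; mu_j, phi_j^{-1})` by log-sum-exp,
#' so well-separated components cannot underflow.
#'
#' @param x length-p vector.
#' @param q length-k probability vector.
#' @param mu list of k length-p mean vectors (or a k x p matrix).
#' @param phi list of k p x p precision matrices.
#' @return The log mixture density (scalar).
#' @export
mixture_logpdf <- function(x, q, mu, phi) {
  if (is.matrix(mu)) mu <- asplit(mu, 1L)
  k <- length(q)
  if (k == 0L) stop("mixture must have at least one component")
  if (length(mu) != k || length(phi) != k)
    stop("q, mu and phi must agree on the number of components")
  lp <- vapply(seq_len(k), function(j) gaussian_logpdf(x, mu[[j]], phi[[j]]),
               numeric(1))
  lw <- ifelse(q > 0, log(q), -Inf)
  m <- max(lw + lp)
  if (!is.finite(m)) return(-Inf)
  m + log(sum(exp(lw + lp - m)))
}

#' Total channel mean of a component
#'
#' The sum of a component's per-channel mean intensities,
#' `m = sum_j mu_j`. Components are ordered by this statistic: the
#' panicle class has the largest total mean among plant/background
#' classes, and a component with total mean at or above the anomaly
#' threshold `eps_a` is treated as an anomaly object (e.g. a white
#' field marker).
#'
#' @param mu numeric vector of per-channel means, or a k x p matrix
#'   (one row per component).
#' @return A scalar, or a length-k vector for matrix input.
#' @examples
#' total_channel_mean(c(0.3, 0.3, 0.3)) # 0.9
#' @export
total_channel_mean <- function(mu) {
  if (is.matrix(mu)) rowSums(mu) else sum(mu)
}
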