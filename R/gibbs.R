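#' Draw the mixture weights from their full conditional
#'
#' One draw of `q | z ~ Dirichlet(alpha + n)` where `n_j` counts the
#' pixels currently labeled `j`. Components with no pixels receive
#' mass through their `alpha_j` alone. Sampled as normalized
#' independent Gamma draws.
#'
#' @param z integer labels in `1..k`.
#' @param alpha length-k positive Dirichlet parameter.
#' @param k number of components (defaults to `length(alpha)`).
#' @return Length-k probability vector summing to 1.
#' @export
sample_q <- function(z, alpha, k = length(alpha)) {
  if (any(alpha <= 0)) stop("alpha entries must be positive")
  n_j <- tabulate(z, nbins = k)
  g <- stats::rgamma(k, shape = alpha + n_j, rate = 1)
  g / sum(g)
}

#' Draw a component precision from its Wishart full conditional
#'
#' One draw of `Phi_j | mu_j, X_j ~ W_p(S_j^{-1}, n_j)` with scatter
#' `S_j = sum_i (x_i - mu_j)(x_i - mu_j)^T` over the component's
#' pixels, via the Bartlett construction ([stats::rWishart()]). When
#' `n_j < p` or `S_j` is singular, `S_j` is replaced by
#' `S_j + ridge * I` and the degrees of freedom raised to `p` so the
#' draw stays positive definite.
#'
#' @param S p x p scatter matrix.
#' @param n_j number of pixels in the component (must be >= 1; an
#'   empty component is signalled as a condition of class
#'   `paniclebayes_empty_component` so the caller can retain the
#'   previous precision).
#' @param ridge non-negative regularizer.
#' @return A p x p symmetric positive definite precision matrix.
#' @export
sample_precision <- function(S, n_j, ridge = 1e-6) {
  S <- as.matrix(S)
  p <- nrow(S)
  if (n_j == 0L)
    stop(errorCondition("empty component: no pixels to form the Wishart scatter",
                        class = "paniclebayes_empty_component"))
  df <- n_j
  ch <- if (n_j >= p) tryCatch(chol((S + t(S)) / 2), error = function(e) NULL)
        else NULL
  if (is.null(ch) ||
      !all(diag(ch) > sqrt(.Machine$double.eps) * max(diag(ch), 1))) {
    S <- (S + t(S)) / 2 + diag(ridge, p)
    ch <- chol(S)
    df <- max(n_j, p)
  }
  scale <- chol2inv(ch)  # S^{-1}
  W <- stats::rWishart(1L, df, scale)[, , 1L]
  if (!is.matrix(W)) W <- matrix(W, 1L, 1L)  # p = 1 keeps matrix shape
  W
}

#' Draw a component mean from its Gaussian full conditional
#'
#' One draw of `mu_j | Phi_j, X_j ~ N_p(tau*, (Omega*)^{-1})` with
#' posterior precision `Omega* = n_j Phi_j + Omega_j` and posterior
#' mean `tau* = (Omega*)^{-1} (n_j Phi_j xbar_j + Omega_j tau_j)`.
#' With `n_j = 0` this reduces to the prior. The draw is generated in
#' the precision parameterization (`backsolve` against the Cholesky
#' factor of `Omega*`), avoiding an explicit covariance.
#'
#' @param phi p x p component precision.
#' @param xbar length-p component sample mean (ignored when `n_j = 0`).
#' @param n_j component pixel count (>= 0).
#' @param tau,omega Gaussian prior mean vector and precision matrix.
#' @return Length-p draw of the component mean.
#' @export
sample_mean <- function(phi, xbar, n_j, tau, omega) {
  p <- length(tau)
  omega_star <- n_j * phi + omega
  rhs <- omega %*% tau
  if (n_j > 0) rhs <- rhs + n_j * (phi %*% xbar)
  R <- .chol_precision(omega_star)
  tau_star <- backsolve(R, backsolve(R, rhs, transpose = TRUE))
  drop(tau_star) + drop(backsolve(R, stats::rnorm(p)))
}

# Per-pixel log joint log(q_j) + log N_p(x_i; mu_j, phi_j^{-1}) as an
# n x k matrix.
.label_logjoint <- function(X, q, mu, phi) {
  k <- length(q)
  L <- matrix(NA_real_, nrow(X), k)
  lw <- ifelse(q > 0, log(q), -Inf)
  for (j in seq_len(k))
    L[, j] <- lw[j] + .gaussian_logpdf_rows(X, mu[j, ], phi[[j]])
  L
}

#' Draw the labels from their full conditional
#'
#' Each pixel label is drawn independently from the categorical
#' distribution with probabilities proportional to
#' `q_j N_p(x_i; mu_j, phi_j^{-1})`, evaluated in log space and
#' normalized by log-sum-exp so no pixel can underflow to an all-zero
#' likelihood. Sufficient statistics for the new partition are
#' returned alongside.
#'
#' @param X a [pixel_matrix()] or numeric matrix.
#' @param q length-k weights.
#' @param mu k x p matrix of component means.
#' @param phi list of k precision matrices.
#' @return A list with `z` (length-n integer labels) and `stats`, a
#'   list with per-component counts `n_j`, sample means `xbar` (k x p,
#'   `NA` rows for empty components) and scatter matrices `S` about
#'   the component means.
#' @export
sample_labels <- function(X, q, mu, phi) {
  dat <- if (inherits(X, "pixel_matrix")) X$data else as.matrix(X)
  L <- .label_logjoint(dat, q, mu, phi)
  P <- exp(L - .row_logsumexp(L))
  k <- length(q)
  cp <- P
  if (k > 1L) for (j in 2L:k) cp[, j] <- cp[, j - 1L] + cp[, j]
  u <- stats::runif(nrow(dat)) * cp[, k]
  z <- 1L + as.integer(rowSums(u > cp))
  z[z > k] <- k
  list(z = z, stats = .suff_stats(dat, z, mu, k))
}

# Counts, sample means, and scatter about mu for each component.
.suff_stats <- function(dat, z, mu, k) {
  p <- ncol(dat)
  n_j <- tabulate(z, nbins = k)
  xbar <- matrix(NA_real_, k, p)
  S <- vector("list", k)
  for (j in seq_len(k)) {
    if (n_j[j] == 0L) { S[[j]] <- matrix(0, p, p); next }
    Xj <- dat[z == j, , drop = FALSE]
    xbar[j, ] <- colMeans(Xj)
    S[[j]] <- crossprod(sweep(Xj, 2L, mu[j, ], "-"))
  }
  list(n_j = n_j, xbar = xbar, S = S)
}

#' Run the Gibbs sampler
#'
#' Executes `n_iter` sweeps of the four full-conditional updates: the
#' weights given the labels, then per component the precision given
#' the current mean and the mean given the new precision, then the
#' labels given everything. From iteration `burn_in` onward the
#' components are relabeled into decreasing [total_channel_mean()]
#' order before label indicators are accumulated — the identifiability
#' rule that defeats label switching — and the indicator sums estimate
#' the per-pixel posterior membership probabilities.
#'
#' An empty component keeps its previous precision and draws its mean
#' from the prior. All randomness flows through one stream seeded from
#' `config$seed`, so equal configurations reproduce the trace exactly.
#'
#' @param X a [pixel_matrix()] or numeric matrix of pixels.
#' @param init initial state from [kmeans_init()] (or a compatible
#'   list with `z0`, `q0`, `mu0`, `phi0`).
#' @param priors a [panicle_priors()] object.
#' @param config a [run_config()] object.
#' @param frozen if `TRUE`, the weights, means and precisions are held
#'   at their initial values and only the labels are resampled — the
#'   closed-form oracle mode used to validate the posterior averaging.
#' @param store_trace if `TRUE`, keep the per-iteration `q`, `mu`,
#'   `phi` draws (memory permitting); the posterior indicator counts
#'   and retained-sweep parameter means are always kept.
#' @return An object of class `gibbs_trace`: a list with
#'   `posterior_counts` (n x k integer matrix; each row sums to the
#'   number of retained sweeps), `retained`, `n_iter`, `burn_in`, `k`,
#'   `mu_mean`/`phi_mean`/`q_mean` (averages over retained sweeps,
#'   after relabeling), `final` (last state), and optionally `states`.
#' @export
run_chain <- function(X, init, priors, config, frozen = FALSE,
                      store_trace = FALSE) {
  dat <- if (inherits(X, "pixel_matrix")) X$data else as.matrix(X)
  n <- nrow(dat); p <- ncol(dat)
  k <- config$k
  if (length(init$q0) != k || nrow(init$mu0) != k)
    stop("init and config disagree on k")
  if (length(priors$alpha) != k)
    stop("priors and config disagree on k")
  set.seed(config$seed)

  z <- as.integer(init$z0)
  q <- as.numeric(init$q0)
  mu <- init$mu0
  phi <- init$phi0
  counts <- matrix(0L, n, k)
  mu_sum <- matrix(0, k, p)
  q_sum <- numeric(k)
  phi_sum <- rep(list(matrix(0, p, p)), k)
  retained <- 0L
  states <- if (store_trace) vector("list", config$n_iter) else NULL

  for (itr in seq_len(config$n_iter)) {
    if (!frozen) {
      q <- tryCatch(sample_q(z, priors$alpha, k),
                    error = function(e) stop("iteration ", itr, ": ",
                                             conditionMessage(e), call. = FALSE))
      st <- .suff_stats(dat, z, mu, k)
      for (j in seq_len(k)) {
        if (st$n_j[j] == 0L) {
          # empty component: keep previous precision, draw mean from prior
          mu[j, ] <- sample_mean(phi[[j]], NULL, 0L, priors$tau[[j]],
                                 priors$omega[[j]])
          next
        }
        phi[[j]] <- tryCatch(
          sample_precision(st$S[[j]], st$n_j[j], config$ridge),
          error = function(e) stop("iteration ", itr, ", component ", j, ": ",
                                   conditionMessage(e), call. = FALSE))
        mu[j, ] <- sample_mean(phi[[j]], st$xbar[j, ], st$n_j[j],
                               priors$tau[[j]], priors$omega[[j]])
      }
    }
    lab <- sample_labels(dat, q, mu, phi)
    z <- lab$z

    if (itr >= config$burn_in) {
      ord <- order(total_channel_mean(mu), decreasing = TRUE)
      if (!identical(ord, seq_len(k))) {
        relab <- integer(k); relab[ord] <- seq_len(k)
        q <- q[ord]; mu <- mu[ord, , drop = FALSE]; phi <- phi[ord]
        z <- relab[z]
      }
      retained <- retained + 1L
      for (j in seq_len(k)) counts[, j] <- counts[, j] + (z == j)
      mu_sum <- mu_sum + mu
      q_sum <- q_sum + q
      for (j in seq_len(k)) phi_sum[[j]] <- phi_sum[[j]] + phi[[j]]
    }
    if (store_trace)
      states[[itr]] <- list(q = q, mu = mu, phi = phi, iteration = itr)
  }

  structure(list(posterior_counts = counts, retained = retained,
                 n_iter = config$n_iter, burn_in = config$burn_in, k = k,
                 mu_mean = mu_sum / retained, q_mean = q_sum / retained,
                 phi_mean = lapply(phi_sum, function(m) m / retained),
                 final = list(z = z, q = q, mu = mu, phi = phi),
                 states = states),
            class = "gibbs_trace")
}

#' @export
print.gibbs_trace <- function(x, ...) {
  cat("gibbs_trace: k =", x$k, "components,", x$n_iter, "sweeps,",
      x$retained, "retained (burn-in", x$burn_in, ")\n")
  m <- total_channel_mean(x$mu_mean)
  cat("posterior-mean total channel means:",
      paste(signif(m, 4), collapse = ", "), "\n")
  invisible(x)
}

#' Posterior membership probabilities from a chain
#'
#' The Monte Carlo estimate of `Pr(z_i = j | X)`: the indicator counts
#' accumulated over the retained sweeps, divided by their number.
#' Rows sum to one.
#'
#' @param trace a `gibbs_trace` from [run_chain()].
#' @return An n x k matrix of posterior probabilities.
#' @export
posterior_probabilities <- function(trace) {
  if (!inherits(trace, "gibbs_trace")) stop("expected a gibbs_trace")
  trace$posterior_counts / trace$retained
}
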