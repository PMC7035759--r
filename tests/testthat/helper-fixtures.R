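# Shared test helpers: small synthetic class sets, permutation
# matching for mixture components, and batch-means Monte Carlo SEs.

# Three well-separated classes (>= 0.2 per channel between every pair),
# rare bright class first so it can play the panicle role.
separated_classes <- function(prev = c(0.06, 0.47, 0.47), sd = 0.04) {
  list(
    scene_class("panicle", c(0.70, 0.72, 0.68), sd = sd, prevalence = prev[1]),
    scene_class("leaf", c(0.40, 0.45, 0.38), sd = sd, prevalence = prev[2]),
    scene_class("background", c(0.15, 0.18, 0.12), sd = sd, prevalence = prev[3]))
}

# Best-permutation match of estimated component means (k x p) against
# true means; returns the permutation minimizing the max abs error.
best_permutation <- function(est, truth) {
  k <- nrow(truth)
  perms <- .permutations(k)
  errs <- vapply(perms, function(pm) max(abs(est[pm, , drop = FALSE] - truth)),
                 numeric(1))
  perms[[which.min(errs)]]
}

.permutations <- function(k) {
  if (k == 1L) return(list(1L))
  out <- list()
  for (i in seq_len(k)) {
    for (rest in .permutations(k - 1L)) {
      v <- seq_len(k)[-i]
      out[[length(out) + 1L]] <- c(i, v[rest])
    }
  }
  out
}

# Batch-means standard error of an MCMC chain (robust to autocorrelation).
batch_se <- function(x, n_batches = 25L) {
  n <- length(x)
  bs <- floor(n / n_batches)
  means <- vapply(seq_len(n_batches),
                  function(b) mean(x[((b - 1L) * bs + 1L):(b * bs)]),
                  numeric(1))
  stats::sd(means) / sqrt(n_batches)
}

# Closed-form label probabilities (the categorical full conditional).
label_probs_oracle <- function(x, q, mu, phi) {
  k <- length(q)
  lp <- vapply(seq_len(k),
               function(j) log(q[j]) + gaussian_logpdf(x, mu[j, ], phi[[j]]),
               numeric(1))
  w <- exp(lp - max(lp))
  w / sum(w)
}

# Adjusted Rand index between two labelings (mclust is the oracle).
ari <- function(a, b) mclust::adjustedRandIndex(a, b)
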