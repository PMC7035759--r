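#' Identify the panicle component
#'
#' The panicle class is the component whose mean has the largest
#' [total_channel_mean()] (panicle pixels are the brightest plant
#' class, ahead of leaves and dark background). Ties break to the
#' lowest index. Anomaly components should be excluded before calling
#' this (see [detect_anomalies()]).
#'
#' @param mu k x p matrix of component means (or list of vectors).
#' @return Integer component index.
#' @export
identify_panicle_component <- function(mu) {
  if (is.list(mu)) mu <- do.call(rbind, mu)
  if (is.null(dim(mu))) mu <- matrix(mu, nrow = 1L)
  if (nrow(mu) < 1L) stop("need at least one component")
  which.max(total_channel_mean(mu))
}

#' Maximum a posteriori pixel labels
#'
#' Per-pixel argmax over the posterior membership probabilities; ties
#' break to the lowest component index.
#'
#' @param posteriors n x k matrix with rows summing to 1.
#' @return Length-n integer labels in `1..k`.
#' @export
map_classify <- function(posteriors) {
  posteriors <- as.matrix(posteriors)
  max.col(posteriors, ties.method = "first")
}

#' Threshold classification of the panicle class
#'
#' Flags a pixel as panicle when its posterior probability of the
#' panicle component is at least `p_th` (ties at exactly `p_th` count
#' as panicle). Raising the threshold trades recall for precision;
#' the published operating point is `p_th = 0.9990`.
#'
#' @param posteriors n x k posterior matrix.
#' @param component panicle component index.
#' @param p_th threshold in \[0, 1\].
#' @return Length-n logical panicle mask.
#' @export
threshold_classify <- function(posteriors, component, p_th = 0.999) {
  if (p_th < 0 || p_th > 1) stop("p_th must lie in [0, 1]")
  posteriors <- as.matrix(posteriors)
  if (component < 1L || component > ncol(posteriors))
    stop("component index out of range")
  posteriors[, component] >= p_th
}
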