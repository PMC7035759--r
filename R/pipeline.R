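#' Segment panicle pixels in an image
#'
#' The full unsupervised pipeline: k-means++ initialization, Gibbs
#' sampling of the Gaussian mixture, post-burn-in posterior
#' probabilities, merging of illumination-split clusters, anomaly
#' detection, panicle identification by largest total channel mean
#' among the non-anomaly clusters, and both MAP and thresholded
#' classification.
#'
#' @param x a [pixel_matrix()], e.g. from [read_image()] or
#'   [generate_scene()].
#' @param config a [run_config()]; its defaults are the published
#'   operating point.
#' @param priors optional [panicle_priors()]; defaults to
#'   `alpha = 1`, `tau = 0`, `omega = 1e-3 * I`.
#' @param merge_weights weight the merged-cluster means by posterior
#'   mass (default) or pixel counts of the MAP partition.
#' @return An object of class `panicle_segmentation`: a list with
#'   `map_labels` (over merged clusters), `panicle_component`,
#'   `panicle_mask` (thresholded at `config$p_th`), `anomaly_mask`
#'   (MAP pixels of anomaly clusters), `threshold_used`,
#'   `component_total_means`, `posterior` (n x k' merged posterior),
#'   `panicle_posterior` (its panicle column), `cluster_graph`,
#'   `anomaly_flags`, `mu_mean` (pre-merge posterior means), `trace`,
#'   `height`, `width`, `config`.
#' @examples
#' \donttest{
#' sc <- generate_scene(scene_spec(height = 60, width = 60, seed = 7))
#' seg <- panicle_segment(sc$pixels, run_config(n_iter = 40, burn_in = 20))
#' mean(seg$panicle_mask)
#' }
#' @export
panicle_segment <- function(x, config = run_config(), priors = NULL,
                            merge_weights = c("posterior", "pixel")) {
  merge_weights <- match.arg(merge_weights)
  if (!inherits(x, "pixel_matrix")) stop("x must be a pixel_matrix")
  p <- ncol(x$data)
  if (is.null(priors)) priors <- panicle_priors(config$k, p)

  init <- kmeans_init(x, config$k, seed = config$seed, ridge = config$ridge)
  trace <- run_chain(x, init, priors, config)
  P <- posterior_probabilities(trace)

  w <- if (merge_weights == "posterior") colMeans(P)
       else tabulate(map_classify(P), nbins = config$k) / nrow(P)
  graph <- merge_clusters(trace$mu_mean, w, config$eps_m)
  Pm <- merge_posteriors(P, graph)
  means_m <- graph$merged_means

  flags <- detect_anomalies(means_m, config$eps_a)
  if (all(flags)) stop("no candidate panicle cluster: every cluster is ",
                       "flagged as anomaly at eps_a = ", config$eps_a)
  cand <- which(!flags)
  comp <- cand[identify_panicle_component(means_m[cand, , drop = FALSE])]

  map_labels <- map_classify(Pm)
  mask <- threshold_classify(Pm, comp, config$p_th)
  anomaly_mask <- map_labels %in% which(flags)

  structure(list(map_labels = map_labels, panicle_component = comp,
                 panicle_mask = mask, anomaly_mask = anomaly_mask,
                 threshold_used = config$p_th,
                 component_total_means = total_channel_mean(means_m),
                 posterior = Pm, panicle_posterior = Pm[, comp],
                 cluster_graph = graph, anomaly_flags = flags,
                 mu_mean = trace$mu_mean, trace = trace,
                 height = x$height, width = x$width, config = config),
            class = "panicle_segmentation")
}

#' @export
print.panicle_segmentation <- function(x, ...) {
  cat("panicle_segmentation: ", x$height, " x ", x$width, " image, ",
      x$config$k, " components -> ", x$cluster_graph$n_merged,
      " merged clusters\n", sep = "")
  cat("total channel means:",
      paste(signif(x$component_total_means, 4), collapse = ", "), "\n")
  if (any(x$anomaly_flags))
    cat("anomaly clusters:", paste(which(x$anomaly_flags), collapse = ", "), "\n")
  cat("panicle component:", x$panicle_component,
      " | mask covers", signif(100 * mean(x$panicle_mask), 4),
      "% of pixels at threshold", x$threshold_used, "\n")
  invisible(x)
}
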