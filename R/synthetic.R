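#' Define a synthetic class
#'
#' One class of a synthetic scene: a multivariate Gaussian over RGB
#' intensities plus a target prevalence.
#'
#' @param name class name (`"background"`, `"leaf"`, `"panicle"`,
#'   `"anomaly"`, or any label).
#' @param mean length-3 mean vector in \[0, 1\].
#' @param sd scalar or length-3 per-channel standard deviation
#'   (diagonal covariance), or alternatively supply `cov`.
#' @param prevalence target fraction of pixels.
#' @param cov optional full 3 x 3 covariance (overrides `sd`).
#' @return A list describing the class.
#' @export
scene_class <- function(name, mean, sd = 0.03, prevalence, cov = NULL) {
  mean <- as.numeric(mean)
  if (is.null(cov)) cov <- diag(rep_len(as.numeric(sd)^2, length(mean)))
  cov <- as.matrix(cov)
  if (is.null(tryCatch(chol(cov), error = function(e) NULL)))
    stop("class '", name, "': covariance is not positive definite")
  list(name = name, mean = mean, cov = cov, prevalence = prevalence)
}

#' Specify a synthetic canopy scene
#'
#' Describes a scene the generator can paint: a leaf/background field
#' with elliptical panicle blobs and, optionally, a rectangular
#' anomaly patch (a white field marker). Per-pixel RGB intensities are
#' drawn from the class's multivariate Gaussian and clipped to
#' \[0, 1\], mimicking camera saturation. Class prevalences must sum
#' to 1.
#'
#' @param height,width image dimensions in pixels.
#' @param classes list of [scene_class()] objects; must contain
#'   classes named `background`, `leaf` (one or more leaf classes is
#'   allowed, e.g. `leaf` and `leaf2` for an illumination split) and
#'   `panicle`; a class named `anomaly` is optional.
#' @param blob_spec list with `panicle_axes` (range of ellipse
#'   semi-axes in pixels) and `leaf_axes`; by default scaled to the
#'   image size (panicle blobs a few pixels across, leaf blobs about
#'   an order of magnitude larger).
#' @param seed integer RNG seed.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(height = 200L, width = 200L,
                       classes = default_scene_classes(),
                       blob_spec = NULL,
                       seed = 1L) {
  side <- min(height, width)
  if (is.null(blob_spec))
    blob_spec <- list(panicle_axes = c(2, max(3, round(side / 33))),
                      leaf_axes = c(max(4, round(side / 25)),
                                    max(6, round(side / 8))))
  prev <- vapply(classes, `[[`, numeric(1), "prevalence")
  if (abs(sum(prev) - 1) > 1e-8) stop("class prevalences must sum to 1")
  nms <- vapply(classes, `[[`, character(1), "name")
  for (need in c("background", "panicle"))
    if (!need %in% nms) stop("scene needs a class named '", need, "'")
  names(classes) <- nms
  amax <- max(blob_spec$panicle_axes, blob_spec$leaf_axes)
  if (pi * amax^2 > height * width)
    stop("blob axes exceed the image dimensions")
  structure(list(height = as.integer(height), width = as.integer(width),
                 classes = classes, blob_spec = blob_spec,
                 clip_policy = "clip", seed = as.integer(seed)),
            class = "scene_spec")
}

#' Default synthetic scene classes
#'
#' The study conditions the generator emulates: a dark background, a
#' mid-intensity green leaf canopy, bright panicle pixels at ~6%
#' prevalence (inside the 3.7--8.5% range observed in real canopy
#' squares), and optionally a white anomaly marker whose total channel
#' mean exceeds the 0.9 anomaly threshold. Total channel means order
#' panicle > leaf > background, and the panicle sum (0.83) stays below
#' the anomaly threshold. With `split_leaf = TRUE` the leaf class is
#' divided into a shaded and a lit component whose means are 0.082
#' apart in RGB space — below the 0.1 merge threshold.
#'
#' @param anomaly include the anomaly marker class.
#' @param split_leaf split the leaf class into two nearby components.
#' @return A list of [scene_class()] objects.
#' @export
default_scene_classes <- function(anomaly = FALSE, split_leaf = FALSE) {
  p_anom <- if (anomaly) 0.02 else 0
  p_leaf <- 0.47
  p_bg <- 1 - 0.06 - p_leaf - p_anom
  cls <- list(
    scene_class("background", c(0.05, 0.07, 0.05), sd = 0.015,
                prevalence = p_bg),
    scene_class("panicle", c(0.35, 0.30, 0.18), sd = 0.035,
                prevalence = 0.06))
  if (split_leaf) {
    cls <- c(cls, list(
      scene_class("leaf", c(0.10, 0.30, 0.12), sd = 0.025,
                  prevalence = p_leaf / 2),
      scene_class("leaf2", c(0.14, 0.36, 0.16), sd = 0.025,
                  prevalence = p_leaf / 2)))
  } else {
    cls <- c(cls, list(
      scene_class("leaf", c(0.12, 0.32, 0.14), sd = 0.03,
                  prevalence = p_leaf)))
  }
  if (anomaly)
    cls <- c(cls, list(
      scene_class("anomaly", c(0.92, 0.93, 0.91), sd = 0.02,
                  prevalence = p_anom)))
  cls
}

# Paint an ellipse of class `cls` onto the label matrix.
.paint_ellipse <- function(lab, cy, cx, a, b, cls) {
  h <- nrow(lab); w <- ncol(lab)
  rows <- max(1L, floor(cy - a)):min(h, ceiling(cy + a))
  cols <- max(1L, floor(cx - b)):min(w, ceiling(cx + b))
  rr <- outer((rows - cy) / a, rep(1, length(cols)))
  cc <- outer(rep(1, length(rows)), (cols - cx) / b)
  inside <- rr^2 + cc^2 <= 1
  lab[rows, cols][inside] <- cls
  lab
}

#' Generate a synthetic canopy scene
#'
#' Paints leaf ellipses over the background field, then panicle
#' ellipses, then (if specified) one rectangular anomaly patch, each
#' until the class reaches its target prevalence; then draws every
#' pixel's RGB vector from its class's Gaussian and clips to \[0, 1\].
#' Deterministic given the spec's seed.
#'
#' @param spec a [scene_spec()].
#' @return A list with `pixels` (a [pixel_matrix()]), `labels`
#'   (length-n integer truth labels, row-major, indexing
#'   `spec$classes`), `class_names`, `clip_fraction` (fraction of
#'   drawn intensities that were clipped), and `spec`.
#' @export
generate_scene <- function(spec) {
  set.seed(spec$seed)
  h <- spec$height; w <- spec$width; n <- h * w
  nms <- names(spec$classes)
  prev <- vapply(spec$classes, `[[`, numeric(1), "prevalence")
  bg <- which(nms == "background")
  lab <- matrix(bg, h, w)

  paint_until <- function(lab, cls_idx, axes) {
    target <- prev[cls_idx]
    guard <- 0L
    while (mean(lab == cls_idx) < target && guard < 10000L) {
      a <- stats::runif(1, axes[1], axes[2])
      b <- stats::runif(1, axes[1], axes[2])
      lab <- .paint_ellipse(lab, stats::runif(1, 1, h), stats::runif(1, 1, w),
                            a, b, cls_idx)
      guard <- guard + 1L
    }
    lab
  }
  for (j in which(startsWith(nms, "leaf")))
    lab <- paint_until(lab, j, spec$blob_spec$leaf_axes)
  for (j in which(nms == "panicle"))
    lab <- paint_until(lab, j, spec$blob_spec$panicle_axes)
  if ("anomaly" %in% nms) {
    j <- which(nms == "anomaly")
    side <- max(2L, round(sqrt(prev[j] * n)))
    if (side > min(h, w)) stop("anomaly patch exceeds the image")
    r0 <- sample.int(h - side + 1L, 1L); c0 <- sample.int(w - side + 1L, 1L)
    lab[r0:(r0 + side - 1L), c0:(c0 + side - 1L)] <- j
  }

  labels <- as.integer(t(lab))  # row-major flattening
  X <- matrix(NA_real_, n, 3L)
  clipped <- 0L
  for (j in seq_along(spec$classes)) {
    idx <- which(labels == j)
    if (length(idx) == 0L) next
    draws <- MASS::mvrnorm(length(idx), spec$classes[[j]]$mean,
                           spec$classes[[j]]$cov)
    draws <- matrix(draws, ncol = 3L)
    clipped <- clipped + sum(draws < 0 | draws > 1)
    X[idx, ] <- pmin(pmax(draws, 0), 1)
  }
  list(pixels = pixel_matrix(X, h, w), labels = labels, class_names = nms,
       clip_fraction = clipped / (3 * n), spec = spec)
}

#' Draw i.i.d. labeled mixture pixels
#'
#' Samples pixels from the exact generative mixture model (class
#' labels from the prevalences, intensities from the class Gaussians,
#' clipped to \[0, 1\]) with no spatial structure — the ground-truth
#' regime for parameter-recovery experiments, since the segmentation
#' model itself treats pixels as spatially independent.
#'
#' @param classes list of [scene_class()] objects.
#' @param n number of pixels.
#' @param seed integer RNG seed.
#' @return A list with `pixels` (a 1 x n [pixel_matrix()]), `labels`,
#'   `class_names`, `clip_fraction`.
#' @export
iid_pixels <- function(classes, n, seed = 1L) {
  set.seed(seed)
  prev <- vapply(classes, `[[`, numeric(1), "prevalence")
  if (abs(sum(prev) - 1) > 1e-8) stop("class prevalences must sum to 1")
  labels <- sample.int(length(classes), n, replace = TRUE, prob = prev)
  p <- length(classes[[1L]]$mean)
  X <- matrix(NA_real_, n, p)
  clipped <- 0L
  for (j in seq_along(classes)) {
    idx <- which(labels == j)
    if (length(idx) == 0L) next
    draws <- matrix(MASS::mvrnorm(length(idx), classes[[j]]$mean,
                                  classes[[j]]$cov), ncol = p)
    clipped <- clipped + sum(draws < 0 | draws > 1)
    X[idx, ] <- pmin(pmax(draws, 0), 1)
  }
  list(pixels = pixel_matrix(X, 1L, n,
                             channel_names = c("red", "green", "blue")[seq_len(p)]),
       labels = labels,
       class_names = vapply(classes, `[[`, character(1), "name"),
       clip_fraction = clipped / (p * n))
}
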