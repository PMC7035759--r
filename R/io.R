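#' Read an RGB image into a pixel matrix
#'
#' Reads a PNG (via the png package) or JPEG (via EBImage, when
#' installed) image, normalizes 8-bit channels to \[0, 1\], and
#' flattens it row-major from the top-left into a [pixel_matrix()].
#'
#' @param path image file path.
#' @param coerce if `TRUE`, a grayscale image is replicated to three
#'   channels and an alpha channel is dropped; if `FALSE` (default)
#'   such inputs are an error.
#' @return A [pixel_matrix()].
#' @export
read_image <- function(path, coerce = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("jpg", "jpeg")) {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("reading JPEG requires the EBImage package; convert to PNG or install it")
    img <- EBImage::imageData(EBImage::readImage(path))
    arr <- if (length(dim(img)) == 2L) array(img, c(dim(img), 1L))
           else aperm(img, c(2L, 1L, 3L)) # EBImage stores x,y
    # EBImage returns width x height; aperm above already fixed 3-d case
    if (length(dim(img)) == 2L) arr <- aperm(arr, c(2L, 1L, 3L))
  } else if (ext == "png") {
    arr <- png::readPNG(path)
    if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  } else {
    stop("unsupported image format '.", ext, "' (PNG or JPEG expected)")
  }
  nc <- dim(arr)[3L]
  if (nc == 4L) {
    if (!coerce) stop("image has an alpha channel; pass coerce = TRUE to drop it")
    arr <- arr[, , 1:3, drop = FALSE]
  } else if (nc %in% c(1L, 2L)) {
    if (!coerce) stop("image is grayscale; pass coerce = TRUE to replicate channels")
    g <- arr[, , 1L]
    arr <- array(c(g, g, g), c(dim(arr)[1:2], 3L))
  } else if (nc != 3L) {
    stop("expected 1-4 channels, got ", nc)
  }
  h <- dim(arr)[1L]; w <- dim(arr)[2L]
  data <- cbind(as.vector(t(arr[, , 1L])), as.vector(t(arr[, , 2L])),
                as.vector(t(arr[, , 3L])))
  pixel_matrix(pmin(pmax(data, 0), 1), h, w)
}

#' Write a binary mask as an 8-bit PNG
#'
#' Panicle pixels are written as 255, everything else as 0; the round
#' trip through [read_mask()] is lossless.
#'
#' @param mask logical vector of length `height * width`, row-major.
#' @param height,width image shape.
#' @param path output PNG path.
#' @return The path, invisibly.
#' @export
write_mask <- function(mask, height, width, path) {
  if (length(mask) != height * width)
    stop("mask length (", length(mask), ") must equal height * width (",
         height * width, ")")
  m <- matrix(as.numeric(mask), height, width, byrow = TRUE)
  png::writePNG(m, path)
  invisible(path)
}

#' Read a binary mask from a PNG
#'
#' Foreground (panicle) is any pixel above half intensity; multi-channel
#' masks are reduced by their first channel.
#'
#' @param path PNG file path.
#' @return A list with `mask` (row-major logical vector), `height`,
#'   `width`.
#' @export
read_mask <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 3L) arr <- arr[, , 1L]
  list(mask = as.vector(t(arr)) > 0.5, height = nrow(arr), width = ncol(arr))
}

#' Write a posterior probability map as plain text
#'
#' One row of tab-separated values per image row, at full double
#' precision ("%.17g") — the operating threshold 0.9990 lives in the
#' far tail, so the map must not be quantized.
#'
#' @param p numeric vector of length `height * width`, row-major.
#' @param height,width image shape.
#' @param path output path.
#' @return The path, invisibly.
#' @export
write_posterior_map <- function(p, height, width, path) {
  if (length(p) != height * width)
    stop("posterior map length must equal height * width")
  m <- matrix(sprintf("%.17g", p), height, width, byrow = TRUE)
  writeLines(apply(m, 1L, paste, collapse = "\t"), path)
  invisible(path)
}

#' Read a posterior probability map written by [write_posterior_map()]
#'
#' @param path file path.
#' @return A list with `p` (row-major numeric vector), `height`,
#'   `width`.
#' @export
read_posterior_map <- function(path) {
  rows <- strsplit(readLines(path), "\t", fixed = TRUE)
  m <- do.call(rbind, lapply(rows, as.numeric))
  list(p = as.vector(t(m)), height = nrow(m), width = ncol(m))
}
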