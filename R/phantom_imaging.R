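#' Phantom photograph container
#'
#' @param pixels numeric array \code{[rows, cols, 3]} of 8-bit RGB values
#'   (0-255).
#' @param scale pixels per millimetre.
#' @return a \code{phantom_image}.
#' @export
phantom_image <- function(pixels, scale = 86) {
  stopifnot(length(dim(pixels)) == 3L, dim(pixels)[3] == 3L)
  if (scale <= 0) stop("pixel scale must be positive")
  if (min(pixels) < 0 || max(pixels) > 255)
    stop("pixel channels must lie in [0, 255]")
  structure(list(pixels = pixels, scale = scale), class = "phantom_image")
}

#' @export
print.phantom_image <- function(x, ...) {
  cat(sprintf("<phantom_image> %d x %d px at %g px/mm\n",
              dim(x$pixels)[1], dim(x$pixels)[2], x$scale))
  invisible(x)
}

#' HSB threshold settings
#'
#' Pass bands on the ImageJ-style 0-255 hue/saturation/brightness scale.
#' The defaults keep pixels with hue at most 217, saturation at least 121
#' and brightness at least 68 (no dark background, so the brightness bound
#' is a minimum).  All three channels accept full (min, max) bands.
#'
#' @param hue_max,sat_min,bright_min primary one-sided bounds.
#' @param hue_min,sat_max,bright_max the remaining band edges.
#' @export
hsb_threshold_spec <- function(hue_max = 217, sat_min = 121, bright_min = 68,
                               hue_min = 0, sat_max = 255, bright_max = 255) {
  v <- c(hue_max, sat_min, bright_min, hue_min, sat_max, bright_max)
  if (any(v < 0 | v > 255)) stop("HSB thresholds must lie in [0, 255]")
  structure(list(hue = c(hue_min, hue_max), sat = c(sat_min, sat_max),
                 bright = c(bright_min, bright_max)),
            class = "hsb_threshold")
}

# reference colours for the synthetic thermochromic gel: pink background,
# magenta-family ablated region; chosen so the default thresholds separate
# the classes with a wide margin relative to the rendering noise
TCP_BACKGROUND <- c(252, 214, 228)
TCP_ABLATED <- c(168, 32, 204)

#' Render a synthetic thermochromic-phantom photograph
#'
#' Emulates a top-view photograph of an ablated thermochromic gel: a pink
#' background with a magenta region wherever the (projected) damage mask is
#' true, upsampled to the photographic pixel scale, with seeded Gaussian
#' channel noise.  Intended for round-trip testing of the HSB
#' quantification against a mask of known area.
#'
#' @param mask_slice logical matrix (top-view damage mask), rows = y,
#'   cols = x.
#' @param spacing_mm physical size of one mask cell, mm.
#' @param scale output pixels per millimetre.
#' @param noise_sd Gaussian channel noise standard deviation (8-bit units).
#' @param seed integer seed for the noise (required, for reproducibility).
#' @return a \code{\link{phantom_image}}.
#' @export
render_synthetic_tcp <- function(mask_slice, spacing_mm, scale = 86,
                                 noise_sd = 4, seed) {
  if (missing(seed)) stop("a seed is required for reproducible rendering")
  if (spacing_mm <= 0 || scale <= 0)
    stop("spacing and scale must be positive")
  mask_slice <- as.matrix(mask_slice)
  npx <- round(dim(mask_slice) * spacing_mm * scale)
  # map each output pixel centre back to a mask cell (nearest neighbour)
  row_cell <- pmin(dim(mask_slice)[1],
                   pmax(1L, ceiling((seq_len(npx[1]) - 0.5) / (spacing_mm * scale))))
  col_cell <- pmin(dim(mask_slice)[2],
                   pmax(1L, ceiling((seq_len(npx[2]) - 0.5) / (spacing_mm * scale))))
  up <- mask_slice[row_cell, col_cell, drop = FALSE]
  px <- array(0, c(npx, 3))
  for (ch in 1:3)
    px[, , ch] <- ifelse(up, TCP_ABLATED[ch], TCP_BACKGROUND[ch])
  if (noise_sd > 0)
    px <- px + withr::with_seed(seed, array(rnorm(length(px), 0, noise_sd),
                                            dim(px)))
  px <- round(pmin(pmax(px, 0), 255))  # array first: pmin/pmax keep its dims
  phantom_image(px, scale)
}

#' HSB colour thresholding
#'
#' Converts every pixel to hue/saturation/brightness on the 0-255 scale
#' (the hue is the standard colour-wheel angle scaled from 0-360 degrees)
#' and keeps pixels inside all three bands.
#'
#' @param image a \code{\link{phantom_image}}.
#' @param thr an \code{\link{hsb_threshold_spec}}.
#' @return logical matrix of passing pixels.
#' @export
hsb_threshold <- function(image, thr = hsb_threshold_spec()) {
  px <- image$pixels
  d <- dim(px)
  rgb <- rbind(as.vector(px[, , 1]), as.vector(px[, , 2]), as.vector(px[, , 3]))
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  hue <- hsv[1, ] * 255
  sat <- hsv[2, ] * 255
  bri <- hsv[3, ] * 255
  pass <- hue >= thr$hue[1] & hue <= thr$hue[2] &
    sat >= thr$sat[1] & sat <= thr$sat[2] &
    bri >= thr$bright[1] & bri <= thr$bright[2]
  matrix(pass, d[1], d[2])
}

#' Measure the thresholded ablated region
#'
#' Area from the passing-pixel count at the known pixel scale; length and
#' width from the bounding box of the largest connected component
#' (face connectivity), with length the larger box dimension.
#'
#' @param mask logical matrix from \code{\link{hsb_threshold}}.
#' @param scale pixels per millimetre.
#' @return list with \code{area_mm2}, \code{length_mm}, \code{width_mm}.
#' @export
measure_ablated_region <- function(mask, scale = 86) {
  if (scale <= 0) stop("pixel scale must be positive")
  if (!any(mask))
    return(list(area_mm2 = 0, length_mm = 0, width_mm = 0))
  area <- sum(mask) / scale^2
  comp <- label_components_cpp(c(dim(mask), 1L), as.vector(mask))
  best <- order(comp$sizes, decreasing = TRUE)[1]
  idx <- which(matrix(comp$labels == best, nrow(mask)), arr.ind = TRUE)
  span <- apply(idx, 2, function(v) diff(range(v)) + 1L) / scale
  list(area_mm2 = area, length_mm = max(span), width_mm = min(span))
}

#' Read a phantom photograph (PNG or TIFF)
#'
#' @param path file path; format chosen by extension.
#' @param scale pixels per millimetre of the photograph.
#' @return a \code{\link{phantom_image}}.
#' @export
read_phantom_image <- function(path, scale = 86) {
  ext <- tolower(tools::file_ext(path))
  arr <- switch(ext,
                png = png::readPNG(path),
                tif = , tiff = tiff::readTIFF(path),
                stop("unsupported image format: ", ext))
  if (length(dim(arr)) == 2L) arr <- array(rep(arr, 3), c(dim(arr), 3))
  phantom_image(round(arr[, , 1:3, drop = FALSE] * 255), scale)
}

#' Write a phantom image or mask (PNG or TIFF)
#'
#' @param image a \code{\link{phantom_image}} or a logical matrix (written
#'   as a binary mask).
#' @param path output path; format chosen by extension.
#' @export
write_phantom_image <- function(image, path) {
  arr <- if (inherits(image, "phantom_image")) image$pixels / 255
  else (as.matrix(image)) * 1.0
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         png = png::writePNG(arr, path),
         tif = , tiff = tiff::writeTIFF(arr, path),
         stop("unsupported image format: ", ext))
  invisible(path)
}
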