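#' Single-channel section image
#'
#' Pixel grid of one abdomen section plus calibration and provenance. The
#' coordinate convention places the origin at the center of the top-left
#' pixel, x increasing along columns (rightward) and y along rows (downward);
#' the um position of pixel `[row, col]` is
#' `((col - 1) * pixel_size, (row - 1) * pixel_size)`.
#'
#' @param pixels numeric matrix of nonnegative intensities, rows indexing y.
#' @param pixel_size calibration in um per pixel (default 0.207).
#' @param bit_depth 8 or 16; intensities must not exceed `2^bit_depth - 1`.
#' @param metadata named list, typically `fly_id`, `condition`, `section_id`.
#' @return a `section_image`.
#' @export
section_image <- function(pixels, pixel_size = 0.207, bit_depth = 8L,
                          metadata = list()) {
  pixels <- as.matrix(pixels)
  bit_depth <- as.integer(bit_depth)
  if (!(bit_depth %in% c(8L, 16L))) stop("bit_depth must be 8 or 16", call. = FALSE)
  if (!is.finite(pixel_size) || pixel_size <= 0) {
    stop("pixel_size must be > 0", call. = FALSE)
  }
  if (any(!is.finite(pixels)) || any(pixels < 0) ||
      any(pixels > 2^bit_depth - 1)) {
    stop(sprintf("pixel intensities must lie in [0, %d]", 2^bit_depth - 1),
         call. = FALSE)
  }
  structure(
    list(pixels = pixels, pixel_size = pixel_size, bit_depth = bit_depth,
         metadata = metadata),
    class = "section_image"
  )
}

#' @export
print.section_image <- function(x, ...) {
  cat(sprintf("<section_image> %d x %d px, %g um/px, %d-bit, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_size, x$bit_depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Render a fluorescence image of a point pattern
#'
#' Produces a synthetic section image: each ground-truth point becomes an
#' isotropic Gaussian blob of standard deviation `psf_sigma / pixel_size`
#' pixels and peak amplitude `peak_intensity`, additive Gaussian background
#' noise (`background_mean`, `background_sd`) covers the whole frame, and
#' pixels outside the window polygon carry background only (the tissue signal
#' is confined to the section). Intensities are rounded and clipped to the bit
#' depth. Uses the current R random number stream for the noise.
#'
#' @param pattern a [point_pattern()] (ground truth) whose window defines the
#'   tissue region.
#' @param spec the [scene_spec()] holding the rendering parameters.
#' @param margin clearance in um added beyond the window bounding box.
#' @return a [section_image()] carrying the pattern's metadata.
#' @export
render_section <- function(pattern, spec, margin = 15) {
  validate_scene_spec(spec)
  stopifnot(inherits(pattern, "point_pattern"))
  if (spec$peak_intensity < spec$background_mean) {
    warning("blob peak below background mean: signal is undetectable",
            call. = FALSE)
  }
  ps <- spec$pixel_size
  bb <- window_bbox(pattern$window)
  nx <- ceiling((bb[2] + margin) / ps) + 1
  ny <- ceiling((bb[4] + margin) / ps) + 1
  maxval <- 2^spec$bit_depth - 1

  signal <- matrix(0, nrow = ny, ncol = nx)
  sig_px <- spec$psf_sigma / ps
  r_px <- ceiling(5 * sig_px)
  pts <- pattern$points
  for (i in seq_len(nrow(pts))) {
    # pixel indices: x_um = (col-1)*ps
    c0 <- pts[i, 1] / ps + 1
    r0 <- pts[i, 2] / ps + 1
    cols <- max(1, floor(c0 - r_px)):min(nx, ceiling(c0 + r_px))
    rows <- max(1, floor(r0 - r_px)):min(ny, ceiling(r0 + r_px))
    gx <- exp(-((cols - c0)^2) / (2 * sig_px^2))
    gy <- exp(-((rows - r0)^2) / (2 * sig_px^2))
    signal[rows, cols] <- signal[rows, cols] +
      spec$peak_intensity * outer(gy, gx)
  }
  mask <- window_pixel_mask(pattern$window, ny, nx, ps)
  signal[!mask] <- 0

  bg <- matrix(stats::rnorm(ny * nx, spec$background_mean, spec$background_sd),
               nrow = ny, ncol = nx)
  img <- round(pmin(pmax(signal + bg, 0), maxval))
  section_image(img, pixel_size = ps, bit_depth = spec$bit_depth,
                metadata = pattern$metadata)
}

# Logical mask of pixels whose centers fall inside the window polygon.
# Only pixels within the window bounding box are tested.
window_pixel_mask <- function(window, ny, nx, pixel_size) {
  bb <- window_bbox(window)
  cols <- max(1, floor(bb[1] / pixel_size)):min(nx, ceiling(bb[2] / pixel_size) + 2)
  rows <- max(1, floor(bb[3] / pixel_size)):min(ny, ceiling(bb[4] / pixel_size) + 2)
  xs <- (cols - 1) * pixel_size
  ys <- (rows - 1) * pixel_size
  grid <- cbind(rep(xs, each = length(ys)), rep(ys, times = length(xs)))
  inside <- points_in_window(window, grid)
  mask <- matrix(FALSE, nrow = ny, ncol = nx)
  mask[rows, cols] <- matrix(inside, nrow = length(rows))
  mask
}
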