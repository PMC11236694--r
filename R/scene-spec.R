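#' Specification of a synthetic abdomen section scene
#'
#' A `scene_spec` bundles every parameter needed to simulate one abdomen
#' section: the geometry of the section window, the point process generating
#' hemocyte positions, and the fluorescence rendering model. Defaults emulate
#' the imaging regime of the real study: 0.207 um/px calibration, GFP-tagged
#' hemocytes of roughly 10 um diameter rendered as Gaussian blobs on a dim
#' noisy background.
#'
#' @param semi_axes numeric length-2, ellipse semi-axes of the section window
#'   in um. Both must be positive.
#' @param boundary_jitter radial perturbation amplitude of the window boundary
#'   as a fraction of the local radius; must lie in `[0, 0.5)` so the boundary
#'   stays a simple star-shaped polygon.
#' @param process_kind one of `"csr"` (homogeneous Poisson, "fed-like"),
#'   `"center_biased"` (radially thinned towards the centroid, "starved-like"),
#'   or `"thomas_cluster"` (Poisson parents with Gaussian-dispersed offspring).
#' @param intensity expected number of points per um^2 (csr and center_biased;
#'   realized counts are Poisson with mean `intensity * area`).
#' @param bias_exponent nonnegative exponent of the radial acceptance weight
#'   `(1 - d/dmax)^bias_exponent` used by `"center_biased"`; 0 recovers csr.
#' @param cluster_parent_intensity parents per um^2 (`"thomas_cluster"`).
#' @param cluster_mean_size expected offspring per parent.
#' @param cluster_sigma offspring dispersion around the parent, um.
#' @param psf_sigma standard deviation of the rendered Gaussian blob, um.
#' @param peak_intensity blob peak amplitude in intensity counts.
#' @param background_mean,background_sd Gaussian background noise parameters
#'   in counts.
#' @param pixel_size image calibration in um per pixel (default 0.207).
#' @param bit_depth image bit depth, 8 or 16.
#' @param n_vertices number of polygon vertices used to discretize the window
#'   boundary.
#'
#' @return an object of class `scene_spec` (a validated list).
#' @examples
#' spec <- scene_spec(semi_axes = c(120, 70), intensity = 0.002)
#' spec$process_kind
#' @export
scene_spec <- function(semi_axes = c(150, 90),
                       boundary_jitter = 0.12,
                       process_kind = c("csr", "center_biased", "thomas_cluster"),
                       intensity = 0.0025,
                       bias_exponent = 2,
                       cluster_parent_intensity = 2.5e-4,
                       cluster_mean_size = 10,
                       cluster_sigma = 10,
                       psf_sigma = 2,
                       peak_intensity = 180,
                       background_mean = 12,
                       background_sd = 4,
                       pixel_size = 0.207,
                       bit_depth = 8,
                       n_vertices = 180) {
  process_kind <- match.arg(process_kind)
  spec <- list(
    semi_axes = as.numeric(semi_axes),
    boundary_jitter = as.numeric(boundary_jitter),
    process_kind = process_kind,
    intensity = as.numeric(intensity),
    bias_exponent = as.numeric(bias_exponent),
    cluster_parent_intensity = as.numeric(cluster_parent_intensity),
    cluster_mean_size = as.numeric(cluster_mean_size),
    cluster_sigma = as.numeric(cluster_sigma),
    psf_sigma = as.numeric(psf_sigma),
    peak_intensity = as.numeric(peak_intensity),
    background_mean = as.numeric(background_mean),
    background_sd = as.numeric(background_sd),
    pixel_size = as.numeric(pixel_size),
    bit_depth = as.integer(bit_depth),
    n_vertices = as.integer(n_vertices)
  )
  class(spec) <- "scene_spec"
  validate_scene_spec(spec)
}

#' @rdname scene_spec
#' @param spec a `scene_spec` object to validate.
#' @export
validate_scene_spec <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  fail <- function(field, msg) {
    stop(sprintf("invalid scene_spec field '%s': %s", field, msg), call. = FALSE)
  }
  if (length(spec$semi_axes) != 2 || any(!is.finite(spec$semi_axes)) ||
      any(spec$semi_axes <= 0)) {
    fail("semi_axes", "must be two positive finite values (um)")
  }
  if (!is.finite(spec$boundary_jitter) || spec$boundary_jitter < 0 ||
      spec$boundary_jitter >= 0.5) {
    fail("boundary_jitter", "must lie in [0, 0.5)")
  }
  if (!is.finite(spec$intensity) || spec$intensity < 0) {
    fail("intensity", "must be a nonnegative density (points per um^2)")
  }
  if (!is.finite(spec$bias_exponent) || spec$bias_exponent < 0) {
    fail("bias_exponent", "must be >= 0")
  }
  if (!is.finite(spec$cluster_parent_intensity) || spec$cluster_parent_intensity < 0) {
    fail("cluster_parent_intensity", "must be >= 0")
  }
  if (!is.finite(spec$cluster_mean_size) || spec$cluster_mean_size < 0) {
    fail("cluster_mean_size", "must be >= 0")
  }
  if (!is.finite(spec$cluster_sigma) || spec$cluster_sigma <= 0) {
    fail("cluster_sigma", "must be > 0 (um)")
  }
  if (!is.finite(spec$psf_sigma) || spec$psf_sigma <= 0) {
    fail("psf_sigma", "must be > 0 (um)")
  }
  if (!is.finite(spec$peak_intensity) || spec$peak_intensity < 0) {
    fail("peak_intensity", "must be >= 0 counts")
  }
  if (!is.finite(spec$background_mean) || spec$background_mean < 0) {
    fail("background_mean", "must be >= 0 counts")
  }
  if (!is.finite(spec$background_sd) || spec$background_sd < 0) {
    fail("background_sd", "must be >= 0 counts")
  }
  if (!is.finite(spec$pixel_size) || spec$pixel_size <= 0) {
    fail("pixel_size", "must be > 0 (um/px)")
  }
  if (!(spec$bit_depth %in% c(8L, 16L))) {
    fail("bit_depth", "must be 8 or 16")
  }
  if (is.na(spec$n_vertices) || spec$n_vertices < 16) {
    fail("n_vertices", "must be an integer >= 16")
  }
  invisible(spec)
}

#' @export
print.scene_spec <- function(x, ...) {
  cat("<scene_spec>\n")
  cat(sprintf("  window   : ellipse %g x %g um, jitter %g (%d vertices)\n",
              x$semi_axes[1], x$semi_axes[2], x$boundary_jitter, x$n_vertices))
  cat(sprintf("  process  : %s, intensity %g pts/um^2\n",
              x$process_kind, x$intensity))
  cat(sprintf("  rendering: psf sigma %g um, peak %g, background %g +/- %g, %g um/px, %d-bit\n",
              x$psf_sigma, x$peak_intensity, x$background_mean,
              x$background_sd, x$pixel_size, x$bit_depth))
  invisible(x)
}
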