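#' Abdomen section window
#'
#' An `abdomen_window` represents the boundary of one abdomen section as a
#' simple closed polygon in micrometer coordinates, together with its centroid
#' and area. The polygon has no interior rings: any annotation holes are
#' considered filled, matching how section regions of interest are prepared
#' before detection.
#'
#' @param vertices numeric matrix with columns `x`, `y` (um), one row per
#'   vertex, open ring (the last vertex is not a repeat of the first).
#' @return an `abdomen_window` with elements `vertices`, `centroid` (x, y um)
#'   and `area` (um^2).
#' @examples
#' sq <- abdomen_window(cbind(c(0, 10, 10, 0), c(0, 0, 10, 10)))
#' sq$area     # 100
#' sq$centroid # (5, 5)
#' @export
abdomen_window <- function(vertices) {
  vertices <- as.matrix(vertices)
  if (ncol(vertices) != 2 || nrow(vertices) < 3) {
    stop("window vertices must be an n x 2 matrix with n >= 3", call. = FALSE)
  }
  if (any(!is.finite(vertices))) stop("window vertices must be finite", call. = FALSE)
  # drop a duplicated closing vertex if the caller supplied a closed ring
  n <- nrow(vertices)
  if (all(vertices[1, ] == vertices[n, ])) vertices <- vertices[-n, , drop = FALSE]
  g <- polygon_geometry(vertices)
  if (g$area <= 0) stop("window polygon has zero area", call. = FALSE)
  structure(
    list(vertices = vertices, centroid = g$centroid, area = g$area),
    class = "abdomen_window"
  )
}

# Shoelace area and centroid of a simple polygon (open ring).
# Returns positive area regardless of vertex orientation.
polygon_geometry <- function(v) {
  x <- v[, 1]; y <- v[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cross <- x * yn - xn * y
  a2 <- sum(cross)                      # twice the signed area
  area <- abs(a2) / 2
  if (a2 == 0) return(list(area = 0, centroid = c(NA_real_, NA_real_)))
  cx <- sum((x + xn) * cross) / (3 * a2)
  cy <- sum((y + yn) * cross) / (3 * a2)
  list(area = area, centroid = c(cx, cy))
}

#' Test whether points lie inside a window
#'
#' @param window an [abdomen_window()].
#' @param points numeric matrix (or length-2 vector) of x, y coordinates in um.
#' @return logical vector, `TRUE` for points strictly inside the polygon.
#' @export
points_in_window <- function(window, points) {
  stopifnot(inherits(window, "abdomen_window"))
  points <- rbind_points(points)
  if (nrow(points) == 0) return(logical(0))
  bnd <- rbind(window$vertices, window$vertices[1, ])
  mgcv::in.out(bnd, points)
}

rbind_points <- function(points) {
  if (is.null(points)) return(matrix(numeric(0), ncol = 2))
  if (is.null(dim(points))) points <- matrix(points, ncol = 2, byrow = TRUE)
  storage.mode(points) <- "double"
  points
}

#' @export
print.abdomen_window <- function(x, ...) {
  cat(sprintf("<abdomen_window> %d vertices, area %.1f um^2, centroid (%.1f, %.1f) um\n",
              nrow(x$vertices), x$area, x$centroid[1], x$centroid[2]))
  invisible(x)
}

#' Generate a jittered-ellipse section window
#'
#' Emulates the irregular closed outline of a manually drawn abdomen section
#' boundary. The boundary is an ellipse with the semi-axes of `spec`, radially
#' perturbed by a low-order random Fourier series whose amplitude is
#' `spec$boundary_jitter` (as a fraction of the local radius), then discretized
#' into `spec$n_vertices` vertices. Because the perturbation is radial and
#' bounded below 0.5, the polygon is star-shaped and therefore simple.
#'
#' The window is positioned so that the ellipse center sits at
#' `semi_axes * (1 + boundary_jitter) + margin`, keeping all geometry in
#' positive coordinates that coincide with rendered image coordinates.
#'
#' Uses the current R random number stream; seed it (or use
#' [generate_cohort()]) for reproducibility.
#'
#' @param spec a [scene_spec()].
#' @param margin extra clearance in um between the jittered boundary and the
#'   coordinate origin (also the image border when rendered).
#' @return an [abdomen_window()].
#' @examples
#' set.seed(1)
#' w <- make_abdomen_window(scene_spec(boundary_jitter = 0))
#' abs(w$area - pi * 150 * 90) / (pi * 150 * 90) < 1e-3
#' @export
make_abdomen_window <- function(spec, margin = 15) {
  validate_scene_spec(spec)
  n <- spec$n_vertices
  theta <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  pert <- numeric(n)
  if (spec$boundary_jitter > 0) {
    harmonics <- 2:5
    amp <- stats::runif(length(harmonics), 0, 1)
    phase <- stats::runif(length(harmonics), 0, 2 * pi)
    amp <- amp / sum(amp)               # sum of |coefficients| = 1
    for (i in seq_along(harmonics)) {
      pert <- pert + amp[i] * cos(harmonics[i] * theta + phase[i])
    }
    pert <- spec$boundary_jitter * pert # |pert| <= boundary_jitter < 0.5
  }
  r <- 1 + pert
  center <- spec$semi_axes * (1 + spec$boundary_jitter) + margin
  vertices <- cbind(
    x = center[1] + spec$semi_axes[1] * r * cos(theta),
    y = center[2] + spec$semi_axes[2] * r * sin(theta)
  )
  abdomen_window(vertices)
}

# Largest centroid-to-boundary distance; used as the normalizing radius for
# center-biased thinning.
window_max_radius <- function(window) {
  d <- sweep(window$vertices, 2, window$centroid)
  max(sqrt(rowSums(d^2)))
}

# Axis-aligned bounding box of the window, as c(xmin, xmax, ymin, ymax).
window_bbox <- function(window) {
  c(range(window$vertices[, 1]), range(window$vertices[, 2]))
}
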