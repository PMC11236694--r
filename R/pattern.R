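#' Planar point pattern inside an abdomen window
#'
#' Container for detected or ground-truth hemocyte coordinates belonging to a
#' single section window. Coordinates are in micrometers in the same frame as
#' the window polygon.
#'
#' @param points numeric matrix with columns x, y (um); may have zero rows.
#' @param window an [abdomen_window()].
#' @param labels optional per-point integer labels (e.g. cluster parent id);
#'   `NA` where unlabelled.
#' @param metadata optional named list (fly id, condition, section id).
#' @param check if `TRUE`, verify that all points lie inside the window.
#' @return a `point_pattern`.
#' @export
point_pattern <- function(points, window, labels = NULL, metadata = list(),
                          check = TRUE) {
  stopifnot(inherits(window, "abdomen_window"))
  points <- rbind_points(points)
  colnames(points) <- c("x", "y")
  if (any(!is.finite(points))) stop("point coordinates must be finite", call. = FALSE)
  if (check && nrow(points) > 0 && !all(points_in_window(window, points))) {
    stop("all points must lie inside the window polygon", call. = FALSE)
  }
  if (!is.null(labels) && length(labels) != nrow(points)) {
    stop("labels must have one entry per point", call. = FALSE)
  }
  structure(
    list(points = points, window = window, labels = labels, metadata = metadata),
    class = "point_pattern"
  )
}

#' @export
print.point_pattern <- function(x, ...) {
  cat(sprintf("<point_pattern> %d points in window of area %.1f um^2\n",
              nrow(x$points), x$window$area))
  invisible(x)
}

#' Number of points in a pattern
#' @param pattern a [point_pattern()].
#' @return integer count.
#' @export
npoints <- function(pattern) nrow(pattern$points)

#' Sample a ground-truth hemocyte pattern
#'
#' Draws one realization of the point process named by `spec$process_kind`
#' inside `window`:
#'
#' * `csr`: homogeneous Poisson process — the realized count is
#'   `Poisson(intensity * area)` and locations are uniform on the window
#'   (rejection sampling from the bounding box). Emulates the dispersed
#'   "fed-like" regime.
#' * `center_biased`: the same Poisson count, but each location is accepted
#'   with probability `(1 - d/dmax)^bias_exponent`, where `d` is its distance
#'   to the window centroid and `dmax` the largest centroid-to-boundary
#'   distance. Expected counts therefore match csr at equal `intensity`,
#'   isolating the localization contrast ("starved-like" agglomeration
#'   towards the centroid).
#' * `thomas_cluster`: Poisson parents at `cluster_parent_intensity` on the
#'   jitter-dilated bounding box, each with a Poisson(`cluster_mean_size`)
#'   number of offspring displaced by isotropic Gaussian(`cluster_sigma`)
#'   noise; offspring falling outside the window are discarded. `labels`
#'   records the parent index of each retained point.
#'
#' Uses the current R random number stream.
#'
#' @param spec a [scene_spec()].
#' @param window an [abdomen_window()].
#' @param metadata optional named list stored on the pattern.
#' @return a [point_pattern()] with ground-truth coordinates.
#' @export
sample_pattern <- function(spec, window, metadata = list()) {
  validate_scene_spec(spec)
  stopifnot(inherits(window, "abdomen_window"))
  if (window$area <= 0) stop("window has zero area", call. = FALSE)
  switch(spec$process_kind,
    csr = {
      n <- stats::rpois(1, spec$intensity * window$area)
      pts <- runif_in_window(n, window)
      point_pattern(pts, window, labels = rep(NA_integer_, n),
                    metadata = metadata, check = FALSE)
    },
    center_biased = {
      n <- stats::rpois(1, spec$intensity * window$area)
      dmax <- window_max_radius(window)
      pts <- matrix(numeric(0), ncol = 2)
      while (nrow(pts) < n) {
        cand <- runif_in_window(max(2 * (n - nrow(pts)), 16), window)
        d <- sqrt(colSums((t(cand) - window$centroid)^2))
        keep <- stats::runif(nrow(cand)) < pmax(0, 1 - d / dmax)^spec$bias_exponent
        pts <- rbind(pts, cand[keep, , drop = FALSE])
      }
      pts <- pts[seq_len(n), , drop = FALSE]
      point_pattern(pts, window, labels = rep(NA_integer_, n),
                    metadata = metadata, check = FALSE)
    },
    thomas_cluster = {
      bb <- window_bbox(window)
      pad <- 4 * spec$cluster_sigma
      w <- (bb[2] - bb[1] + 2 * pad); h <- (bb[4] - bb[3] + 2 * pad)
      n_par <- stats::rpois(1, spec$cluster_parent_intensity * w * h)
      pts <- matrix(numeric(0), ncol = 2)
      labels <- integer(0)
      if (n_par > 0) {
        px <- stats::runif(n_par, bb[1] - pad, bb[2] + pad)
        py <- stats::runif(n_par, bb[3] - pad, bb[4] + pad)
        for (i in seq_len(n_par)) {
          m <- stats::rpois(1, spec$cluster_mean_size)
          if (m == 0) next
          off <- cbind(stats::rnorm(m, px[i], spec$cluster_sigma),
                       stats::rnorm(m, py[i], spec$cluster_sigma))
          keep <- points_in_window(window, off)
          pts <- rbind(pts, off[keep, , drop = FALSE])
          labels <- c(labels, rep(i, sum(keep)))
        }
      }
      point_pattern(pts, window, labels = labels, metadata = metadata,
                    check = FALSE)
    }
  )
}

# n uniform points inside the window by rejection from the bounding box.
runif_in_window <- function(n, window) {
  if (n == 0) return(matrix(numeric(0), ncol = 2))
  bb <- window_bbox(window)
  out <- matrix(numeric(0), ncol = 2)
  # acceptance rate is area / bbox area (>= ~0.5 for near-elliptical windows)
  while (nrow(out) < n) {
    m <- max(ceiling(1.6 * (n - nrow(out))), 16)
    cand <- cbind(stats::runif(m, bb[1], bb[2]), stats::runif(m, bb[3], bb[4]))
    out <- rbind(out, cand[points_in_window(window, cand), , drop = FALSE])
  }
  out[seq_len(n), , drop = FALSE]
}
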