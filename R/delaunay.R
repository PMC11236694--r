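#' Delaunay neighborhood summary of a pattern
#'
#' Triangulates the pattern (Delaunay triangulation via \pkg{deldir}) and
#' summarizes the induced neighbor graph: two points are neighbors when they
#' share a triangulation edge, optionally pruning edges longer than
#' `max_edge`. Reports the degree (neighbor-count) histogram, the number of
#' triangles, and the mean triangle area as a fraction of the window area —
#' clustered patterns form many small triangles, so this fraction drops as
#' points agglomerate.
#'
#' Patterns with fewer than three points, or with all points collinear, have
#' no triangulation; the summary is returned flagged `undefined` with a
#' logged message rather than an error, so cohort loops can skip and record
#' them as missing.
#'
#' Without pruning, the triangle statistics use the identities that any
#' triangulation of all n points has `2n - 2 - h` triangles (h = points on
#' the convex hull boundary) tiling the convex hull, so the mean triangle
#' area is the hull area over the triangle count; the explicit triangle list
#' is extracted only when requested or when pruning makes it necessary.
#'
#' @param pattern a [point_pattern()].
#' @param max_edge prune neighbor edges longer than this (um); `NULL` (the
#'   default) keeps all edges. Triangles containing a pruned edge are
#'   discarded from the triangle statistics.
#' @param keep_triangles if `TRUE`, always include the explicit triangle
#'   index triples in the result.
#' @return a `delaunay_summary`: list with `undefined` flag,
#'   `neighbor_count_histogram` (named counts by degree, degree 0 included),
#'   `degrees` (per point), `n_triangles`, `mean_triangle_area_fraction`,
#'   `triangles` (index triples, or `NULL` on the fast path) and `edges`
#'   (index pairs with lengths).
#' @examples
#' w <- abdomen_window(cbind(c(-1, 4, 4, -1), c(-1, -1, 4, 4)))
#' p <- point_pattern(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), w)
#' delaunay_summary(p)$n_triangles  # 2
#' @export
delaunay_summary <- function(pattern, max_edge = NULL, keep_triangles = FALSE) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- npoints(pattern)
  undef <- structure(
    list(undefined = TRUE, neighbor_count_histogram = NULL,
         degrees = NULL, n_triangles = NA_integer_,
         mean_triangle_area_fraction = NA_real_, triangles = NULL,
         edges = NULL),
    class = "delaunay_summary"
  )
  if (n < 3) {
    message("delaunay_summary: fewer than 3 points, undefined")
    return(undef)
  }
  pts <- pattern$points
  # collinearity: all cross products relative to the first edge vanish
  v1 <- pts[2, ] - pts[1, ]
  rel <- sweep(pts[-1, , drop = FALSE], 2, pts[1, ])
  cross <- abs(v1[1] * rel[, 2] - v1[2] * rel[, 1])
  scale <- max(abs(rel)) + 1
  if (all(cross < 1e-9 * scale^2)) {
    message("delaunay_summary: points are collinear, undefined")
    return(undef)
  }
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  edges <- cbind(i = dd$delsgs$ind1, j = dd$delsgs$ind2)
  elen <- sqrt((dd$delsgs$x1 - dd$delsgs$x2)^2 +
               (dd$delsgs$y1 - dd$delsgs$y2)^2)
  need_tri <- keep_triangles || !is.null(max_edge)
  tri_idx <- NULL
  if (need_tri) {
    tm <- deldir::triMat(dd)
    tri_idx <- if (nrow(tm) > 0) {
      t(apply(tm, 1, sort))
    } else {
      matrix(integer(0), ncol = 3)
    }
  }
  if (!is.null(max_edge)) {
    keep_edge <- elen <= max_edge
    if (nrow(tri_idx) > 0) {
      pair_len <- function(a, b) {
        sqrt(rowSums((pts[a, , drop = FALSE] - pts[b, , drop = FALSE])^2))
      }
      tri_keep <- pair_len(tri_idx[, 1], tri_idx[, 2]) <= max_edge &
                  pair_len(tri_idx[, 1], tri_idx[, 3]) <= max_edge &
                  pair_len(tri_idx[, 2], tri_idx[, 3]) <= max_edge
      tri_idx <- tri_idx[tri_keep, , drop = FALSE]
    }
    edges <- edges[keep_edge, , drop = FALSE]
    elen <- elen[keep_edge]
  }
  degrees <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  hist_counts <- table(factor(degrees, levels = 0:max(degrees)))
  if (is.null(max_edge)) {
    # any triangulation of all n points tiles the convex hull with
    # 2n - 2 - h triangles, h = hull vertices (ties on the hull boundary
    # are measure-zero for continuous coordinates)
    hull <- unique(grDevices::chull(pts))
    h <- length(hull)
    n_tri <- 2L * n - 2L - h
    hull_area <- polygon_geometry(pts[hull, , drop = FALSE])$area
    mean_frac <- if (n_tri > 0) (hull_area / n_tri) / pattern$window$area else NA_real_
  } else {
    n_tri <- nrow(tri_idx)
    tri_areas <- if (n_tri > 0) {
      apply(tri_idx, 1, function(ix) polygon_geometry(pts[ix, , drop = FALSE])$area)
    } else {
      numeric(0)
    }
    mean_frac <- if (n_tri > 0) mean(tri_areas) / pattern$window$area else NA_real_
  }
  structure(
    list(undefined = FALSE,
         neighbor_count_histogram = hist_counts,
         degrees = degrees,
         n_triangles = as.integer(n_tri),
         mean_triangle_area_fraction = mean_frac,
         triangles = tri_idx,
         edges = cbind(as.data.frame(edges), length = elen)),
    class = "delaunay_summary"
  )
}

#' @export
print.delaunay_summary <- function(x, ...) {
  if (x$undefined) {
    cat("<delaunay_summary> undefined (too few or collinear points)\n")
  } else {
    cat(sprintf("<delaunay_summary> %d triangles, %d edges, mean triangle area fraction %.4g\n",
                x$n_triangles, nrow(x$edges), x$mean_triangle_area_fraction))
  }
  invisible(x)
}
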