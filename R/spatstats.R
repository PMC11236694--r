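#' Equal-area percentile annuli around the window centroid
#'
#' Builds the ten concentric circles used for the percentile-distance
#' construction. The outer radius is the circumcircle radius `Rc`, the
#' distance from the window centroid to the farthest point of the pattern;
#' the i-th radius is `R_i = Rc * sqrt(i / 10)`, so the ten annuli
#' `(R_{i-1}, R_i]` all have area `pi * Rc^2 / 10` and `R_10 = Rc` exactly.
#' Working in percentile radii makes sections of different absolute size
#' comparable.
#'
#' @param pattern a [point_pattern()] with at least one point.
#' @return an `annulus_set`: list with `Rc` (um) and `radii` (length 10, um).
#' @examples
#' w <- abdomen_window(cbind(c(-200, 200, 200, -200), c(-200, -200, 200, 200)))
#' p <- point_pattern(cbind(c(0, 100), c(0, 0)), w)
#' annulus_radii(p)$radii[10]  # == Rc == 100
#' @export
annulus_radii <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (npoints(pattern) == 0) stop("no points: cannot build annuli", call. = FALSE)
  d <- centroid_distances(pattern)
  Rc <- max(d)
  structure(list(Rc = Rc, radii = Rc * sqrt((1:10) / 10)),
            class = "annulus_set")
}

# Distances from each point to the window centroid.
centroid_distances <- function(pattern) {
  sqrt(colSums((t(pattern$points) - pattern$window$centroid)^2))
}

#' Proportion of points within each percentile distance
#'
#' The cumulative proportion of pattern points whose distance to the window
#' centroid is at most `R_i`, for the ten equal-area annulus radii of
#' [annulus_radii()]. The curve is nondecreasing and ends at 1 (the farthest
#' point defines `R_10 = Rc`).
#'
#' @param pattern a [point_pattern()] with at least one point.
#' @return numeric vector of length 10 named by percentile index, with the
#'   `annulus_set` attached as attribute `"annuli"`.
#' @export
centroid_proportion_curve <- function(pattern) {
  ann <- annulus_radii(pattern)
  d <- centroid_distances(pattern)
  v <- vapply(ann$radii, function(r) mean(d <= r), numeric(1))
  names(v) <- paste0("p", 1:10)
  attr(v, "annuli") <- ann
  v
}

#' Aggregate replicate curves into a mean and 95% band
#'
#' Pointwise mean of monotone `[0, 1]` curves on a common grid, with the
#' normal-approximation 95% confidence band `mean +/- 1.96 * sd / sqrt(m)`
#' truncated to `[0, 1]`. With a single curve the mean is returned and the
#' band flagged undefined.
#'
#' @param curves numeric matrix (one row per replicate curve) or list of
#'   equal-length numeric vectors.
#' @param grid abscissa values (percentile index or distance in um).
#' @return a `curve_set`: list with `grid`, `per_section_curves`,
#'   `mean_curve`, `band_low`, `band_high`, `band_defined`, `n_curves`.
#' @export
aggregate_curves <- function(curves, grid) {
  if (is.list(curves) && !is.matrix(curves)) curves <- do.call(rbind, curves)
  curves <- as.matrix(curves)
  if (ncol(curves) != length(grid)) {
    stop("curves and grid have mismatched lengths", call. = FALSE)
  }
  m <- nrow(curves)
  if (m < 1) stop("need at least one curve", call. = FALSE)
  mean_curve <- colMeans(curves)
  if (m >= 2) {
    se <- apply(curves, 2, stats::sd) / sqrt(m)
    band_low <- pmax(mean_curve - 1.96 * se, 0)
    band_high <- pmin(mean_curve + 1.96 * se, 1)
    band_defined <- TRUE
  } else {
    band_low <- band_high <- rep(NA_real_, length(grid))
    band_defined <- FALSE
  }
  structure(list(grid = grid, per_section_curves = curves,
                 mean_curve = mean_curve, band_low = band_low,
                 band_high = band_high, band_defined = band_defined,
                 n_curves = m),
            class = "curve_set")
}

#' @export
print.curve_set <- function(x, ...) {
  cat(sprintf("<curve_set> %d curves on %d grid points%s\n", x$n_curves,
              length(x$grid),
              if (x$band_defined) ", 95% band" else ", band undefined"))
  invisible(x)
}

#' Tidy data frame of a curve set
#' @param x a `curve_set`.
#' @param ... unused.
#' @return data frame with `grid_value`, `mean`, `band_low`, `band_high`.
#' @export
as.data.frame.curve_set <- function(x, ...) {
  data.frame(grid_value = x$grid, mean = x$mean_curve,
             band_low = x$band_low, band_high = x$band_high)
}

#' Histogram of pairwise distances
#'
#' Bins all `n(n-1)/2` unordered pairwise Euclidean distances of a pattern.
#' Shorter pairwise distances indicate points lying closer together
#' (agglomeration).
#'
#' @param pattern a [point_pattern()].
#' @param bin_edges increasing numeric vector of bin edges in um covering the
#'   distance range; defaults to 30 equal bins over `[0, max distance]`.
#' @return list with `counts`, `bin_edges`, `mids` and `n_pairs`; when
#'   `n < 2` the histogram is empty and a message is logged.
#' @export
pairwise_distance_histogram <- function(pattern, bin_edges = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- npoints(pattern)
  if (n < 2) {
    message("pairwise_distance_histogram: fewer than 2 points, skipping")
    edges <- if (is.null(bin_edges)) numeric(0) else bin_edges
    return(list(counts = integer(max(length(edges) - 1, 0)),
                bin_edges = edges, mids = numeric(max(length(edges) - 1, 0)),
                n_pairs = 0L))
  }
  d <- as.vector(stats::dist(pattern$points))
  if (is.null(bin_edges)) bin_edges <- seq(0, max(d), length.out = 31)
  h <- graphics::hist(d, breaks = bin_edges, plot = FALSE,
                      include.lowest = TRUE)
  list(counts = h$counts, bin_edges = bin_edges, mids = h$mids,
       n_pairs = length(d))
}

#' Distances to the k nearest neighbors
#'
#' For each point of `points` (n x 2 matrix, um), the sorted distances to its
#' k nearest other points. Computed blockwise so patterns with thousands of
#' points avoid a full distance matrix.
#'
#' @param points n x 2 coordinate matrix.
#' @param k number of neighbors, `k <= n - 1`.
#' @param block rows per block.
#' @return n x k matrix; column j holds the j-th nearest-neighbor distance.
#' @export
knn_distances <- function(points, k, block = 512L) {
  points <- rbind_points(points)
  n <- nrow(points)
  stopifnot(k >= 1, n >= k + 1)
  out <- matrix(NA_real_, nrow = n, ncol = k)
  for (start in seq(1, n, by = block)) {
    idx <- start:min(start + block - 1, n)
    d2 <- outer(points[idx, 1], points[, 1], "-")^2 +
          outer(points[idx, 2], points[, 2], "-")^2
    d2[cbind(seq_along(idx), idx)] <- Inf   # exclude self
    for (r in seq_along(idx)) {
      out[idx[r], ] <- sqrt(sort(d2[r, ], partial = seq_len(k))[seq_len(k)])
    }
  }
  out
}

#' k-nearest-neighbor G-function across sections
#'
#' The G-function is the cumulative distribution function of nearest-neighbor
#' distances. Following the pooled-k variant, each section contributes the
#' empirical CDF of the multiset of its points' 1st..k-th nearest-neighbor
#' distances (k = 5 by default), evaluated on a common distance grid;
#' per-section curves are then averaged with a 95% band by
#' [aggregate_curves()]. Sections with `n <= k` points cannot contribute and
#' are excluded with a warning. No edge correction is applied; for
#' comparisons against the closed CSR form `1 - exp(-lambda * pi * r^2)`,
#' restrict query points away from the boundary with `boundary_guard`.
#'
#' @param patterns list of [point_pattern()]s (the replicate sections).
#' @param k number of neighbors pooled per point.
#' @param grid increasing distances (um) at which the CDFs are evaluated.
#' @param boundary_guard exclude query points closer than this (um) to the
#'   window boundary (their neighbor distances still use all points).
#' @return a `curve_set`; excluded section ids in attribute `"excluded"`.
#' @export
knn_gfunction <- function(patterns, k = 5, grid, boundary_guard = 0) {
  if (inherits(patterns, "point_pattern")) patterns <- list(patterns)
  stopifnot(k >= 1, length(grid) >= 1, all(diff(grid) > 0))
  curves <- list(); excluded <- character(0)
  for (i in seq_along(patterns)) {
    p <- patterns[[i]]
    id <- if (!is.null(p$metadata$section_id)) p$metadata$section_id else as.character(i)
    if (npoints(p) <= k) {
      warning(sprintf("knn_gfunction: section '%s' has n <= k, excluded", id),
              call. = FALSE)
      excluded <- c(excluded, id)
      next
    }
    nn <- knn_distances(p$points, k)
    if (boundary_guard > 0) {
      keep <- boundary_distances(p) >= boundary_guard
      nn <- nn[keep, , drop = FALSE]
      if (nrow(nn) == 0) {
        warning(sprintf("knn_gfunction: section '%s' has no interior points, excluded", id),
                call. = FALSE)
        excluded <- c(excluded, id)
        next
      }
    }
    d <- as.vector(nn)
    curves[[id]] <- vapply(grid, function(r) mean(d <= r), numeric(1))
  }
  if (length(curves) == 0) stop("no usable patterns for the G-function", call. = FALSE)
  cs <- aggregate_curves(curves, grid)
  attr(cs, "excluded") <- excluded
  cs
}

# Distance from each pattern point to the window boundary polygon.
boundary_distances <- function(pattern) {
  v <- pattern$window$vertices
  w <- rbind(v[-1, , drop = FALSE], v[1, , drop = FALSE])   # edge endpoints
  p <- pattern$points
  n <- nrow(p)
  dmin <- rep(Inf, n)
  ex <- w[, 1] - v[, 1]; ey <- w[, 2] - v[, 2]
  len2 <- ex^2 + ey^2
  for (e in seq_len(nrow(v))) {
    tx <- p[, 1] - v[e, 1]; ty <- p[, 2] - v[e, 2]
    tt <- pmin(pmax((tx * ex[e] + ty * ey[e]) / len2[e], 0), 1)
    dx <- tx - tt * ex[e]; dy <- ty - tt * ey[e]
    dmin <- pmin(dmin, dx^2 + dy^2)
  }
  sqrt(dmin)
}

#' Normalize a pattern to the unit disk
#'
#' Translates coordinates so the window centroid is the origin and scales by
#' `1 / Rc` (the circumcircle radius), mapping every point into the closed
#' unit disk with the farthest point on its boundary. This registration lets
#' sections of different size and position be pooled.
#'
#' @param pattern a [point_pattern()] with at least one point.
#' @return n x 2 matrix of unit-frame coordinates.
#' @export
normalize_pattern <- function(pattern) {
  stopifnot(inherits(pattern, "point_pattern"))
  if (npoints(pattern) == 0) stop("no points to normalize", call. = FALSE)
  centered <- sweep(pattern$points, 2, pattern$window$centroid)
  Rc <- max(sqrt(rowSums(centered^2)))
  if (Rc == 0) {
    message("normalize_pattern: all points at the centroid; returning zeros")
    return(centered)
  }
  centered / Rc
}

#' Pooled 2D histogram of normalized coordinates
#'
#' Normalizes every section to the unit disk ([normalize_pattern()]), pools
#' the coordinates and bins them on `[-1, 1]^2`. Darker (higher-count) bins
#' mark locations where hemocytes recur across replicates.
#'
#' @param patterns list of [point_pattern()]s.
#' @param bins number of bins per axis.
#' @return `bins x bins` integer matrix (rows = y from -1 to 1, columns = x),
#'   with the bin edges in attribute `"edges"`; sums to the pooled point
#'   count.
#' @export
coordinate_histogram_2d <- function(patterns, bins = 32) {
  if (inherits(patterns, "point_pattern")) patterns <- list(patterns)
  stopifnot(length(patterns) >= 1, bins >= 1)
  pooled <- do.call(rbind, lapply(patterns, normalize_pattern))
  edges <- seq(-1, 1, length.out = bins + 1)
  ix <- findInterval(pooled[, 1], edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  iy <- findInterval(pooled[, 2], edges, rightmost.closed = TRUE,
                     all.inside = TRUE)
  h <- matrix(0L, nrow = bins, ncol = bins)
  for (i in seq_len(nrow(pooled))) h[iy[i], ix[i]] <- h[iy[i], ix[i]] + 1L
  attr(h, "edges") <- edges
  h
}
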