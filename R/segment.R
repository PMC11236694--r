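#' Yen entropy threshold of a section image
#'
#' Computes the automatic background threshold that maximizes Yen's maximum
#' correlation criterion over the image histogram. For a candidate split
#' after histogram bin t with class probabilities `P = sum(p[1:t])` and
#' within-class squared sums `G1 = sum(p[1:t]^2)`, `G2 = sum(p[(t+1):B]^2)`,
#' the criterion is
#'
#'   `TC(t) = -log(G1 * G2) + 2 * log(P * (1 - P))`
#'
#' and the returned threshold is the upper edge of the maximizing bin, so it
#' always lies strictly between the image minimum and maximum. Pixels below
#' the threshold are background (see [suppress_background()]).
#'
#' The histogram uses the native 256 integer levels for 8-bit images and 1024
#' equal-width bins for 16-bit images.
#'
#' @param image a [section_image()] (or numeric matrix, assumed 8-bit).
#' @return the threshold intensity (scalar).
#' @export
yen_threshold <- function(image) {
  px <- if (inherits(image, "section_image")) image$pixels else as.matrix(image)
  bit_depth <- if (inherits(image, "section_image")) image$bit_depth else 8L
  if (length(unique(as.vector(px))) < 2) {
    stop("degenerate histogram: image has fewer than 2 distinct intensities",
         call. = FALSE)
  }
  if (bit_depth == 8L) {
    edges <- seq(-0.5, 255.5, by = 1)
  } else {
    edges <- seq(0, 65536, length.out = 1025)
  }
  counts <- graphics::hist(as.vector(px), breaks = edges, plot = FALSE,
                           right = FALSE)$counts
  p <- counts / sum(counts)
  p2 <- p^2
  P1 <- cumsum(p)
  G1 <- cumsum(p2)
  G2 <- rev(cumsum(rev(p2)))           # G2[t] = sum(p2[t:B])
  B <- length(p)
  t_idx <- seq_len(B - 1)              # split after bin t
  valid <- P1[t_idx] > 0 & P1[t_idx] < 1
  crit <- rep(-Inf, B - 1)
  g1 <- G1[t_idx][valid]
  g2 <- G2[t_idx + 1][valid]
  pp <- P1[t_idx][valid]
  crit[valid] <- -log(pmax(g1 * g2, .Machine$double.xmin)) +
    2 * log(pp * (1 - pp))
  t_star <- which.max(crit)
  edges[t_star + 1]                    # upper edge of the maximizing bin
}

#' Zero pixels below a threshold
#'
#' Background suppression: every pixel with intensity strictly below
#' `threshold` is set to zero, all others are unchanged. Idempotent for any
#' fixed threshold at or below the smallest surviving intensity, and in
#' particular when reapplied with the same threshold.
#'
#' @param image a [section_image()].
#' @param threshold finite intensity cutoff.
#' @return a [section_image()] with the same calibration and metadata.
#' @export
suppress_background <- function(image, threshold) {
  stopifnot(inherits(image, "section_image"), is.finite(threshold))
  px <- image$pixels
  px[px < threshold] <- 0
  section_image(px, pixel_size = image$pixel_size, bit_depth = image$bit_depth,
                metadata = image$metadata)
}

#' Detection parameters
#'
#' Tunable knobs of [detect_cells()]. Area bounds default to 20-200 um^2,
#' bracketing the ~10 um diameter (~78 um^2) of a hemocyte, so both debris
#' specks and fused aggregates are rejected.
#'
#' @param smooth_sigma Gaussian smoothing before watershed, in pixels.
#' @param min_area,max_area object area bounds in um^2.
#' @param min_mean_intensity positive-cell mean-intensity cutoff in counts;
#'   `NULL` defaults to the suppression threshold in [segment_section()] and
#'   to no cutoff in a bare [detect_cells()] call.
#' @param watershed_tolerance minimum depth (in counts) separating two
#'   intensity maxima for them to seed distinct objects.
#' @param watershed_ext neighborhood radius (px) used for the local maxima.
#' @return a list of class `detect_params`.
#' @export
detect_params <- function(smooth_sigma = 1, min_area = 20, max_area = 200,
                          min_mean_intensity = NULL,
                          watershed_tolerance = 1, watershed_ext = 1) {
  stopifnot(smooth_sigma > 0, min_area >= 0, max_area > min_area,
            watershed_tolerance >= 0, watershed_ext >= 1)
  structure(list(smooth_sigma = smooth_sigma, min_area = min_area,
                 max_area = max_area,
                 min_mean_intensity = min_mean_intensity,
                 watershed_tolerance = watershed_tolerance,
                 watershed_ext = watershed_ext),
            class = "detect_params")
}

#' Watershed detection of positive cells
#'
#' Splits the background-suppressed image into candidate cells: Gaussian
#' smoothing, then a watershed transform of the smoothed intensity seeded at
#' local maxima (maxima closer in height than `watershed_tolerance` merge),
#' so touching bright blobs separate along their intensity valley. Each
#' labelled region becomes a [point_pattern()]-compatible detection with
#' centroid (um), area (um^2) and intensity statistics computed from the
#' input image. Regions are then filtered by area bounds, by mean intensity
#' and by requiring the centroid to fall inside the window polygon (regions
#' touching the boundary are kept if their centroid is inside).
#'
#' @param image a [section_image()] already processed by
#'   [suppress_background()] (zeros are treated as background).
#' @param window the [abdomen_window()] of the section.
#' @param params a [detect_params()].
#' @return data frame with one row per detection: `x_um`, `y_um`, `area_um2`,
#'   `mean_intensity`, `max_intensity`.
#' @export
detect_cells <- function(image, window, params = detect_params()) {
  stopifnot(inherits(image, "section_image"), inherits(window, "abdomen_window"),
            inherits(params, "detect_params"))
  px <- image$pixels
  ps <- image$pixel_size
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      area_um2 = numeric(0), mean_intensity = numeric(0),
                      max_intensity = numeric(0))
  if (all(px == 0)) return(empty)
  # EBImage stores images x-major; transpose in and out
  ei <- EBImage::Image(t(px))
  sm <- EBImage::gblur(ei, sigma = params$smooth_sigma)
  sm[t(px) == 0] <- 0
  labels_x <- EBImage::watershed(sm, tolerance = params$watershed_tolerance,
                                 ext = params$watershed_ext)
  lab <- t(EBImage::imageData(labels_x))
  ids <- which(lab > 0)
  if (length(ids) == 0) return(empty)
  lv <- lab[ids]
  rows <- ((ids - 1) %% nrow(lab)) + 1
  cols <- ((ids - 1) %/% nrow(lab)) + 1
  vals <- px[ids]
  n_px <- tabulate(lv)
  keep_lab <- which(n_px > 0)
  sum_x <- rowsum(cols - 1, lv)[, 1]
  sum_y <- rowsum(rows - 1, lv)[, 1]
  sum_i <- rowsum(vals, lv)[, 1]
  max_i <- tapply(vals, lv, max)
  n <- n_px[keep_lab]
  det <- data.frame(
    x_um = (sum_x / n) * ps,
    y_um = (sum_y / n) * ps,
    area_um2 = n * ps^2,
    mean_intensity = sum_i / n,
    max_intensity = as.numeric(max_i)
  )
  det <- det[det$area_um2 >= params$min_area & det$area_um2 <= params$max_area, ,
             drop = FALSE]
  if (!is.null(params$min_mean_intensity)) {
    det <- det[det$mean_intensity >= params$min_mean_intensity, , drop = FALSE]
  }
  if (nrow(det) > 0) {
    inside <- points_in_window(window, as.matrix(det[, c("x_um", "y_um")]))
    det <- det[inside, , drop = FALSE]
  }
  rownames(det) <- NULL
  det
}

#' Threshold and detect in one step
#'
#' Convenience wrapper reproducing the full per-section detection chain:
#' Yen threshold, background suppression, watershed detection. The Yen
#' threshold doubles as the positive-cell mean-intensity cutoff unless
#' `params` overrides it.
#'
#' @inheritParams detect_cells
#' @return as [detect_cells()], with the threshold attached as attribute
#'   `"threshold"`.
#' @export
segment_section <- function(image, window, params = detect_params()) {
  thr <- yen_threshold(image)
  if (is.null(params$min_mean_intensity)) params$min_mean_intensity <- thr
  det <- detect_cells(suppress_background(image, thr), window, params)
  attr(det, "threshold") <- thr
  det
}

#' Percentage of window area occupied by detections
#'
#' @param detections data frame from [detect_cells()] (needs `area_um2`).
#' @param window the section [abdomen_window()].
#' @return percentage in `[0, 100]` for non-overlapping detections.
#' @export
percent_area_occupied <- function(detections, window) {
  stopifnot(inherits(window, "abdomen_window"))
  if (window$area <= 0) stop("window has zero area", call. = FALSE)
  if (nrow(detections) == 0) return(0)
  100 * sum(detections$area_um2) / window$area
}

#' Integrated intensity per unit tissue area
#'
#' Sums pixel intensities whose centers fall inside the window polygon and
#' divides by the window area in um^2 — the intensity-density readout used
#' for stain quantification (integrated density / tissue area).
#'
#' @param image a [section_image()].
#' @param window the [abdomen_window()] delimiting the tissue.
#' @return intensity counts per um^2.
#' @export
intensity_density <- function(image, window) {
  stopifnot(inherits(image, "section_image"), inherits(window, "abdomen_window"))
  if (window$area <= 0) stop("window has zero area", call. = FALSE)
  mask <- window_pixel_mask(window, nrow(image$pixels), ncol(image$pixels),
                            image$pixel_size)
  sum(image$pixels[mask]) / window$area
}

#' Export detection features as CSV
#'
#' Writes one row per detection (`fly_id, condition, section_id, x_um, y_um,
#' area_um2, mean_intensity, max_intensity`) plus a companion
#' `<path minus extension>_window.csv` with the window summary (centroid and
#' area), mirroring a QuPath-style feature export so that real exports can be
#' ingested interchangeably.
#'
#' @param detections data frame from [detect_cells()].
#' @param window the section [abdomen_window()].
#' @param path output CSV path for the detection table.
#' @param metadata named list with `fly_id`, `condition`, `section_id`.
#' @return invisibly, the two file paths written.
#' @export
export_features <- function(detections, window, path, metadata = list()) {
  meta <- function(key) if (is.null(metadata[[key]])) NA_character_ else metadata[[key]]
  n <- nrow(detections)
  tab <- data.frame(
    fly_id = rep(meta("fly_id"), n),
    condition = rep(meta("condition"), n),
    section_id = rep(meta("section_id"), n),
    x_um = detections$x_um, y_um = detections$y_um,
    area_um2 = detections$area_um2,
    mean_intensity = detections$mean_intensity,
    max_intensity = detections$max_intensity
  )
  ok <- try(utils::write.csv(tab, path, row.names = FALSE), silent = TRUE)
  if (inherits(ok, "try-error")) {
    stop(sprintf("failed to write feature table to '%s'", path), call. = FALSE)
  }
  wpath <- paste0(tools::file_path_sans_ext(path), "_window.csv")
  wtab <- data.frame(
    fly_id = meta("fly_id"), condition = meta("condition"),
    section_id = meta("section_id"),
    centroid_x_um = window$centroid[1], centroid_y_um = window$centroid[2],
    area_um2 = window$area
  )
  utils::write.csv(wtab, wpath, row.names = FALSE)
  invisible(c(features = path, window = wpath))
}
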