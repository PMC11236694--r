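#' Write a section image as single-channel TIFF
#'
#' @param image a [section_image()].
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_section <- function(image, path) {
  stopifnot(inherits(image, "section_image"))
  maxval <- 2^image$bit_depth - 1
  tiff::writeTIFF(image$pixels / maxval, path,
                  bits.per.sample = image$bit_depth)
  invisible(path)
}

#' Read a section image from TIFF
#'
#' Reads a single-channel TIFF and attaches calibration and metadata.
#' Multi-channel or multi-frame files are rejected: the pipeline operates on
#' one fluorescence channel.
#'
#' @param path path to the TIFF file.
#' @param pixel_size calibration in um/px to attach (default 0.207).
#' @param metadata named list (`fly_id`, `condition`, `section_id`).
#' @return a [section_image()].
#' @export
read_section <- function(path, pixel_size = 0.207, metadata = list()) {
  if (!file.exists(path)) {
    stop(sprintf("cannot read section image: '%s' does not exist", path),
         call. = FALSE)
  }
  raw <- tryCatch(tiff::readTIFF(path, info = TRUE, all = TRUE),
                  error = function(e) {
                    stop(sprintf("failed to read TIFF '%s': %s", path,
                                 conditionMessage(e)), call. = FALSE)
                  })
  if (length(raw) != 1) {
    stop(sprintf("'%s' has %d frames; a single-channel single-frame TIFF is required",
                 path, length(raw)), call. = FALSE)
  }
  arr <- raw[[1]]
  if (length(dim(arr)) == 3) {
    if (dim(arr)[3] != 1) {
      stop(sprintf("'%s' has %d channels; a single channel is required",
                   path, dim(arr)[3]), call. = FALSE)
    }
    arr <- arr[, , 1]
  }
  bits <- attr(arr, "bits.per.sample")
  if (is.null(bits)) bits <- 8L
  maxval <- 2^bits - 1
  px <- round(arr * maxval)
  attributes(px) <- list(dim = dim(px))   # drop TIFF tag attributes
  section_image(px, pixel_size = pixel_size,
                bit_depth = as.integer(bits), metadata = metadata)
}

#' Write / read a window boundary polygon as CSV
#'
#' Persists the boundary so downstream stages can rebuild the
#' [abdomen_window()] without the generator.
#'
#' @param window an [abdomen_window()].
#' @param path CSV path (columns `x_um`, `y_um`, one vertex per row).
#' @return `write_window_csv`: invisibly the path; `read_window_csv`: the
#'   reconstructed [abdomen_window()].
#' @export
write_window_csv <- function(window, path) {
  stopifnot(inherits(window, "abdomen_window"))
  utils::write.csv(data.frame(x_um = window$vertices[, 1],
                              y_um = window$vertices[, 2]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_window_csv
#' @export
read_window_csv <- function(path) {
  df <- utils::read.csv(path)
  abdomen_window(cbind(df$x_um, df$y_um))
}
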