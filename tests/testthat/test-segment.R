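noiseless_spec <- function(...) {
  scene_spec(semi_axes = c(40, 30), boundary_jitter = 0,
             background_mean = 0, background_sd = 0, ...)
}

test_that("yen threshold matches an exhaustive criterion scan", {
  set.seed(1)
  # mixed fixture: dim background plus a bright minority population
  px <- matrix(c(sample(0:40, 900, replace = TRUE),
                 sample(150:255, 100, replace = TRUE)), 25, 40)
  img <- section_image(px, bit_depth = 8L)
  expect_equal(yen_threshold(img), bf_yen_scan(px))

  # a second fixture with three intensity populations
  set.seed(2)
  px2 <- matrix(c(rpois(600, 8), rpois(300, 60), rpois(100, 200)), 20, 50)
  px2 <- pmin(px2, 255)
  expect_equal(yen_threshold(section_image(px2)), bf_yen_scan(px2))
})

test_that("yen threshold separates a two-valued image and is deterministic", {
  px <- matrix(10, 20, 20)
  px[sample(400, 40)] <- 200
  img <- section_image(px)
  thr <- yen_threshold(img)
  expect_gt(thr, 10)
  expect_lt(thr, 200)
  expect_identical(thr, yen_threshold(section_image(px)))
  expect_error(yen_threshold(section_image(matrix(7, 5, 5))),
               "degenerate histogram")
})

test_that("background suppression zeroes below-threshold pixels and is idempotent", {
  img <- section_image(matrix(c(5, 15, 10, 20), 2, 2, byrow = TRUE))
  expect_identical(suppress_background(img, 0)$pixels, img$pixels)
  expect_true(all(suppress_background(img, 21)$pixels == 0))
  out <- suppress_background(img, 12)
  expect_identical(out$pixels, matrix(c(0, 15, 0, 20), 2, 2, byrow = TRUE))
  expect_identical(suppress_background(out, 12)$pixels, out$pixels)
})

test_that("a blank image yields zero detections", {
  set.seed(3)
  w <- make_abdomen_window(noiseless_spec())
  img <- section_image(matrix(0, 100, 100))
  expect_identical(nrow(detect_cells(img, w)), 0L)
})

test_that("watershed splits two blobs three psf-sigma apart", {
  spec <- noiseless_spec(psf_sigma = 2)
  set.seed(4)
  w <- make_abdomen_window(spec)
  sep <- 3 * spec$psf_sigma
  pts <- rbind(w$centroid - c(sep / 2, 0), w$centroid + c(sep / 2, 0))
  img <- render_section(point_pattern(pts, w), spec)
  # the two blobs merge into one above-threshold component...
  sup <- suppress_background(img, 20)
  lab <- EBImage::bwlabel(EBImage::Image(t(sup$pixels > 0)))
  expect_equal(as.numeric(max(lab)), 1)
  # ...which the watershed separates into exactly two detections
  det <- detect_cells(sup, w)
  expect_identical(nrow(det), 2L)
  ev <- evaluate_detections(as.matrix(det[, c("x_um", "y_um")]), pts,
                            tolerance = 3)
  expect_equal(ev$f1, 1)
})

test_that("well-separated high-SNR blobs are recovered at F1 >= 0.95", {
  spec <- scene_spec()   # SNR = 180/4 = 45
  set.seed(5)
  w <- make_abdomen_window(spec)
  pat <- make_separated_pattern(w, 50, 4 * spec$psf_sigma)
  set.seed(6)
  img <- render_section(pat, spec)
  det <- segment_section(img, w)
  ev <- evaluate_detections(as.matrix(det[, c("x_um", "y_um")]), pat,
                            tolerance = 5)
  expect_gte(ev$f1, 0.95)
})

test_that("detections translate with a whole-pixel image shift", {
  spec <- noiseless_spec()
  set.seed(7)
  w <- make_abdomen_window(spec)
  pat <- make_separated_pattern(w, 10, 10)
  img <- render_section(pat, spec)
  sup <- suppress_background(img, 20)
  det <- detect_cells(sup, w)

  dr <- 12L; dc <- 7L   # shift down 12 px, right 7 px
  shifted <- matrix(0, nrow(sup$pixels) + dr, ncol(sup$pixels) + dc)
  shifted[(dr + 1):(dr + nrow(sup$pixels)),
          (dc + 1):(dc + ncol(sup$pixels))] <- sup$pixels
  ps <- spec$pixel_size
  w_shift <- abdomen_window(sweep(w$vertices, 2, -c(dc * ps, dr * ps)))
  det_shift <- detect_cells(section_image(shifted, pixel_size = ps), w_shift)

  ord <- order(det$x_um, det$y_um)
  ord2 <- order(det_shift$x_um, det_shift$y_um)
  expect_equal(det_shift$x_um[ord2], det$x_um[ord] + dc * ps, tolerance = 1e-9)
  expect_equal(det_shift$y_um[ord2], det$y_um[ord] + dr * ps, tolerance = 1e-9)
  expect_equal(det_shift$area_um2[ord2], det$area_um2[ord], tolerance = 1e-9)
})

test_that("recovery degrades as background noise grows (fixed seeds)", {
  sd_ladder <- c(2, 10, 30, 55, 80)
  f1 <- vapply(seq_along(sd_ladder), function(i) {
    spec <- scene_spec(semi_axes = c(60, 45), background_sd = sd_ladder[i],
                       peak_intensity = 120)
    set.seed(70)
    w <- make_abdomen_window(spec)
    pat <- make_separated_pattern(w, 30, 4 * spec$psf_sigma)
    set.seed(71)
    img <- render_section(pat, spec)
    det <- segment_section(img, w)
    evaluate_detections(as.matrix(det[, c("x_um", "y_um")]), pat,
                        tolerance = 5)$f1
  }, numeric(1))
  expect_true(all(diff(f1) <= 0))
  expect_lt(f1[length(f1)], f1[1])
})

test_that("percent area occupied follows the area ratio", {
  w <- square_window(100)  # area 1e4
  expect_equal(percent_area_occupied(data.frame(area_um2 = numeric(0)), w), 0)
  one <- data.frame(area_um2 = w$area / 4)
  expect_equal(percent_area_occupied(one, w), 25)
  three <- data.frame(area_um2 = c(10, 20, 30))
  w6000 <- abdomen_window(cbind(c(0, 100, 100, 0), c(0, 0, 60, 60)))
  expect_equal(percent_area_occupied(three, w6000), 1.0)
})

test_that("intensity density is integrated intensity over window area", {
  px <- matrix(0, 4, 4)
  px[1:2, 1:2] <- c(1, 3, 2, 4)   # pixel centers (0,0),(1,0),(0,1),(1,1)
  img <- section_image(px, pixel_size = 1)
  w <- abdomen_window(cbind(c(-0.5, 1.5, 1.5, -0.5), c(-0.5, -0.5, 1.5, 1.5)))
  expect_equal(intensity_density(img, w), 10 / 4)
  expect_equal(intensity_density(section_image(matrix(0, 4, 4), pixel_size = 1), w), 0)
  # uniform field: per-pixel value over per-pixel area
  uni <- section_image(matrix(7, 60, 60), pixel_size = 0.5)
  w_in <- square_window(20, origin = c(4, 4))
  expect_equal(intensity_density(uni, w_in), 7 / 0.5^2, tolerance = 0.01)
})

test_that("feature export round-trips and counts rows", {
  tmp <- withr::local_tempdir()
  w <- square_window(100)
  det <- data.frame(x_um = c(10.123456, 50.5), y_um = c(20.654321, 60.25),
                    area_um2 = c(30, 40), mean_intensity = c(100, 120),
                    max_intensity = c(150, 180))
  path <- file.path(tmp, "features.csv")
  meta <- list(fly_id = "f1", condition = "fed", section_id = "s1")
  export_features(det, w, path, metadata = meta)
  back <- read.csv(path)
  expect_identical(nrow(back), 2L)
  expect_equal(back$x_um, det$x_um, tolerance = 1e-6)
  expect_equal(back$y_um, det$y_um, tolerance = 1e-6)
  expect_identical(unique(back$fly_id), "f1")
  wb <- read.csv(file.path(tmp, "features_window.csv"))
  expect_equal(wb$area_um2, w$area)
  # zero detections: header-only table
  export_features(det[0, ], w, file.path(tmp, "empty.csv"), metadata = meta)
  expect_identical(nrow(read.csv(file.path(tmp, "empty.csv"))), 0L)
})
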