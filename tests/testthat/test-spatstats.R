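unit_pattern <- function(points, win = NULL) {
  if (is.null(win)) win <- disk_window(500)
  point_pattern(points, win, check = FALSE)
}

test_that("annulus radii split the circumcircle into ten equal areas", {
  p <- unit_pattern(cbind(c(10, 0, -100), c(0, 20, 0)))
  ann <- annulus_radii(p)
  expect_equal(ann$Rc, 100)
  expect_equal(ann$radii[10], ann$Rc)
  expect_equal(ann$radii[1], 100 * sqrt(0.1), tolerance = 1e-12)
  ring_areas <- diff(c(0, pi * ann$radii^2))
  expect_equal(ring_areas, rep(pi * ann$Rc^2 / 10, 10), tolerance = 1e-9)
  expect_error(annulus_radii(unit_pattern(matrix(numeric(0), ncol = 2))),
               "no points")
})

test_that("centroid proportion curve counts points within percentile radii", {
  # distances 10, 20, 30, 100 from the centroid of a centered disk window
  p <- unit_pattern(cbind(c(10, 20, 30, 100), 0))
  cv <- centroid_proportion_curve(p)
  expect_equal(unname(cv[1]), 3 / 4)   # R1 ~ 31.62 covers 10, 20, 30
  expect_equal(unname(cv[10]), 1)
  expect_true(all(diff(cv) >= 0))
  # all points at the centroid: flat curve of ones (exact-centroid window)
  sq <- square_window(1000, origin = c(-500, -500))
  p0 <- point_pattern(matrix(0, nrow = 5, ncol = 2), sq, check = FALSE)
  expect_equal(as.numeric(centroid_proportion_curve(p0)), rep(1, 10))
  # one point: a 0/1 step ending at 1
  p1 <- unit_pattern(cbind(50, 0))
  cv1 <- centroid_proportion_curve(p1)
  expect_true(all(cv1 %in% c(0, 1)))
  expect_equal(unname(cv1[10]), 1)
})

test_that("curve aggregation means curves and bands shrink with agreement", {
  same <- rbind(c(0.1, 0.5, 1), c(0.1, 0.5, 1))
  cs <- aggregate_curves(same, grid = 1:3)
  expect_equal(cs$mean_curve, c(0.1, 0.5, 1))
  expect_equal(cs$band_low, cs$band_high)   # zero-width band
  two <- rbind(c(0.2, 0.2), c(0.4, 0.4))
  expect_equal(aggregate_curves(two, 1:2)$mean_curve, c(0.3, 0.3))
  one <- aggregate_curves(matrix(c(0.5, 1), 1), 1:2)
  expect_false(one$band_defined)
  expect_true(all(is.na(one$band_low)))
})

test_that("the csr centroid curve lies inside the replicate band", {
  # under csr in a disk, distance^2 is uniform, so the true curve at the
  # equal-area radii is i/10
  spec <- scene_spec(semi_axes = c(80, 80), boundary_jitter = 0,
                     intensity = 150 / (pi * 80^2))
  set.seed(50)
  w <- make_abdomen_window(spec)
  curves <- replicate(50, {
    as.numeric(centroid_proportion_curve(sample_pattern(spec, w)))
  })
  cs <- aggregate_curves(t(curves), grid = 1:10)
  truth <- (1:10) / 10
  # Rc estimation biases the last bins slightly; 9 of 10 inside suffices
  inside <- truth >= cs$band_low & truth <= cs$band_high
  expect_gte(sum(inside), 9)
})

test_that("pairwise distance histograms bin every unordered pair", {
  tri <- unit_pattern(cbind(c(0, 1, 0.5), c(0, 0, sqrt(3) / 2)))
  h <- pairwise_distance_histogram(tri, bin_edges = c(0, 0.5, 1.5))
  expect_equal(sum(h$counts), 3)
  expect_equal(h$counts, c(0, 3))   # all three distances are exactly 1
  set.seed(60)
  p10 <- unit_pattern(cbind(runif(10, -50, 50), runif(10, -50, 50)))
  h10 <- pairwise_distance_histogram(p10)
  expect_equal(sum(h10$counts), 45)
  expect_equal(h10$n_pairs, 45L)
  # scale equivariance: x2 coordinates, x2 bin edges, identical counts
  p2 <- unit_pattern(p10$points * 2)
  h2 <- pairwise_distance_histogram(p2, bin_edges = h10$bin_edges * 2)
  expect_identical(h2$counts, h10$counts)
  expect_message(pairwise_distance_histogram(unit_pattern(cbind(1, 1))),
                 "skipping")
})

test_that("delaunay summary is exact on the unit square", {
  # 5 x 2 window of area exactly 10 um^2 around the unit square
  w10 <- abdomen_window(cbind(c(-2, 3, 3, -2), c(-0.5, -0.5, 1.5, 1.5)))
  sq <- point_pattern(cbind(c(0, 1, 1, 0), c(0, 0, 1, 1)), w10, check = FALSE)
  ds <- delaunay_summary(sq, keep_triangles = TRUE)
  expect_identical(ds$n_triangles, 2L)
  expect_equal(ds$mean_triangle_area_fraction, 0.05)
  expect_identical(nrow(ds$triangles), 2L)
  # sum of degrees = 2 * number of edges
  expect_equal(sum(ds$degrees), 2 * nrow(ds$edges))
})

test_that("delaunay triangle counts satisfy the euler relation", {
  set.seed(61)
  w <- disk_window(100)
  for (i in 1:5) {
    n <- sample(10:40, 1)
    p <- point_pattern(hemospat:::runif_in_window(n, w), w, check = FALSE)
    ds <- delaunay_summary(p)
    h <- bf_hull_size(p$points)
    expect_identical(ds$n_triangles, 2L * n - 2L - as.integer(h))
    expect_equal(sum(ds$degrees), 2 * nrow(ds$edges))
  }
})

test_that("edge pruning empties the neighbor graph below the minimum spacing", {
  set.seed(62)
  w <- disk_window(100)
  p <- point_pattern(hemospat:::runif_in_window(20, w), w, check = FALSE)
  min_pair <- min(dist(p$points))
  ds <- delaunay_summary(p, max_edge = min_pair * 0.9)
  expect_true(all(ds$degrees == 0))
  expect_identical(ds$n_triangles, 0L)
})

test_that("degenerate patterns give an undefined summary, not an error", {
  w <- disk_window(100)
  expect_message(ds2 <- delaunay_summary(point_pattern(cbind(c(0, 1), c(0, 0)),
                                                       w, check = FALSE)),
                 "fewer than 3")
  expect_true(ds2$undefined)
  coll <- point_pattern(cbind(c(0, 1, 2, 3), c(0, 1, 2, 3)), w, check = FALSE)
  expect_message(ds3 <- delaunay_summary(coll), "collinear")
  expect_true(ds3$undefined)
})

test_that("knn distances agree with the exhaustive distance matrix", {
  set.seed(63)
  for (i in 1:5) {
    n <- sample(8:50, 1)
    k <- sample(1:5, 1)
    pts <- cbind(runif(n, 0, 100), runif(n, 0, 100))
    expect_equal(knn_distances(pts, k, block = 7L), bf_knn(pts, k))
  }
})

test_that("the g-function matches brute force and steps where it should", {
  w <- disk_window(100)
  # k = 1, two points at distance d: unit step at d
  d <- 13.7
  p2 <- point_pattern(cbind(c(0, d), c(0, 0)), w, check = FALSE)
  g <- knn_gfunction(p2, k = 1, grid = c(5, 13.69, 13.71, 50))
  expect_equal(unname(g$mean_curve), c(0, 0, 1, 1))
  # six listed points, k = 2: ECDF of the 12 brute-force j-NN distances
  pts6 <- cbind(c(0, 3, 10, 11, 30, 31), c(0, 4, 0, 0, 5, 5))
  p6 <- point_pattern(pts6, w, check = FALSE)
  grid <- seq(0, 40, by = 0.5)
  g6 <- knn_gfunction(p6, k = 2, grid = grid)
  ref <- vapply(grid, function(r) mean(bf_knn(pts6, 2) <= r), numeric(1))
  expect_equal(unname(g6$mean_curve), ref)
  # patterns with n <= k are excluded with a warning
  expect_warning(
    g_mix <- knn_gfunction(list(p6, p2), k = 2, grid = grid),
    "excluded"
  )
  expect_identical(g_mix$n_curves, 1L)
})

test_that("statistics are translation invariant and scale linearly", {
  set.seed(64)
  w <- disk_window(100)
  pts <- hemospat:::runif_in_window(25, w)
  p <- point_pattern(pts, w, check = FALSE)
  shift <- c(123.4, -56.7)
  w_t <- abdomen_window(sweep(w$vertices, 2, -shift))
  p_t <- point_pattern(sweep(pts, 2, -shift), w_t, check = FALSE)
  expect_equal(annulus_radii(p_t)$Rc, annulus_radii(p)$Rc)
  expect_equal(centroid_proportion_curve(p_t), centroid_proportion_curve(p),
               ignore_attr = TRUE)
  expect_equal(knn_distances(p_t$points, 3), knn_distances(p$points, 3))
  expect_equal(delaunay_summary(p_t)$mean_triangle_area_fraction,
               delaunay_summary(p)$mean_triangle_area_fraction)
  # isotropic scaling: distances scale linearly
  s <- 2.5
  w_s <- abdomen_window(w$vertices * s)
  p_s <- point_pattern(pts * s, w_s, check = FALSE)
  expect_equal(annulus_radii(p_s)$Rc, s * annulus_radii(p)$Rc)
  expect_equal(knn_distances(p_s$points, 1), s * knn_distances(pts, 1))
})

test_that("patterns normalize into the closed unit disk", {
  w <- square_window(100, origin = c(-10, -40))  # centroid exactly (40, 10)
  pts <- rbind(c(40, 10), c(90, 10), c(40, 35))
  p <- point_pattern(pts, w, check = FALSE)
  z <- normalize_pattern(p)
  expect_equal(unname(z[1, ]), c(0, 0))
  expect_equal(max(sqrt(rowSums(z^2))), 1)       # farthest point on the rim
  expect_equal(unname(z[3, ]), c(0, 0.5))        # half-radius point
  p0 <- point_pattern(matrix(c(40, 10), 1), w, check = FALSE)
  expect_message(z0 <- normalize_pattern(p0), "centroid")
  expect_equal(z0, matrix(0, 1, 2), ignore_attr = TRUE)
})

test_that("2d coordinate histograms conserve counts and detect center bias", {
  w <- disk_window(100)
  set.seed(65)
  p7 <- point_pattern(hemospat:::runif_in_window(7, w), w, check = FALSE)
  h <- coordinate_histogram_2d(list(p7), bins = 8)
  expect_equal(sum(h), 7)
  # center-biased cohorts concentrate mass near the origin vs matched csr
  spec_csr <- scene_spec(semi_axes = c(80, 80), boundary_jitter = 0,
                         intensity = 100 / (pi * 80^2))
  spec_cb <- scene_spec(semi_axes = c(80, 80), boundary_jitter = 0,
                        intensity = 100 / (pi * 80^2),
                        process_kind = "center_biased", bias_exponent = 2)
  set.seed(66)
  win <- make_abdomen_window(spec_csr)
  pats_csr <- replicate(20, sample_pattern(spec_csr, win), simplify = FALSE)
  pats_cb <- replicate(20, sample_pattern(spec_cb, win), simplify = FALSE)
  central_fraction <- function(pats) {
    z <- do.call(rbind, lapply(pats, normalize_pattern))
    mean(sqrt(rowSums(z^2)) <= 0.3)
  }
  expect_gt(central_fraction(pats_cb), central_fraction(pats_csr))
})
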