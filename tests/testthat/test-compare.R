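test_that("area QC keeps comparable sections and logs every drop", {
  secs <- data.frame(section_id = c("a", "b", "c", "d"),
                     window_area_um2 = c(100, 100, 100, 10))
  out <- qc_filter_sections(secs)
  expect_identical(out$kept$section_id, c("a", "b", "c"))
  expect_identical(out$log$section_id, "d")
  expect_match(out$log$reason, "below")
  # equal areas: everything kept
  eq <- data.frame(section_id = letters[1:3], window_area_um2 = rep(5, 3))
  expect_identical(nrow(qc_filter_sections(eq)$kept), 3L)
  # identity filter
  all_kept <- qc_filter_sections(secs, low_frac = 0, high_frac = Inf)
  expect_identical(nrow(all_kept$kept), 4L)
  # everything out of range errors
  expect_error(qc_filter_sections(secs[4, ], low_frac = 2, high_frac = 3),
               "QC removed all sections")
})

test_that("per-fly averaging reduces sections to fly means", {
  expect_equal(unname(per_fly_average(c(10, 20), c("f", "f"))), 15)
  out <- per_fly_average(c(1, 2, 3, 4), c("a", "a", "a", "b"))
  expect_equal(out[["a"]], 2)
  expect_equal(out[["b"]], 4)
  # one section per fly: identity
  expect_equal(unname(per_fly_average(c(7, 9), c("x", "y"))), c(7, 9))
  # missing values are omitted with a note
  expect_message(m <- per_fly_average(c(1, NA, 5), c("a", "a", "b")), "omitted")
  expect_equal(m[["a"]], 1)
})

test_that("mann-whitney U and exact p match hand calculations", {
  mw <- mann_whitney_u(c(1, 2), c(3, 4))
  expect_equal(mw$U, 0)
  expect_equal(mw$p_value, 2 / 6)
  expect_identical(mw$method, "exact")
  # complete separation the other way
  mw2 <- mann_whitney_u(c(3, 4), c(1, 2))
  expect_equal(mw2$U, 4)
  expect_equal(mw2$p_value, 2 / 6)
  # identical samples: no separation, p = 1
  mw3 <- mann_whitney_u(c(1, 2, 3), c(1, 2, 3))
  expect_equal(mw3$p_value, 1)
  expect_error(mann_whitney_u(numeric(0), 1), "nonempty")
})

test_that("mann-whitney properties: symmetry, U + U' = nm, tie handling", {
  set.seed(80)
  for (i in 1:20) {
    x <- rnorm(sample(2:9, 1)); y <- rnorm(sample(2:9, 1))
    a <- mann_whitney_u(x, y); b <- mann_whitney_u(y, x)
    expect_equal(a$p_value, b$p_value, tolerance = 1e-12)
    expect_equal(a$U + b$U, length(x) * length(y))
  }
  # ties force the corrected normal approximation
  expect_warning(mwt <- mann_whitney_u(c(1, 1, 2), c(1, 2, 2), exact = TRUE),
                 "ties")
  expect_identical(mwt$method, "normal_approx")
  expect_true(mwt$p_value >= 0 && mwt$p_value <= 1)
})

test_that("exact p equals the permutation p on moderate samples", {
  set.seed(81)
  for (i in 1:10) {
    x <- rnorm(sample(3:6, 1)); y <- rnorm(sample(3:6, 1))
    expect_equal(mann_whitney_u(x, y)$p_value, bf_mw_perm_p(x, y),
                 tolerance = 1e-12)
  }
  # cross-check against the standard implementation as well
  set.seed(82)
  x <- rnorm(6); y <- rnorm(5)
  expect_equal(mann_whitney_u(x, y)$p_value,
               stats::wilcox.test(x, y, exact = TRUE)$p.value,
               tolerance = 1e-12)
})

test_that("per-section statistics record NA when undefined", {
  w <- disk_window(50)
  p1 <- point_pattern(cbind(10, 0), w, check = FALSE,
                      metadata = list(fly_id = "f", condition = "fed",
                                      section_id = "s"))
  s1 <- section_statistics(p1)
  expect_identical(s1$hemocyte_count, 1L)
  expect_true(is.na(s1$median_nn_distance))
  expect_true(is.na(s1$mean_triangle_area_fraction))
  expect_equal(s1$median_centroid_distance, 10)
})

test_that("comparison reports are label-symmetric and need both conditions", {
  co <- generate_cohort(c(3L, 3L), 2L, scene_spec(semi_axes = c(60, 40)),
                        scene_spec(semi_axes = c(60, 40),
                                   process_kind = "center_biased"),
                        seed = 10, render = FALSE)
  stats_df <- do.call(rbind, lapply(co$patterns, section_statistics))
  a <- run_comparison(stats_df, conditions = c("fed", "starved"))
  b <- run_comparison(stats_df, conditions = c("starved", "fed"))
  expect_equal(a$p_table$p_value, b$p_table$p_value, tolerance = 1e-12)
  only_fed <- stats_df[stats_df$condition == "fed", ]
  expect_error(run_comparison(only_fed), "starved")
})

test_that("type-I error stays near nominal under the null", {
  pv <- null_pvals_matrix(200)
  rates <- colMeans(pv < 0.05)
  expect_true(all(rates <= 0.07))
})
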