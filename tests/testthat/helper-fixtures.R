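# Shared fixtures and independent brute-force oracles.

square_window <- function(side = 100, origin = c(0, 0)) {
  abdomen_window(cbind(
    origin[1] + c(0, side, side, 0),
    origin[2] + c(0, 0, side, side)
  ))
}

disk_window <- function(r = 100, center = c(0, 0), n = 256) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  abdomen_window(cbind(center[1] + r * cos(th), center[2] + r * sin(th)))
}

# Brute-force j-th nearest neighbor distances, j = 1..k, via the full
# distance matrix (independent of knn_distances' blockwise path).
bf_knn <- function(points, k) {
  d <- as.matrix(dist(points))
  diag(d) <- Inf
  matrix(t(apply(d, 1, function(r) sort(r)[seq_len(k)])),
         nrow = nrow(d), ncol = k, byrow = FALSE)
}

# Exhaustive two-sided permutation p-value of the Mann-Whitney U statistic.
bf_mw_perm_p <- function(x, y) {
  n <- length(x); m <- length(y)
  pooled <- c(x, y)
  u_stat <- function(xi) {
    xx <- pooled[xi]; yy <- pooled[-xi]
    sum(outer(xx, yy, ">")) + 0.5 * sum(outer(xx, yy, "=="))
  }
  u_obs <- u_stat(seq_len(n))
  combos <- utils::combn(n + m, n)
  us <- apply(combos, 2, u_stat)
  mu <- n * m / 2
  # two-sided: permutations at least as extreme in |U - nm/2|
  mean(abs(us - mu) >= abs(u_obs - mu) - 1e-9)
}

# Direct Yen criterion scan over all 8-bit split levels (plain sums).
bf_yen_scan <- function(pixels) {
  counts <- tabulate(as.vector(pixels) + 1L, nbins = 256)
  p <- counts / sum(counts)
  best_t <- NA_integer_; best <- -Inf
  for (t in 0:254) {
    P1 <- sum(p[1:(t + 1)])
    if (P1 <= 0 || P1 >= 1) next
    G1 <- sum(p[1:(t + 1)]^2)
    G2 <- sum(p[(t + 2):256]^2)
    crit <- -log(max(G1 * G2, .Machine$double.xmin)) + 2 * log(P1 * (1 - P1))
    if (crit > best) { best <- crit; best_t <- t }
  }
  best_t + 0.5   # threshold between level t and t + 1
}

# Is the circumcircle of triangle (a, b, c) empty of all other points?
# Standard in-circle determinant test.
bf_circumcircle_empty <- function(pts, ia, ib, ic, tol = 1e-9) {
  a <- pts[ia, ]; b <- pts[ib, ]; c <- pts[ic, ]
  # ensure counterclockwise orientation
  orient <- (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1])
  if (orient < 0) { tmp <- b; b <- c; c <- tmp }
  others <- setdiff(seq_len(nrow(pts)), c(ia, ib, ic))
  for (id in others) {
    d <- pts[id, ]
    m <- rbind(
      c(a[1] - d[1], a[2] - d[2], (a[1] - d[1])^2 + (a[2] - d[2])^2),
      c(b[1] - d[1], b[2] - d[2], (b[1] - d[1])^2 + (b[2] - d[2])^2),
      c(c[1] - d[1], c[2] - d[2], (c[1] - d[1])^2 + (c[2] - d[2])^2)
    )
    if (det(m) > tol) return(FALSE)   # d strictly inside the circumcircle
  }
  TRUE
}

# Number of convex hull vertices (for the Euler triangle-count relation).
bf_hull_size <- function(pts) {
  length(unique(grDevices::chull(pts)))
}

# A well-separated high-SNR scene: points placed by hard-core rejection so
# every pair is at least min_spacing apart.
make_separated_pattern <- function(window, n, min_spacing) {
  pts <- matrix(numeric(0), ncol = 2)
  tries <- 0
  while (nrow(pts) < n && tries < 20000) {
    cand <- hemospat:::runif_in_window(1, window)
    tries <- tries + 1
    if (nrow(pts) == 0 ||
        min(sqrt((pts[, 1] - cand[1])^2 + (pts[, 2] - cand[2])^2)) >= min_spacing) {
      pts <- rbind(pts, cand)
    }
  }
  point_pattern(pts, window, check = FALSE)
}

# --- memoized cohort simulations shared by the comparison and acceptance
# tests (the null simulation is reused for the type-I checks) ---------------

.sim_cache <- new.env(parent = emptyenv())

sim_cohort_pvals <- function(seed, starved_kind) {
  fed <- scene_spec(process_kind = "csr")
  starved <- scene_spec(process_kind = starved_kind)
  co <- generate_cohort(c(8L, 10L), 3L, fed, starved, seed = seed,
                        render = FALSE)
  stats_df <- do.call(rbind, lapply(co$patterns, section_statistics))
  rep <- run_comparison(stats_df)
  stats::setNames(rep$p_table$p_value, rep$p_table$statistic)
}

null_pvals_matrix <- function(n_runs = 200) {
  key <- paste0("null_", n_runs)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- t(vapply(
      seq_len(n_runs),
      function(s) sim_cohort_pvals(1000 + s, "csr"),
      sim_cohort_pvals(1000, "csr")
    ))
  }
  .sim_cache[[key]]
}

power_pvals_matrix <- function(n_runs = 100) {
  key <- paste0("power_", n_runs)
  if (is.null(.sim_cache[[key]])) {
    .sim_cache[[key]] <- t(vapply(
      seq_len(n_runs),
      function(s) sim_cohort_pvals(5000 + s, "center_biased"),
      sim_cohort_pvals(5000, "center_biased")
    ))
  }
  .sim_cache[[key]]
}
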