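#' Quality-control filter on section areas
#'
#' Keeps sections whose window area is comparable across the cohort: the
#' default rule retains areas within `[low_frac, high_frac]` times the cohort
#' median, discarding the small sections cut from the dorsal/ventral
#' extremities of the abdomen (and any outsized ones). Every exclusion is
#' logged with the offending area and the bound it violated, so the QC is
#' auditable.
#'
#' @param sections data frame with at least `section_id` and the area column.
#' @param low_frac,high_frac multiples of the median area bounding the kept
#'   range.
#' @param area_col name of the area column (um^2).
#' @return list with `kept` (filtered data frame) and `log` (data frame of
#'   drops: `section_id`, `area`, `bound`, `reason`).
#' @export
qc_filter_sections <- function(sections, low_frac = 0.5, high_frac = 1.5,
                               area_col = "window_area_um2") {
  stopifnot(is.data.frame(sections), nrow(sections) >= 1,
            area_col %in% names(sections), low_frac >= 0,
            high_frac >= low_frac)
  areas <- sections[[area_col]]
  med <- stats::median(areas)
  lo <- low_frac * med; hi <- high_frac * med
  keep <- areas >= lo & areas <= hi
  log <- data.frame(
    section_id = sections$section_id[!keep],
    area = areas[!keep],
    bound = ifelse(areas[!keep] < lo, lo, hi),
    reason = ifelse(areas[!keep] < lo,
                    sprintf("area below %.3g x median", low_frac),
                    sprintf("area above %.3g x median", high_frac)),
    stringsAsFactors = FALSE
  )
  if (!any(keep)) stop("QC removed all sections", call. = FALSE)
  list(kept = sections[keep, , drop = FALSE], log = log)
}

#' Average section values within each fly
#'
#' The fly is the experimental unit: section-level values are averaged per
#' fly before any between-condition test. Flies with no kept sections are
#' simply absent from the output.
#'
#' @param values numeric vector of per-section values.
#' @param fly_id character/factor vector of the same length mapping each
#'   section to its fly.
#' @return named numeric vector, one arithmetic mean per fly.
#' @examples
#' per_fly_average(c(1, 2, 3, 4), c("a", "a", "a", "b"))  # a = 2, b = 4
#' @export
per_fly_average <- function(values, fly_id) {
  stopifnot(length(values) == length(fly_id))
  ok <- !is.na(values)
  if (any(!ok)) {
    message(sprintf("per_fly_average: %d missing section values omitted",
                    sum(!ok)))
  }
  vapply(split(values[ok], as.character(fly_id[ok])), mean, numeric(1))
}

#' Two-sample Mann-Whitney U test
#'
#' Rank-based nonparametric comparison of two samples. The statistic is
#' `U = #\{(i, j): x_i > y_j\} + 0.5 * #\{ties\}`, computed from midranks.
#' With both sample sizes at most `exact_max` and no ties, the two-sided
#' p-value comes from the exact null distribution of U (equivalent to the
#' permutation distribution over all choose(n+m, n) labelings); otherwise
#' the normal approximation with tie-corrected variance and continuity
#' correction is used. The method actually applied is recorded in the
#' result.
#'
#' @param x,y numeric samples (nonempty).
#' @param exact force (`TRUE`) or forbid (`FALSE`) the exact p-value; the
#'   default `NULL` uses exact when both sizes are `<= exact_max` and there
#'   are no ties. Exact with ties is refused (falls back with a warning).
#' @param exact_max size cutoff of the automatic exact rule.
#' @return a `mann_whitney` list: `U`, `p_value`, `method` ("exact" or
#'   "normal_approx"), `n_x`, `n_y`, `ties`.
#' @examples
#' mann_whitney_u(c(1, 2), c(3, 4))  # U = 0, exact p = 1/3
#' @export
mann_whitney_u <- function(x, y, exact = NULL, exact_max = 8L) {
  if (length(x) < 1 || length(y) < 1) {
    stop("both samples must be nonempty", call. = FALSE)
  }
  stopifnot(all(is.finite(x)), all(is.finite(y)))
  nx <- length(x); ny <- length(y)
  combined <- c(x, y)
  r <- rank(combined)
  U <- sum(r[seq_len(nx)]) - nx * (nx + 1) / 2
  ties <- anyDuplicated(combined) > 0
  if (is.null(exact)) exact <- (nx <= exact_max && ny <= exact_max && !ties)
  if (exact && ties) {
    warning("exact Mann-Whitney p-value is not available with ties; using normal approximation",
            call. = FALSE)
    exact <- FALSE
  }
  if (exact) {
    # two-sided exact p from the null distribution of U
    if (U > nx * ny / 2) {
      p <- 2 * (1 - stats::pwilcox(U - 1, nx, ny))
    } else {
      p <- 2 * stats::pwilcox(U, nx, ny)
    }
    p <- min(p, 1)
    method <- "exact"
  } else {
    N <- nx + ny
    tie_counts <- table(combined)
    tie_term <- sum(tie_counts^3 - tie_counts)
    sigma2 <- (nx * ny / 12) * ((N + 1) - tie_term / (N * (N - 1)))
    z <- U - nx * ny / 2
    if (sigma2 <= 0) {
      p <- 1
    } else {
      z <- z - sign(z) * 0.5           # continuity correction
      p <- min(2 * stats::pnorm(-abs(z) / sqrt(sigma2)), 1)
    }
    method <- "normal_approx"
  }
  structure(list(U = U, p_value = p, method = method, n_x = nx, n_y = ny,
                 ties = ties),
            class = "mann_whitney")
}

#' @export
print.mann_whitney <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g, two-sided p = %.4g (%s; n = %d vs %d)\n",
              x$U, x$p_value, x$method, x$n_x, x$n_y))
  invisible(x)
}

#' Per-section statistic panel
#'
#' Computes the scalar localization statistics for one section from its
#' (detected or ground-truth) point pattern: hemocyte count, median
#' 1st-nearest-neighbor distance, median distance to the window centroid,
#' and the Delaunay mean-triangle-area fraction. When a detection table is
#' supplied, the percentage of window area occupied is included as well.
#' Statistics whose preconditions fail (too few points) are recorded as
#' `NA`, never imputed.
#'
#' @param pattern a [point_pattern()].
#' @param detections optional detection data frame (for `pct_area_occupied`).
#' @return one-row data frame with the section metadata and statistics.
#' @export
section_statistics <- function(pattern, detections = NULL) {
  stopifnot(inherits(pattern, "point_pattern"))
  n <- npoints(pattern)
  med_nn <- if (n >= 2) stats::median(knn_distances(pattern$points, 1)[, 1]) else NA_real_
  med_d2c <- if (n >= 1) stats::median(centroid_distances(pattern)) else NA_real_
  tri_frac <- if (n >= 3) {
    ds <- suppressMessages(delaunay_summary(pattern))
    if (ds$undefined) NA_real_ else ds$mean_triangle_area_fraction
  } else {
    NA_real_
  }
  meta <- function(key) if (is.null(pattern$metadata[[key]])) NA_character_ else pattern$metadata[[key]]
  data.frame(
    fly_id = meta("fly_id"), condition = meta("condition"),
    section_id = meta("section_id"),
    window_area_um2 = pattern$window$area,
    hemocyte_count = n,
    pct_area_occupied = if (is.null(detections)) NA_real_ else
      percent_area_occupied(detections, pattern$window),
    median_nn_distance = med_nn,
    median_centroid_distance = med_d2c,
    mean_triangle_area_fraction = tri_frac,
    stringsAsFactors = FALSE
  )
}

#' Compare conditions across the statistic panel
#'
#' The full statistical stage: quality-control filtering on section area,
#' per-fly averaging of each statistic, and a two-sided Mann-Whitney U test
#' per statistic between the two conditions. When section point patterns are
#' supplied, the per-condition centroid-distance ECDF and k-nearest-neighbor
#' G-function curve sets are attached. Unadjusted p-values are reported (one
#' test per statistic, as in the motivating analysis), with a Holm-adjusted
#' column added for transparency.
#'
#' @param section_stats data frame of per-section rows as produced by
#'   [section_statistics()] (columns `fly_id`, `condition`, `section_id`,
#'   `window_area_um2` plus statistic columns).
#' @param patterns optional named list of [point_pattern()]s (names =
#'   section ids) used for the curve sets.
#' @param conditions length-2 character, reference then comparison condition.
#' @param qc_low_frac,qc_high_frac area QC bounds (see
#'   [qc_filter_sections()]).
#' @param statistics statistic columns to test; defaults to every panel
#'   column present.
#' @param exact passed to [mann_whitney_u()].
#' @param k,g_grid G-function parameters (neighbors pooled; distance grid in
#'   um, `NULL` for an automatic grid).
#' @return a `hemocyte_comparison`: list with `p_table` (statistic, U,
#'   p_value, p_holm, method, n_fed, n_starved), `results` (per-statistic
#'   detail incl. per-fly values), `qc` (kept/dropped log), `curves`
#'   (per-condition `curve_set`s), `conditions`.
#' @export
run_comparison <- function(section_stats, patterns = NULL,
                           conditions = c("fed", "starved"),
                           qc_low_frac = 0.5, qc_high_frac = 1.5,
                           statistics = NULL, exact = NULL,
                           k = 5, g_grid = NULL) {
  stopifnot(is.data.frame(section_stats), length(conditions) == 2)
  present <- unique(section_stats$condition)
  missing_cond <- setdiff(conditions, present)
  if (length(missing_cond) > 0) {
    stop(sprintf("condition '%s' absent from the data", missing_cond[1]),
         call. = FALSE)
  }
  qc <- qc_filter_sections(section_stats, qc_low_frac, qc_high_frac)
  kept <- qc$kept
  if (is.null(statistics)) {
    panel <- c("hemocyte_count", "pct_area_occupied", "median_nn_distance",
               "median_centroid_distance", "mean_triangle_area_fraction")
    statistics <- intersect(panel, names(kept))
    statistics <- statistics[vapply(statistics,
                                    function(s) !all(is.na(kept[[s]])),
                                    logical(1))]
  }
  results <- list()
  for (s in statistics) {
    a <- kept[kept$condition == conditions[1], ]
    b <- kept[kept$condition == conditions[2], ]
    fa <- per_fly_average(a[[s]], a$fly_id)
    fb <- per_fly_average(b[[s]], b$fly_id)
    mw <- mann_whitney_u(as.numeric(fa), as.numeric(fb), exact = exact)
    results[[s]] <- list(
      statistic_name = s,
      per_fly = data.frame(
        fly_id = c(names(fa), names(fb)),
        condition = rep(conditions, c(length(fa), length(fb))),
        value = c(as.numeric(fa), as.numeric(fb)),
        stringsAsFactors = FALSE
      ),
      U = mw$U, p_value = mw$p_value, method = mw$method,
      n_fed = length(fa), n_starved = length(fb)
    )
  }
  p_table <- data.frame(
    statistic = names(results),
    U = vapply(results, `[[`, numeric(1), "U"),
    p_value = vapply(results, `[[`, numeric(1), "p_value"),
    method = vapply(results, `[[`, character(1), "method"),
    n_fed = vapply(results, `[[`, integer(1), "n_fed"),
    n_starved = vapply(results, `[[`, integer(1), "n_starved"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  p_table$p_holm <- stats::p.adjust(p_table$p_value, method = "holm")
  curves <- NULL
  if (!is.null(patterns)) {
    curves <- condition_curves(patterns, kept, conditions, k = k,
                               g_grid = g_grid)
  }
  structure(list(p_table = p_table, results = results, qc = qc,
                 curves = curves, conditions = conditions),
            class = "hemocyte_comparison")
}

# Per-condition centroid-ECDF and G-function curve sets over kept sections.
condition_curves <- function(patterns, kept, conditions, k = 5,
                             g_grid = NULL) {
  out <- list()
  for (cond in conditions) {
    ids <- kept$section_id[kept$condition == cond]
    pats <- patterns[intersect(ids, names(patterns))]
    pats <- Filter(function(p) npoints(p) >= 1, pats)
    ec <- NULL
    usable <- Filter(function(p) npoints(p) >= 1, pats)
    if (length(usable) >= 2) {
      cur <- lapply(usable, centroid_proportion_curve)
      ec <- aggregate_curves(lapply(cur, as.numeric), grid = 1:10)
    }
    gf <- NULL
    gpats <- Filter(function(p) npoints(p) > k, pats)
    if (length(gpats) >= 2) {
      if (is.null(g_grid)) {
        dmax <- stats::quantile(unlist(lapply(gpats, function(p)
          knn_distances(p$points, min(k, npoints(p) - 1))[, 1])), 0.99)
        g_grid <- seq(0, max(dmax * 3, 1), length.out = 50)
      }
      gf <- suppressWarnings(knn_gfunction(gpats, k = k, grid = g_grid))
    }
    out[[cond]] <- list(ecdf = ec, gfunction = gf)
  }
  out
}

#' @export
print.hemocyte_comparison <- function(x, ...) {
  cat(sprintf("<hemocyte_comparison> %s vs %s, %d sections kept, %d dropped\n",
              x$conditions[1], x$conditions[2], nrow(x$qc$kept),
              nrow(x$qc$log)))
  print(x$p_table, row.names = FALSE)
  invisible(x)
}
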