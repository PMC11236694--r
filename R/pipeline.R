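#' Run the full analysis pipeline
#'
#' Executes every stage end to end on a synthetic cohort: simulation
#' ([stage_simulate()]), segmentation ([stage_segment()]), spatial statistics
#' ([stage_stats()]) and condition comparison ([stage_compare()]). All
#' randomness derives from the configured seed, and every output is a plain
#' CSV/JSON file, so a rerun with the same configuration reproduces the run
#' byte for byte.
#'
#' @param config a [pipeline_config()] (or anything accepted by it).
#' @param seed overrides the configured seed when given.
#' @param outdir overrides the configured output directory when given.
#' @return invisibly, the [run_comparison()] report of the final stage.
#' @export
run_pipeline <- function(config = pipeline_config(), seed = NULL,
                         outdir = NULL) {
  cfg <- as_pipeline_config(config, seed, outdir)
  stage_simulate(cfg)
  stage_segment(cfg)
  stage_stats(cfg)
  report <- stage_compare(cfg)
  write_run_summary(cfg)
  invisible(report)
}

as_pipeline_config <- function(config, seed = NULL, outdir = NULL) {
  cfg <- if (inherits(config, "pipeline_config")) config else pipeline_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  if (!is.null(outdir)) cfg$outdir <- outdir
  cfg
}

#' Pipeline stages
#'
#' The four stages of [run_pipeline()], each reading its inputs from and
#' writing its outputs to `config$outdir` so they can also be run (and
#' rerun) individually:
#'
#' * `stage_simulate`: generates the synthetic cohort — TIFF images,
#'   ground-truth CSVs, window boundary CSVs and `manifest.csv`.
#' * `stage_segment`: Yen threshold + background suppression + watershed
#'   detection per section; writes `<section>_features.csv` (QuPath-style
#'   columns) and `segmentation_summary.csv` with per-section F1 against
#'   ground truth where truth is available.
#' * `stage_stats`: rebuilds point patterns from the feature CSVs and writes
#'   the per-section statistic panel (`section_stats.csv`), tidy per-
#'   condition curve tables (`curves_ecdf.csv`, `curves_gfunction.csv`) and
#'   pooled 2D coordinate histograms (`coordhist_<condition>.csv`).
#' * `stage_compare`: area QC, per-fly averaging and Mann-Whitney tests;
#'   writes `comparison.csv`, `per_fly_values.csv` and `qc_log.csv`.
#'
#' @param config a [pipeline_config()].
#' @name pipeline_stages
NULL

#' @rdname pipeline_stages
#' @export
stage_simulate <- function(config) {
  cfg <- as_pipeline_config(config)
  dir.create(cfg$outdir, recursive = TRUE, showWarnings = FALSE)
  sg <- cfg$synthgen
  cohort <- generate_cohort(
    n_flies = c(sg$n_fed_flies, sg$n_starved_flies),
    sections_per_fly = sg$sections_per_fly,
    fed_spec = sg$fed_spec, starved_spec = sg$starved_spec,
    seed = cfg$seed, outdir = cfg$outdir, render = TRUE
  )
  for (id in names(cohort$patterns)) {
    write_window_csv(cohort$patterns[[id]]$window,
                     file.path(cfg$outdir, paste0(id, "_boundary.csv")))
  }
  invisible(cohort$manifest)
}

#' @rdname pipeline_stages
#' @export
stage_segment <- function(config) {
  cfg <- as_pipeline_config(config)
  manifest <- utils::read.csv(file.path(cfg$outdir, "manifest.csv"))
  params <- do.call(detect_params, cfg$segment[names(cfg$segment) != "min_mean_intensity"])
  params$min_mean_intensity <- cfg$segment$min_mean_intensity
  seg_rows <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    meta <- list(fly_id = row$fly_id, condition = row$condition,
                 section_id = row$section_id)
    img <- read_section(file.path(cfg$outdir, row$image_path),
                        pixel_size = cfg$pixel_size, metadata = meta)
    win <- read_window_csv(file.path(cfg$outdir,
                                     paste0(row$section_id, "_boundary.csv")))
    det <- segment_section(img, win, params)
    export_features(det, win,
                    file.path(cfg$outdir, paste0(row$section_id, "_features.csv")),
                    metadata = meta)
    f1 <- NA_real_
    truth_file <- file.path(cfg$outdir, row$truth_path)
    if (!is.na(row$truth_path) && file.exists(truth_file)) {
      truth <- utils::read.csv(truth_file)
      ev <- evaluate_detections(as.matrix(det[, c("x_um", "y_um")]),
                                cbind(truth$x_um, truth$y_um), tolerance = 5)
      f1 <- ev$f1
    }
    seg_rows[[i]] <- data.frame(section_id = row$section_id,
                                n_detections = nrow(det),
                                threshold = attr(det, "threshold"), f1 = f1)
  }
  out <- do.call(rbind, seg_rows)
  utils::write.csv(out, file.path(cfg$outdir, "segmentation_summary.csv"),
                   row.names = FALSE)
  invisible(out)
}

#' @rdname pipeline_stages
#' @export
stage_stats <- function(config) {
  cfg <- as_pipeline_config(config)
  manifest <- utils::read.csv(file.path(cfg$outdir, "manifest.csv"))
  patterns <- read_cohort_patterns(cfg$outdir, manifest)
  stats_df <- do.call(rbind, lapply(names(patterns), function(id) {
    det <- utils::read.csv(file.path(cfg$outdir, paste0(id, "_features.csv")))
    section_statistics(patterns[[id]], detections = det)
  }))
  utils::write.csv(stats_df, file.path(cfg$outdir, "section_stats.csv"),
                   row.names = FALSE)
  sp <- cfg$spatstats
  g_grid <- seq(0, sp$g_grid_max, length.out = sp$g_grid_n)
  curves_ecdf <- list(); curves_g <- list()
  for (cond in c("fed", "starved")) {
    pats <- patterns[stats_df$section_id[stats_df$condition == cond]]
    pats <- Filter(function(p) npoints(p) >= 1, pats)
    if (length(pats) >= 2) {
      curves_ecdf[[cond]] <- aggregate_curves(
        lapply(pats, function(p) as.numeric(centroid_proportion_curve(p))),
        grid = 1:10
      )
    }
    gpats <- Filter(function(p) npoints(p) > sp$k, pats)
    if (length(gpats) >= 2) {
      curves_g[[cond]] <- suppressWarnings(
        knn_gfunction(gpats, k = sp$k, grid = g_grid)
      )
    }
    if (length(pats) >= 1) {
      ch <- coordinate_histogram_2d(pats, bins = sp$bins_2d)
      utils::write.csv(as.data.frame(unclass(ch)),
                       file.path(cfg$outdir, paste0("coordhist_", cond, ".csv")),
                       row.names = FALSE)
    }
  }
  write_curve_table(curves_ecdf, file.path(cfg$outdir, "curves_ecdf.csv"))
  write_curve_table(curves_g, file.path(cfg$outdir, "curves_gfunction.csv"))
  invisible(stats_df)
}

#' @rdname pipeline_stages
#' @export
stage_compare <- function(config) {
  cfg <- as_pipeline_config(config)
  stats_df <- utils::read.csv(file.path(cfg$outdir, "section_stats.csv"))
  cp <- cfg$compare
  report <- run_comparison(stats_df, patterns = NULL,
                           qc_low_frac = cp$qc_low_frac,
                           qc_high_frac = cp$qc_high_frac,
                           exact = cp$exact)
  utils::write.csv(report$p_table, file.path(cfg$outdir, "comparison.csv"),
                   row.names = FALSE)
  per_fly <- do.call(rbind, lapply(report$results, function(r) {
    cbind(statistic = r$statistic_name, r$per_fly)
  }))
  utils::write.csv(per_fly, file.path(cfg$outdir, "per_fly_values.csv"),
                   row.names = FALSE)
  utils::write.csv(report$qc$log, file.path(cfg$outdir, "qc_log.csv"),
                   row.names = FALSE)
  invisible(report)
}

# Rebuild point patterns from exported feature + boundary CSVs.
read_cohort_patterns <- function(outdir, manifest) {
  patterns <- list()
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    det <- utils::read.csv(file.path(outdir, paste0(row$section_id, "_features.csv")))
    win <- read_window_csv(file.path(outdir, paste0(row$section_id, "_boundary.csv")))
    patterns[[row$section_id]] <- point_pattern(
      cbind(det$x_um, det$y_um), win,
      metadata = list(fly_id = row$fly_id, condition = row$condition,
                      section_id = row$section_id),
      check = FALSE
    )
  }
  patterns
}

# Tidy CSV of per-condition curve sets: one row per (condition, section,
# grid value) plus mean/band rows labelled section_id = "__mean__".
write_curve_table <- function(curve_sets, path) {
  rows <- list()
  for (cond in names(curve_sets)) {
    cs <- curve_sets[[cond]]
    if (is.null(cs)) next
    ids <- rownames(cs$per_section_curves)
    if (is.null(ids)) ids <- paste0("s", seq_len(nrow(cs$per_section_curves)))
    for (r in seq_len(nrow(cs$per_section_curves))) {
      rows[[length(rows) + 1]] <- data.frame(
        condition = cond, section_id = ids[r], grid_value = cs$grid,
        curve_value = cs$per_section_curves[r, ],
        band_low = NA_real_, band_high = NA_real_
      )
    }
    rows[[length(rows) + 1]] <- data.frame(
      condition = cond, section_id = "__mean__", grid_value = cs$grid,
      curve_value = cs$mean_curve, band_low = cs$band_low,
      band_high = cs$band_high
    )
  }
  tab <- if (length(rows)) do.call(rbind, rows) else
    data.frame(condition = character(0), section_id = character(0),
               grid_value = numeric(0), curve_value = numeric(0),
               band_low = numeric(0), band_high = numeric(0))
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}

# JSON run summary: config hash, seed, package version, file inventory.
write_run_summary <- function(cfg) {
  summary <- list(
    package = "hemospat",
    version = as.character(utils::packageVersion("hemospat")),
    seed = cfg$seed,
    config_hash = config_hash(cfg),
    outputs = sort(list.files(cfg$outdir))
  )
  jsonlite::write_json(summary, file.path(cfg$outdir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  plain <- unclass(cfg)
  plain$synthgen$fed_spec <- unclass(plain$synthgen$fed_spec)
  plain$synthgen$starved_spec <- unclass(plain$synthgen$starved_spec)
  yaml::write_yaml(plain, file.path(cfg$outdir, "config_used.yaml"))
  invisible(summary)
}
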