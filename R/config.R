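#' Pipeline configuration
#'
#' Loads and validates the configuration driving a full pipeline run. The
#' configuration is a nested list (or a YAML file with the same structure)
#' with blocks `synthgen`, `segment`, `spatstats` and `compare`; unknown keys
#' at any level are rejected so typos cannot silently fall back to defaults.
#' A serialized copy is written into every output directory by
#' [run_pipeline()].
#'
#' Top-level keys: `seed`, `pixel_size`, `outdir`.
#' `synthgen`: `n_fed_flies`, `n_starved_flies`, `sections_per_fly`, and
#' `fed` / `starved` sub-blocks of [scene_spec()] arguments.
#' `segment`: [detect_params()] arguments.
#' `spatstats`: `k`, `g_grid_max`, `g_grid_n`, `bins_2d`, `max_edge`.
#' `compare`: `qc_low_frac`, `qc_high_frac`, `exact`.
#'
#' @param x path to a YAML file, or a nested list of overrides (possibly
#'   empty for all defaults).
#' @return a validated `pipeline_config` list.
#' @export
pipeline_config <- function(x = list()) {
  if (is.character(x)) {
    if (!file.exists(x)) stop(sprintf("config file '%s' not found", x), call. = FALSE)
    x <- yaml::read_yaml(x)
    if (is.null(x)) x <- list()
  }
  stopifnot(is.list(x))
  defaults <- list(
    seed = 1L,
    pixel_size = 0.207,
    outdir = "hemospat_run",
    synthgen = list(
      n_fed_flies = 8L, n_starved_flies = 10L, sections_per_fly = 3L,
      fed = list(process_kind = "csr"),
      starved = list(process_kind = "center_biased")
    ),
    segment = list(smooth_sigma = 1, min_area = 20, max_area = 200,
                   min_mean_intensity = NULL, watershed_tolerance = 1,
                   watershed_ext = 1),
    spatstats = list(k = 5L, g_grid_max = 60, g_grid_n = 60, bins_2d = 32L,
                     max_edge = NULL),
    compare = list(qc_low_frac = 0.5, qc_high_frac = 1.5, exact = NULL)
  )
  cfg <- merge_config(defaults, x, path = "config")
  # the scene-spec sub-blocks are validated by scene_spec() itself
  for (cond in c("fed", "starved")) {
    spec_args <- cfg$synthgen[[cond]]
    spec_args$pixel_size <- cfg$pixel_size
    cfg$synthgen[[paste0(cond, "_spec")]] <- do.call(scene_spec, spec_args)
  }
  stopifnot(cfg$synthgen$n_fed_flies >= 1, cfg$synthgen$n_starved_flies >= 1,
            cfg$synthgen$sections_per_fly >= 1)
  class(cfg) <- "pipeline_config"
  cfg
}

# Recursive default merge; rejects keys absent from the defaults. The
# scene-spec sub-blocks are free-form (checked by scene_spec()).
merge_config <- function(defaults, overrides, path) {
  free_form <- c("config$synthgen$fed", "config$synthgen$starved")
  unknown <- setdiff(names(overrides), names(defaults))
  if (length(unknown) > 0 && !(path %in% free_form)) {
    stop(sprintf("unknown config key '%s$%s'", path, unknown[1]), call. = FALSE)
  }
  if (path %in% free_form) return(utils::modifyList(defaults, overrides))
  out <- defaults
  for (key in names(overrides)) {
    if (is.list(defaults[[key]]) && is.list(overrides[[key]])) {
      out[[key]] <- merge_config(defaults[[key]], overrides[[key]],
                                 paste0(path, "$", key))
    } else {
      out[[key]] <- overrides[[key]]
    }
  }
  out
}

# Stable hash of the configuration for provenance logging.
config_hash <- function(cfg) {
  plain <- unclass(cfg)
  plain$synthgen$fed_spec <- unclass(plain$synthgen$fed_spec)
  plain$synthgen$starved_spec <- unclass(plain$synthgen$starved_spec)
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  yaml::write_yaml(plain, tmp)
  unname(tools::md5sum(tmp))
}
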