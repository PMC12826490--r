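## Configuration files, presets and run manifests.

## "resolution" maps onto simulation_config(n = ...); a bare "n" is a YAML 1.1
## boolean and cannot be used as a key.
CONFIG_SIM_KEYS <- c("resolution", "dt", "seed", "safety", "output_times",
                     "nucleus_stop_time", "growth_stop_time", "fc_shift",
                     "sty_fraction", "egfr_fraction", "grk_multiplier",
                     "gamma_sty_zero_after")
CONFIG_GEOM_KEYS <- c("dimensions_csv", "source_ratios_csv", "nucleus_start",
                      "anchor_time", "oocyte_floor")
CONFIG_SRC_KEYS <- c("bar_thickness", "ratio_dorsal_length",
                     "ratio_posterior_width", "ratio_anterior_width")

#' Load a simulation configuration from YAML
#'
#' Reads a flat YAML file whose keys are the kinetic parameter symbols (as in
#' [kinetic_params()]), simulation settings (`n`, `dt`, `seed`, `safety`,
#' `output_times`, perturbation switches), geometry settings
#' (`dimensions_csv`, `source_ratios_csv`, `nucleus_start`, `anchor_time`)
#' and source shape overrides. Unknown keys are rejected; missing keys fall
#' back to the packaged defaults; literature-range violations are reported as
#' warnings, invalid values as errors.
#'
#' @param path YAML file path, or `NULL` for pure defaults.
#' @return A [simulation_config()].
#' @export
load_config <- function(path = NULL) {
  raw <- if (is.null(path)) list() else yaml::read_yaml(path)
  if (is.null(raw)) raw <- list()
  kin_keys <- names(yaml::read_yaml(system.file("extdata", "kinetic_params.yaml",
                                                package = "grksim")))
  known <- c(kin_keys, CONFIG_SIM_KEYS, CONFIG_GEOM_KEYS, CONFIG_SRC_KEYS)
  bad <- setdiff(names(raw), known)
  if (length(bad) > 0L) {
    abort(paste0("unknown configuration keys: ", paste(bad, collapse = ", ")))
  }
  kin <- raw[intersect(names(raw), kin_keys)]
  params <- do.call(kinetic_params, kin)
  validate_params(params, warn_ranges = TRUE)

  dims <- if (!is.null(raw$dimensions_csv)) stage_dimensions(raw$dimensions_csv) else stage_dimensions()
  tl_args <- list(dims = dims)
  for (k in c("nucleus_start", "anchor_time", "oocyte_floor")) {
    if (!is.null(raw[[k]])) tl_args[[k]] <- raw[[k]]
  }
  timeline <- do.call(chamber_timeline, tl_args)

  ratios <- NULL
  if (!is.null(raw$source_ratios_csv)) {
    ratios <- tibble::as_tibble(read.csv(raw$source_ratios_csv, stringsAsFactors = FALSE))
  }
  src <- source_spec(V0 = params$V0, ratios = ratios,
                     bar_thickness = raw$bar_thickness %||% 0.1)
  for (k in c("ratio_dorsal_length", "ratio_posterior_width", "ratio_anterior_width")) {
    if (!is.null(raw[[k]])) {
      if (raw[[k]] <= 0 || raw[[k]] > 1) abort(paste0(k, " must be in (0, 1]"))
      src$ratios[[k]] <- raw[[k]]
    }
  }

  sim_args <- raw[intersect(names(raw), CONFIG_SIM_KEYS)]
  if (!is.null(sim_args$resolution)) {
    sim_args$n <- sim_args$resolution
    sim_args$resolution <- NULL
  }
  do.call(simulation_config,
          c(list(params = params, source = src, timeline = timeline), sim_args))
}

PRESETS <- list(
  "wt" = list(),
  "nucleus-stop" = list(nucleus_stop_time = 10.5),
  "no-fc-shift" = list(fc_shift = FALSE),
  "growth-stop" = list(growth_stop_time = 10.5),
  "sty-rnai" = list(sty_fraction = 0.5),
  "egfr-rnai" = list(egfr_fraction = 0.5),
  "grk-1x" = list(grk_multiplier = 0.5),
  "grk-4x" = list(grk_multiplier = 2)
)

#' Run a named perturbation preset
#'
#' Executes one of the standard experiments end-to-end and tabulates the
#' signal metrics: maximum dpERK at stages S8L, S9L and S10A, and signal
#' elongation (arc-length above `threshold` times the wild-type maximum at
#' the corresponding stage) at S9L and S10A, absolute and as percent of
#' wild type. Presets: `wt`, `nucleus-stop`, `no-fc-shift`, `growth-stop`,
#' `sty-rnai`, `egfr-rnai`, `grk-1x`, `grk-4x`.
#'
#' @param name Preset name.
#' @param config Base configuration (default [simulation_config()]).
#' @param wt A previously computed wild-type preset run to normalize against
#'   (avoids re-running it); `NULL` runs wild type as needed.
#' @param threshold Elongation threshold on the normalized signal.
#' @return A list of class `preset_run` with elements `name`, `sim`, `wt_sim`
#'   and `metrics` (a tibble).
#' @export
run_preset <- function(name, config = simulation_config(), wt = NULL,
                       threshold = 0.6) {
  if (!name %in% names(PRESETS)) {
    abort(paste0("unknown preset '", name, "'; available: ",
                 paste(names(PRESETS), collapse = ", ")))
  }
  cfg <- config
  for (k in names(PRESETS[[name]])) cfg[[k]] <- PRESETS[[name]][[k]]
  cfg$output_times <- sort(unique(c(cfg$output_times, 10.5, 16.5, 19.5)))
  sim <- simulate_chamber(cfg)
  wt_sim <- if (name == "wt") sim else if (!is.null(wt)) wt$sim else simulate_chamber(config)
  t_max <- c(10.5, 16.5, 19.5)
  t_el <- c(16.5, 19.5)
  maxes <- vapply(t_max, function(t) max_signal(sim, t), 0)
  wt_el <- vapply(t_el, function(t) {
    elongation(wt_sim, t, threshold, reference = max_signal(wt_sim, t))
  }, 0)
  el <- vapply(seq_along(t_el), function(i) {
    elongation(sim, t_el[i], threshold, reference = max_signal(wt_sim, t_el[i]))
  }, 0)
  metrics <- tibble::tibble(
    metric = c(paste0("max_dpERK_", c("S8L", "S9L", "S10A")),
               paste0("elongation_um_", c("S9L", "S10A")),
               paste0("elongation_pct_wt_", c("S9L", "S10A"))),
    value = c(maxes, el, 100 * el / wt_el)
  )
  structure(list(name = name, sim = sim, wt_sim = wt_sim, metrics = metrics,
                 threshold = threshold),
            class = "preset_run")
}

#' @export
print.preset_run <- function(x, ...) {
  cat("<preset_run> ", x$name, "\n", sep = "")
  print(x$metrics)
  invisible(x)
}

#' Run manifest
#'
#' Captures everything needed to reproduce a run bit-identically: package
#' version, the resolved configuration (defaults materialized), and digests
#' of the packaged fixture files.
#'
#' @param sim A [simulate_chamber()] result.
#' @param path Optional JSON output path.
#' @return The manifest as a list (invisibly if written to `path`).
#' @export
run_manifest <- function(sim, path = NULL) {
  cfg <- sim$config
  fixture_files <- c("stage_dimensions.csv", "kinetic_params.yaml", "source_ratios.csv")
  digests <- vapply(fixture_files, function(f) {
    unname(tools::md5sum(system.file("extdata", f, package = "grksim")))
  }, "")
  man <- list(
    package = "grksim",
    version = as.character(utils::packageVersion("grksim")),
    timestamp = format(Sys.time(), tz = "UTC"),
    n = cfg$n, dt = cfg$dt, seed = cfg$seed, safety = cfg$safety,
    output_times = cfg$output_times,
    perturbations = list(
      nucleus_stop_time = cfg$nucleus_stop_time,
      growth_stop_time = cfg$growth_stop_time,
      fc_shift = cfg$fc_shift,
      sty_fraction = cfg$sty_fraction,
      egfr_fraction = cfg$egfr_fraction,
      grk_multiplier = cfg$grk_multiplier,
      gamma_sty_zero_after = cfg$gamma_sty_zero_after
    ),
    params = unclass(sim$params),
    fixture_md5 = as.list(digests),
    n_steps = sim$n_steps,
    clip_count = sim$clip_count
  )
  if (!is.null(path)) {
    jsonlite::write_json(man, path, auto_unbox = TRUE, digits = NA, null = "null", pretty = TRUE)
    return(invisible(man))
  }
  man
}
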