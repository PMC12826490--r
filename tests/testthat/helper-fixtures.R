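## Shared fixtures: small meshes and configurations built in code, plus a
## session-level cache so expensive simulations are computed once and shared
## between test files.

.sim_cache <- new.env(parent = emptyenv())

## Deterministic key for a configuration (the solver itself is deterministic).
cfg_key <- function(cfg) {
  paste(utils::capture.output(utils::str(cfg[setdiff(names(cfg), c("timeline", "params", "source"))])),
        utils::capture.output(utils::str(unclass(cfg$params))),
        cfg$source$V0, cfg$grk_multiplier,
        collapse = "|")
}

cached_sim <- function(cfg) {
  key <- digest_key(cfg_key(cfg))
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- simulate_chamber(cfg)
  .sim_cache[[key]]
}

digest_key <- function(x) {
  ## tiny string hash (no external digest dependency)
  v <- utf8ToInt(paste(x, collapse = ""))
  as.character(sum(v * seq_along(v) %% 97) + 1e6 * (sum(v) %% 1009))
}

## Kinetics with every reaction switched off (transport-only runs).
silent_params <- function(...) {
  kinetic_params(
    D = 0, k_ec = 0, k_on = 0, k_off = 0, k_er = 0,
    alpha_rec = 0.5, alpha_deg = 0.5, k_rec = 0, k_deg = 0, k_d = 0,
    V0 = 0, Q_r = 0, k_s = 0, k_STY = 0, k_dSTY = 0, k_KEK1 = 0, k_dKEK1 = 0,
    ...
  )
}

## A chamber_sim-shaped object around a hand-built field (for profile and
## elongation unit tests).
fake_sim <- function(mesh, fields, t = 19.5, timeline = chamber_timeline(),
                     fc_shift = TRUE) {
  if (is.vector(fields)) {
    fields <- matrix(rep(fields, 7), ncol = 7, dimnames = list(NULL, c("L", "C", "Ci", "R", "S", "STY", "KEK1")))
  }
  structure(list(
    snapshots = stats::setNames(list(fields), as.character(t)),
    snapshot_axes = stats::setNames(list(c(a = mesh$a, b = mesh$b)), as.character(t)),
    mesh = mesh,
    timeline = timeline,
    config = list(n = mesh$n, fc_shift = fc_shift),
    diagnostics = tibble::tibble()
  ), class = "chamber_sim")
}

## Memoised front-ends used by the parameter-recovery acceptance test.
with_sim_cache_curves <- function(cfg, dosages, times, noise_sd = 0, seed = 1L) {
  synth_reference_curves(cfg, dosages = dosages, times = times,
                         noise_sd = noise_sd, seed = seed,
                         sim_fun = cached_sim)
}

calibrate_with_cache <- function(grid_sty, grid_kek, ref, cfg, dosages, times) {
  calibrate_gammas(grid_sty, grid_kek, ref, cfg, dosages = dosages,
                   times = times, sim_fun = cached_sim)
}

## The four mechanistic runs shared by the qualitative and quantitative
## acceptance tests (n = 32, full 3-19.5 h span).
acceptance_run <- function(which = c("wt", "nucleus-stop", "no-fc-shift", "growth-stop"),
                           n = 32) {
  which <- match.arg(which)
  cfg <- simulation_config(n = n)
  cfg2 <- switch(which,
    "wt" = cfg,
    "nucleus-stop" = { cfg$nucleus_stop_time <- 10.5; cfg },
    "no-fc-shift" = { cfg$fc_shift <- FALSE; cfg },
    "growth-stop" = { cfg$growth_stop_time <- 10.5; cfg }
  )
  cached_sim(cfg2)
}
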