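## Profile extraction and model-data comparison.

stage_of <- function(timeline, t) {
  d <- timeline$dims
  i <- which.min(abs(d$time_hr - t))
  if (abs(d$time_hr[i] - t) < 1e-6) d$stage[i] else NA_character_
}

new_profile <- function(df, axis, n_points) {
  class(df) <- c("intensity_profile", class(df))
  attr(df, "axis") <- axis
  attr(df, "n_points") <- n_points
  df
}

#' Anterior-posterior intensity profile
#'
#' Samples a species along the dorsal midline (`theta = 0`) at `n_points`
#' positions evenly spaced in arc-length, from the anterior edge of the
#' columnar follicle cells to the posterior pole. While the follicle cells
#' still cover the whole chamber (stages 7-8, or with the shift disabled) the
#' profile spans the full egg chamber length.
#'
#' @param sim A [simulate_chamber()] result.
#' @param t Snapshot time in hours.
#' @param species Species name (default `"S"`, the dpERK signal).
#' @param n_points Number of samples (default 100).
#' @return A tibble of class `intensity_profile` with columns `axis`, `stage`,
#'   `time_hr`, `position_um` (arc-length from the anterior end of the
#'   profile), `position_frac`, `eta` and `value`.
#' @export
extract_ap_profile <- function(sim, t, species = "S", n_points = 100L) {
  sn <- snapshot_at(sim, t)
  mesh <- sn$mesh
  tl <- sim$timeline
  eta_fc <- tl_eta_fc(tl, t, sim$config$fc_shift)
  tab <- arc_tables(mesh$a, mesh$b)
  s_fc <- meridian_arc(mesh$a, mesh$b, eta_fc, tab = tab)
  pos <- seq(0, s_fc, length.out = n_points)          # 0 = anterior edge
  arc_from_pole <- s_fc - pos
  eta <- eta_at_arc(mesh$a, mesh$b, arc_from_pole, tab = tab)
  vals <- mesh_interp(mesh, eta, rep(0, n_points), sn$fields[, species])
  new_profile(tibble::tibble(
    axis = "AP", stage = stage_of(tl, t), time_hr = t,
    position_um = pos, position_frac = pos / s_fc,
    eta = eta, value = vals
  ), "AP", n_points)
}

#' Dorso-ventral intensity profile
#'
#' Samples a species along the transverse ring just posterior of the oocyte
#' nucleus, restricted to the central 30% of the ring circumference centered
#' on the dorsal midline, at `n_points` evenly spaced positions.
#'
#' @inheritParams extract_ap_profile
#' @param n_points Number of samples (default 50).
#' @param ring_offset Meridian offset posterior of the nucleus, as a fraction
#'   of the oocyte curved length.
#' @param central_frac Sampled fraction of the ring circumference.
#' @return A tibble of class `intensity_profile` (positions along the ring
#'   from its ventral-most sampled point).
#' @export
extract_dv_profile <- function(sim, t, species = "S", n_points = 50L,
                               ring_offset = 0.05, central_frac = 0.30) {
  sn <- snapshot_at(sim, t)
  mesh <- sn$mesh
  tl <- sim$timeline
  tab <- arc_tables(mesh$a, mesh$b)
  eta_n <- tl_eta_nucleus(tl, t)
  oo_arc <- meridian_arc(mesh$a, mesh$b, tl_eta_oo(tl, t), tab = tab)
  eta_dv <- eta_at_arc(mesh$a, mesh$b,
                       max(0, meridian_arc(mesh$a, mesh$b, eta_n, tab = tab) -
                             ring_offset * oo_arc), tab = tab)
  eta_dv <- max(eta_dv, 0.05)
  r_ring <- mesh$b * sin(eta_dv)
  circ <- 2 * pi * r_ring
  th_max <- central_frac * pi                      # half-arc in theta
  theta <- seq(-th_max, th_max, length.out = n_points)
  vals <- mesh_interp(mesh, rep(eta_dv, n_points), theta, sn$fields[, species])
  pos <- (theta + th_max) * r_ring
  new_profile(tibble::tibble(
    axis = "DV", stage = stage_of(tl, t), time_hr = t,
    position_um = pos, position_frac = pos / (central_frac * circ),
    eta = eta_dv, value = vals
  ), "DV", n_points)
}

## Dorsal meridian circle profile (theta = 0 side then theta = pi side),
## parameterized by arc-length around the full meridian ellipse starting at
## the posterior pole on the dorsal side.
meridian_circle_profile <- function(sim, t, species = "S", n_points = 512L) {
  sn <- snapshot_at(sim, t)
  mesh <- sn$mesh
  tab <- arc_tables(mesh$a, mesh$b)
  half <- meridian_arc(mesh$a, mesh$b, pi, tab = tab)
  k <- n_points %/% 2L
  arc_d <- seq(0, half, length.out = k)
  eta_d <- eta_at_arc(mesh$a, mesh$b, arc_d, tab = tab)
  arc_v <- seq(half, 2 * half, length.out = n_points - k + 1L)[-1L]
  eta_v <- eta_at_arc(mesh$a, mesh$b, 2 * half - arc_v, tab = tab)
  eta <- c(eta_d, eta_v)
  theta <- c(rep(0, k), rep(pi, n_points - k))
  vals <- mesh_interp(mesh, eta, theta, sn$fields[, species])
  tibble::tibble(arc_um = c(arc_d, arc_v), eta = eta, theta = theta,
                 value = vals, total_um = 2 * half)
}

#' Maximum signal intensity
#'
#' Maximum nodal value of a species over the whole egg chamber surface at a
#' snapshot time.
#'
#' @inheritParams extract_ap_profile
#' @return A scalar (mol/um^2).
#' @export
max_signal <- function(sim, t, species = "S") {
  sn <- snapshot_at(sim, t)
  max(sn$fields[, species])
}

#' Signal elongation along the anterior-posterior axis
#'
#' Arc-length of the dorsal-meridian region whose normalized signal exceeds a
#' threshold: the signal is sampled around the full meridian circle (dorsal
#' and ventral sides), divided by `reference` (by default the wild-type-style
#' self maximum over the surface at the same time), and the arc-length where
#' it exceeds `threshold` is summed, with linear interpolation at the
#' crossings.
#'
#' @inheritParams extract_ap_profile
#' @param threshold Threshold on the normalized signal (the conventional
#'   value is 0.6).
#' @param reference Normalization value; defaults to [max_signal()] of this
#'   simulation at `t`. For perturbation runs pass the wild-type maximum at
#'   the corresponding stage.
#' @param n_points Meridian sampling resolution.
#' @return Elongation in um.
#' @export
elongation <- function(sim, t, threshold = 0.6, reference = NULL,
                       species = "S", n_points = 512L) {
  prof <- meridian_circle_profile(sim, t, species, n_points)
  reference <- reference %||% max_signal(sim, t, species)
  if (reference <= 0) return(0)
  v <- prof$value / reference - threshold
  x <- prof$arc_um
  seg <- 0
  for (i in seq_len(length(v) - 1L)) {
    v1 <- v[i]; v2 <- v[i + 1L]; dx <- x[i + 1L] - x[i]
    if (v1 >= 0 && v2 >= 0) {
      seg <- seg + dx
    } else if (v1 >= 0 && v2 < 0) {
      seg <- seg + dx * v1 / (v1 - v2)
    } else if (v1 < 0 && v2 >= 0) {
      seg <- seg + dx * v2 / (v2 - v1)
    }
  }
  seg
}

#' L1 relative error between two intensity profiles
#'
#' Integral of the absolute difference between the curves divided by the
#' integral of the reference curve, both by the trapezoid rule on the
#' simulated profile's fractional positions (the reference is linearly
#' resampled there first).
#'
#' @param sim_profile,ref_profile Tibbles with columns `position_frac` and
#'   `value`.
#' @return A nonnegative dimensionless error.
#' @export
l1_relative_error <- function(sim_profile, ref_profile) {
  x <- sim_profile$position_frac
  ys <- sim_profile$value
  yr <- approx(ref_profile$position_frac, ref_profile$value, xout = x, rule = 2)$y
  trap <- function(y) sum((y[-1] + y[-length(y)]) / 2 * diff(x))
  denom <- trap(abs(yr))
  if (denom <= 0) abort("reference curve integrates to zero; L1 relative error undefined")
  trap(abs(ys - yr)) / denom
}

#' Normalize simulated profiles to reference curves
#'
#' Applies one global factor to all simulated profiles, chosen so that the
#' simulated wild-type AP curve at stage 10A equals the reference curve at
#' 20% of the profile length (the standard anchoring of simulated arbitrary
#' units to experimental intensities).
#'
#' @param sim_profiles,ref_profiles Long tibbles of profiles (columns `axis`,
#'   `time_hr`, `position_frac`, `value`, optionally `dosage`).
#' @param anchor_time Stage time of the anchor curve (default 19.5).
#' @param anchor_frac Fractional position of the anchor (default 0.2).
#' @return `sim_profiles` with `value` rescaled; the factor is attached as
#'   attribute `"factor"`.
#' @export
normalize_to_reference <- function(sim_profiles, ref_profiles,
                                   anchor_time = 19.5, anchor_frac = 0.2) {
  pick <- function(df) {
    out <- df[df$axis == "AP" & abs(df$time_hr - anchor_time) < 1e-6, ]
    if ("dosage" %in% names(out)) out <- out[out$dosage == 1, ]
    if (nrow(out) == 0L) abort("wild-type AP anchor curve not found")
    out
  }
  s <- pick(sim_profiles); r <- pick(ref_profiles)
  vs <- approx(s$position_frac, s$value, xout = anchor_frac)$y
  vr <- approx(r$position_frac, r$value, xout = anchor_frac)$y
  if (!is.finite(vs) || vs == 0 || !is.finite(vr)) {
    abort("anchor value is zero or undefined; cannot normalize")
  }
  fac <- vr / vs
  sim_profiles$value <- sim_profiles$value * fac
  attr(sim_profiles, "factor") <- fac
  sim_profiles
}

## All AP + DV profiles of a simulation at the given times, as one tibble.
profiles_of <- function(sim, times, species = "S") {
  bind_rows(lapply(times, function(t) {
    bind_rows(extract_ap_profile(sim, t, species),
              extract_dv_profile(sim, t, species))
  }))
}

## Summed L1 relative error of simulated profiles against reference curves,
## matched on axis, time and (if present) dosage.
profile_set_error <- function(sim_profiles, ref_curves) {
  keys <- c("axis", "time_hr", if ("dosage" %in% names(sim_profiles) &&
                                   "dosage" %in% names(ref_curves)) "dosage")
  sp <- split(sim_profiles, sim_profiles[keys], drop = TRUE)
  rp <- split(ref_curves, ref_curves[keys], drop = TRUE)
  common <- intersect(names(sp), names(rp))
  if (length(common) == 0L) abort("no matching profile curves between simulation and reference")
  sum(vapply(common, function(k) l1_relative_error(sp[[k]], rp[[k]]), 0))
}

#' Synthetic reference intensity curves
#'
#' Runs the simulator at the given configuration for each ligand dosage,
#' extracts AP and DV dpERK profiles at the requested stages, and adds
#' independent Gaussian noise with standard deviation `noise_sd` times each
#' curve's maximum — a reproducible synthetic stand-in for experimental
#' immunostaining intensity data, in the same layout the calibration reads.
#'
#' @param config A [simulation_config()] used as the ground truth.
#' @param dosages Ligand dosage multipliers (default 0.5, 1, 2 for 1x / 2x /
#'   4x gurken copies).
#' @param times Stage times at which profiles are extracted.
#' @param noise_sd Noise standard deviation as a fraction of each curve's
#'   maximum value.
#' @param seed Integer seed (reproducible).
#' @param path Optional CSV path to write the curves to.
#' @param sim_fun Simulation runner, by default [simulate_chamber()] (a
#'   memoising wrapper can be substituted).
#' @return A long tibble of profiles with a `dosage` column.
#' @export
synth_reference_curves <- function(config, dosages = c(0.5, 1, 2),
                                   times = c(13.5, 19.5),
                                   noise_sd = 0, seed = 1L, path = NULL,
                                   sim_fun = simulate_chamber) {
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  curves <- bind_rows(lapply(dosages, function(dk) {
    cfg <- config
    cfg$grk_multiplier <- dk
    sim <- sim_fun(cfg)
    pr <- profiles_of(sim, times)
    pr$dosage <- dk
    pr
  }))
  if (noise_sd > 0) curves <- add_profile_noise(curves, noise_sd, seed)
  if (!is.null(path)) utils::write.csv(curves, path, row.names = FALSE)
  curves
}

#' Add curve-relative Gaussian noise to reference profiles
#'
#' Adds independent Gaussian noise with standard deviation `noise_sd` times
#' each curve's maximum value, per (axis, stage, dosage) curve; seeded and
#' reproducible.
#'
#' @param curves A long profile tibble.
#' @param noise_sd Noise standard deviation as a fraction of each curve's max.
#' @param seed Integer seed.
#' @return The tibble with perturbed `value`.
#' @export
add_profile_noise <- function(curves, noise_sd, seed = 1L) {
  if (noise_sd < 0) abort("noise_sd must be nonnegative")
  if (noise_sd == 0) return(curves)
  set.seed(as.integer(seed))
  keys <- intersect(c("axis", "time_hr", "dosage"), names(curves))
  curves |>
    group_by(across(dplyr::all_of(keys))) |>
    mutate(value = .data$value + rnorm(dplyr::n(), 0, noise_sd * max(.data$value))) |>
    ungroup()
}

#' Calibrate the inhibitor strengths on a gamma grid
#'
#' Reproduces the inhibitor-strength calibration: for every grid combination
#' of `gamma_STY` and `gamma_KEK1`, the model is run at each ligand dosage and
#' the AP/DV dpERK profiles are compared to the reference curves in summed L1
#' relative error; the minimizing grid point is returned together with the
#' full error surface.
#'
#' @param grid_sty,grid_kek Numeric vectors of candidate strengths.
#' @param ref_curves Reference profiles (see [synth_reference_curves()] for
#'   the layout; external curves with the same columns work equally).
#' @param config Base [simulation_config()].
#' @param dosages Dosage multipliers present in the reference set.
#' @param times Stage times compared.
#' @param sim_fun Simulation runner, by default [simulate_chamber()].
#' @return An object of class `gamma_calibration`: list with `best` (named
#'   vector), `errors` (tibble) and the settings.
#' @export
calibrate_gammas <- function(grid_sty, grid_kek, ref_curves, config,
                             dosages = c(0.5, 1, 2), times = c(13.5, 19.5),
                             sim_fun = simulate_chamber) {
  if (length(grid_sty) == 0L || length(grid_kek) == 0L) abort("gamma grids must be nonempty")
  grid <- expand.grid(gamma_STY = grid_sty, gamma_KEK1 = grid_kek)
  errs <- rep(NA_real_, nrow(grid))
  for (i in seq_len(nrow(grid))) {
    err_i <- tryCatch({
      prs <- bind_rows(lapply(dosages, function(dk) {
        cfg <- config
        cfg$params$gamma_STY <- grid$gamma_STY[i]
        cfg$params$gamma_KEK1 <- grid$gamma_KEK1[i]
        cfg$grk_multiplier <- dk
        sim <- sim_fun(cfg)
        pr <- profiles_of(sim, times)
        pr$dosage <- dk
        pr
      }))
      profile_set_error(prs, ref_curves)
    }, error = function(e) {
      warn(paste0("grid point (", grid$gamma_STY[i], ", ", grid$gamma_KEK1[i],
                  ") failed and was excluded: ", conditionMessage(e)))
      NA_real_
    })
    errs[i] <- err_i
  }
  if (all(is.na(errs))) abort("all calibration grid points failed")
  best <- which.min(errs)
  structure(list(
    best = c(gamma_STY = grid$gamma_STY[best], gamma_KEK1 = grid$gamma_KEK1[best]),
    errors = tibble::as_tibble(cbind(grid, l1_error = errs)),
    dosages = dosages, times = times
  ), class = "gamma_calibration")
}

#' @export
print.gamma_calibration <- function(x, ...) {
  cat("<gamma_calibration> best: gamma_STY =", x$best[["gamma_STY"]],
      ", gamma_KEK1 =", x$best[["gamma_KEK1"]], "\n")
  invisible(x)
}

#' Depletion scan against reference curves
#'
#' Runs the sty- or EGFR-depleted model at each candidate remaining fraction,
#' compares the S10A AP and DV dpERK profiles to the reference curves in
#' summed L1 relative error, and returns the best-fitting fraction with the
#' error table (the in-silico estimate of an RNAi knockdown strength).
#'
#' @param target `"sty"` or `"egfr"`.
#' @param ref_curves Reference AP and DV profiles at the scan time.
#' @param config Base [simulation_config()].
#' @param fractions Candidate remaining fractions (default 0.25, 0.5, 0.75).
#' @param time Stage time compared (default 19.5, stage 10A).
#' @param sim_fun Simulation runner, by default [simulate_chamber()].
#' @return An object of class `depletion_scan`: list with `best_fraction` and
#'   `errors` tibble.
#' @export
depletion_scan <- function(target = c("sty", "egfr"), ref_curves, config,
                           fractions = c(0.25, 0.5, 0.75), time = 19.5,
                           sim_fun = simulate_chamber) {
  target <- match.arg(target)
  errs <- rep(NA_real_, length(fractions))
  for (i in seq_along(fractions)) {
    errs[i] <- tryCatch({
      cfg <- config
      if (target == "sty") cfg$sty_fraction <- fractions[i]
      else cfg$egfr_fraction <- fractions[i]
      sim <- sim_fun(cfg)
      profile_set_error(profiles_of(sim, time), ref_curves)
    }, error = function(e) {
      warn(paste0("fraction ", fractions[i], " failed and was excluded: ",
                  conditionMessage(e)))
      NA_real_
    })
  }
  if (all(is.na(errs))) abort("all depletion fractions failed")
  structure(list(
    target = target,
    best_fraction = fractions[which.min(errs)],
    errors = tibble::tibble(fraction = fractions, l1_error = errs)
  ), class = "depletion_scan")
}

#' @export
print.depletion_scan <- function(x, ...) {
  cat("<depletion_scan> target:", x$target, " best fraction:", x$best_fraction, "\n")
  invisible(x)
}
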