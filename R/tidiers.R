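## broom-style tidiers and ggplot2 methods.

#' Tidy a simulation result
#'
#' One row per cell, species and snapshot time, with surface coordinates —
#' ready for dplyr/ggplot2 pipelines.
#'
#' @param x A [simulate_chamber()] result.
#' @param times Snapshot times to include (default: all).
#' @param species Species to include (default: all seven).
#' @param ... Unused.
#' @return A long tibble.
#' @export
tidy.chamber_sim <- function(x, times = NULL, species = SPECIES, ...) {
  times <- times %||% as.numeric(names(x$snapshots))
  bind_rows(lapply(times, function(t) {
    sn <- snapshot_at(x, t)
    nd <- mesh_nodes(sn$mesh)
    bind_rows(lapply(species, function(sp) {
      mutate(nd, time_hr = t, species = sp, value = sn$fields[, sp])
    }))
  }))
}

#' Summarize a simulation result
#'
#' One-row tibble with the headline outcomes: final maximum dpERK, final
#' total ligand and signal mass, elongation at the final stage, step and
#' clip counters.
#'
#' @param x A [simulate_chamber()] result.
#' @param ... Unused.
#' @return A one-row tibble.
#' @export
glance.chamber_sim <- function(x, ...) {
  t_end <- max(as.numeric(names(x$snapshots)))
  sn <- snapshot_at(x, t_end)
  tibble::tibble(
    t_end = t_end,
    max_dpERK = max(sn$fields[, "S"]),
    ligand_mass = integrate_surface(sn$mesh, sn$fields[, "L"]),
    signal_mass = integrate_surface(sn$mesh, sn$fields[, "S"]),
    elongation_um = elongation(x, t_end),
    n_steps = x$n_steps,
    clip_count = x$clip_count
  )
}

#' @export
tidy.gamma_calibration <- function(x, ...) x$errors

#' @export
glance.gamma_calibration <- function(x, ...) {
  tibble::tibble(gamma_STY = x$best[["gamma_STY"]],
                 gamma_KEK1 = x$best[["gamma_KEK1"]],
                 min_l1_error = min(x$errors$l1_error, na.rm = TRUE))
}

#' @export
tidy.depletion_scan <- function(x, ...) x$errors

#' @export
glance.depletion_scan <- function(x, ...) {
  tibble::tibble(target = x$target, best_fraction = x$best_fraction,
                 min_l1_error = min(x$errors$l1_error, na.rm = TRUE))
}

#' Plot an intensity profile
#'
#' @param object An `intensity_profile` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.intensity_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$position_um, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = paste0(attr(object, "axis") %||% object$axis[1], " position (um)"),
      y = "intensity (mol/um^2)",
      title = paste0(object$axis[1], " profile, t = ", object$time_hr[1], " hr")
    ) +
    ggplot2::theme_minimal()
}

#' Plot a simulated surface field
#'
#' Angular-coordinate heat map (posterior pole at eta = 0, dorsal midline at
#' theta = 0) of one species at one snapshot time.
#'
#' @param object A [simulate_chamber()] result.
#' @param t Snapshot time (default: last).
#' @param species Species name (default `"S"`).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.chamber_sim <- function(object, t = NULL, species = "S", ...) {
  t <- t %||% max(as.numeric(names(object$snapshots)))
  df <- tidy(object, times = t, species = species)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$eta, y = .data$theta, colour = .data$value)) +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::labs(x = "eta (0 = posterior pole)", y = "theta (0 = dorsal)",
                  colour = species,
                  title = paste0(species, " at t = ", t, " hr")) +
    ggplot2::theme_minimal()
}

#' Plot a calibration error surface
#'
#' @param object A [calibrate_gammas()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.gamma_calibration <- function(object, ...) {
  ggplot2::ggplot(object$errors,
                  ggplot2::aes(x = factor(.data$gamma_STY),
                               y = factor(.data$gamma_KEK1),
                               fill = .data$l1_error)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "gamma_STY", y = "gamma_KEK1", fill = "L1 error") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
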