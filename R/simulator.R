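#' Simulation configuration
#'
#' Bundles everything a run needs: geometry timeline, kinetic parameters,
#' secretion source, mesh resolution, time stepping and the mechanistic /
#' genetic perturbation switches. The solver is deterministic; `seed` is kept
#' in the configuration only for randomized companions (e.g. synthetic
#' reference curves).
#'
#' @param n Mesh cells per zone edge.
#' @param dt Macro time step in hours, `NULL` for automatic selection from the
#'   reaction rates (diffusion is sub-cycled within each macro step to satisfy
#'   the explicit stability bound).
#' @param params A [kinetic_params()].
#' @param source A [source_spec()].
#' @param timeline An [chamber_timeline()].
#' @param output_times Snapshot times (hours), default the six stage times.
#' @param nucleus_stop_time,growth_stop_time Optional freeze times (hours) for
#'   the mechanistic perturbations (the conventional value is 10.5, late S8).
#' @param fc_shift Logical: posterior follicle-cell shift active?
#' @param sty_fraction,egfr_fraction Optional remaining fractions in (0, 1]
#'   for the RNAi-style depletions (see [depletion_variant()]).
#' @param grk_multiplier Ligand dosage multiplier (0.5 / 1 / 2 for 1x / 2x /
#'   4x gurken copies; 0 switches the source off).
#' @param gamma_sty_zero_after Optional time after which the STY feedback
#'   strength is set to zero (the alternative sty-RNAi description).
#' @param init_uniform Optional named vector of uniform initial concentrations
#'   (mol/um^2) overriding the default initial state; names among
#'   `L, C, Ci, R, S, STY, KEK1`.
#' @param seed Integer seed recorded in the configuration.
#' @param safety Stability safety factor (at most 0.9).
#' @return An object of class `chamber_config`.
#' @export
simulation_config <- function(n = 32,
                              dt = NULL,
                              params = kinetic_params(),
                              source = source_spec(V0 = params$V0),
                              timeline = chamber_timeline(),
                              output_times = NULL,
                              nucleus_stop_time = NULL,
                              growth_stop_time = NULL,
                              fc_shift = TRUE,
                              sty_fraction = NULL,
                              egfr_fraction = NULL,
                              grk_multiplier = 1,
                              gamma_sty_zero_after = NULL,
                              init_uniform = NULL,
                              seed = 1L,
                              safety = 0.8) {
  if (safety > 0.9) {
    warn("safety factor reduced to 0.9 (explicit stability bound)")
    safety <- 0.9
  }
  output_times <- output_times %||% timeline$dims$time_hr
  if (any(output_times < timeline$t_start - 1e-9 | output_times > timeline$t_end + 1e-9)) {
    abort("output times must lie within the timeline range")
  }
  if (!is.null(dt) && (!is.numeric(dt) || dt <= 0)) abort("dt must be positive")
  if (grk_multiplier < 0) abort("grk_multiplier must be nonnegative")
  for (f in list(sty_fraction, egfr_fraction)) {
    if (!is.null(f) && (f <= 0 || f > 1)) abort("depletion fractions must be in (0, 1]")
  }
  if (!is.null(init_uniform)) {
    bad <- setdiff(names(init_uniform), SPECIES)
    if (length(bad) > 0L) abort(paste0("unknown species in init_uniform: ", paste(bad, collapse = ", ")))
  }
  structure(list(
    n = n, dt = dt, params = params, source = source, timeline = timeline,
    output_times = sort(unique(output_times)),
    nucleus_stop_time = nucleus_stop_time, growth_stop_time = growth_stop_time,
    fc_shift = fc_shift, sty_fraction = sty_fraction, egfr_fraction = egfr_fraction,
    grk_multiplier = grk_multiplier, gamma_sty_zero_after = gamma_sty_zero_after,
    init_uniform = init_uniform, seed = as.integer(seed), safety = safety
  ), class = "chamber_config")
}

## Materialize perturbations: timeline freezes, kinetic depletions, dosage.
resolve_config <- function(cfg) {
  tl <- cfg$timeline
  tl$nucleus_stop_time <- cfg$nucleus_stop_time %||% tl$nucleus_stop_time
  tl$growth_stop_time <- cfg$growth_stop_time %||% tl$growth_stop_time
  p <- cfg$params
  if (!is.null(cfg$sty_fraction)) p <- depletion_variant(p, "sty", cfg$sty_fraction)
  if (!is.null(cfg$egfr_fraction)) p <- depletion_variant(p, "egfr", cfg$egfr_fraction)
  src <- cfg$source
  if (cfg$grk_multiplier != 1) {
    src$V0 <- src$V0 * cfg$grk_multiplier  # allow 0 (no dosage_variant contract)
  }
  list(timeline = tl, params = p, source = src)
}

#' Nondimensionalize a kinetic parameter set
#'
#' Rescales all parameters to the working units: concentrations in units of
#' `conc_scale` (default `R0`), lengths in units of `length_scale`, times in
#' units of `time_scale`. Returns the scaled parameters together with a scale
#' record from which [redimensionalize()] reconstructs the original set
#' exactly. The integrator itself works in concentration units of `R0` (so
#' state variables are order 1) while keeping micrometers and hours.
#'
#' @param params A [kinetic_params()].
#' @param conc_scale Concentration scale, mol/um^2.
#' @param length_scale Length scale, um.
#' @param time_scale Time scale, hours.
#' @return A list with elements `params` (scaled) and `scales`.
#' @export
nondimensionalize <- function(params, conc_scale = params$R0,
                              length_scale = 1, time_scale = 1) {
  C <- conc_scale; L <- length_scale; T <- time_scale
  p <- params
  p$D <- params$D * T / L^2
  p$k_on <- params$k_on * C * T / L
  for (k in c("k_ec", "k_off", "k_er", "k_rec", "k_deg", "k_d", "k_s",
              "k_STY", "k_dSTY", "k_KEK1", "k_dKEK1")) {
    p[[k]] <- params[[k]] * T
  }
  p$R0 <- params$R0 / C
  p$V0 <- params$V0 * T / C
  p$Q_r <- params$Q_r * T / C
  p$H <- params$H / L
  p$K_kek <- params$K_kek / C
  p$K_sty <- params$K_sty / C
  list(params = p, scales = list(conc = C, length = L, time = T))
}

#' Undo a nondimensionalization
#'
#' @param scaled A list as returned by [nondimensionalize()].
#' @return The original `kinetic_params` object.
#' @export
redimensionalize <- function(scaled) {
  s <- scaled$scales
  nondimensionalize(scaled$params, conc_scale = 1 / s$conc,
                    length_scale = 1 / s$length, time_scale = 1 / s$time)$params
}

#' Initial field state
#'
#' At the start of the run all species are zero except the free receptor,
#' which sits at its resting density `R0` uniformly over the follicle-cell
#' covered region (the whole surface at S7). With an `egfr_fraction`
#' perturbation the depleted `R0` applies.
#'
#' @param config A [simulation_config()].
#' @param mesh Optional prebuilt mesh (defaults to a fresh mesh at the start
#'   time's semi-axes).
#' @return A numeric `8 n^2` x 7 matrix (mol/um^2) with species columns.
#' @export
initial_state <- function(config, mesh = NULL) {
  rs <- resolve_config(config)
  tl <- rs$timeline
  if (is.null(mesh)) {
    d0 <- dims_at(tl, tl$t_start)
    mesh <- cubed_spheroid(config$n, d0$L_AP, d0$L_DV)
  }
  X <- matrix(0, mesh$N, 7L, dimnames = list(NULL, SPECIES))
  mask <- mesh$cells$eta <= fc_extent_eta(tl, tl$t_start, config$fc_shift) + 1e-12
  X[, "R"] <- rs$params$R0 * mask
  if (!is.null(config$init_uniform)) {
    for (sp in names(config$init_uniform)) X[, sp] <- config$init_uniform[[sp]]
  }
  X
}

## ---- engine -------------------------------------------------------------

engine_init <- function(cfg) {
  rs <- resolve_config(cfg)
  tl <- rs$timeline; p <- rs$params; src <- rs$source
  d0 <- dims_at(tl, tl$t_start)
  mesh <- cubed_spheroid(cfg$n, d0$L_AP, d0$L_DV)
  scale <- p$R0
  pnd <- p
  pnd$kon_over_H <- p$k_on * scale / p$H
  pnd$K_kek <- p$K_kek / scale
  pnd$K_sty <- p$K_sty / scale
  E <- new.env(parent = emptyenv())
  E$cfg <- cfg; E$tl <- tl; E$p <- p; E$pnd <- pnd; E$src <- src
  E$scale <- scale; E$Qr_nd <- p$Q_r / scale
  ## slow-rate sum for the adaptive macro-step bound
  E$slow_rates <- p$k_off + p$k_ec + p$k_er +
    p$alpha_rec * p$k_rec + p$alpha_deg * p$k_deg + p$k_d + p$k_s +
    p$k_STY + p$k_dSTY + p$k_KEK1 + p$k_dKEK1
  E$mesh <- mesh
  E$tab <- arc_tables(mesh$a, mesh$b)
  E$X <- initial_state(cfg, mesh) / scale
  E$t <- tl$t_start
  E$geom_tol <- 0
  E$clip_count <- 0
  E$steps <- 0L
  E$diag <- list()
  E
}

## Adaptive macro step: forward-Euler accuracy bound from the currently
## realized reaction rates (the ligand-binding rate is evaluated with the
## KEK1-suppressed effective k_on) plus a CFL bound for the cell-shift
## advection. Diffusion has its own sub-cycled bound inside the step.
engine_dt <- function(E) {
  pnd <- E$pnd
  supp <- 1 + pnd$gamma_KEK1 * E$X[, 7L] / pnd$K_kek
  bind_rate <- pnd$kon_over_H * max(pmax(E$X[, 4L], E$X[, 1L]) / supp)
  lam <- bind_rate + E$slow_rates
  dt <- min(E$cfg$dt %||% Inf, 0.35 / lam)
  if (E$cfg$fc_shift) {
    er <- abs(fc_edge_eta_rate(E$tl, E$t))
    if (er > 1e-14) {
      wmax <- er * max(E$mesh$a, E$mesh$b)
      dt <- min(dt, 0.4 * E$mesh$geom$h_min / wmax)
    }
  }
  dt
}

engine_check <- function(X, substep) {
  if (!all(is.finite(X))) {
    abort(paste0("solver diverged (non-finite values) in sub-step: ", substep))
  }
}

## One macro step: (1) ligand diffusion (sub-cycled), (2) growth transport
## with area-Jacobian dilution, (3) follicle-cell shift of all species except
## the ligand, (4) reactions plus secretion source, clipped at zero and masked
## to the follicle-cell region.
engine_step <- function(E, dt) {
  t1 <- E$t + dt
  mesh <- E$mesh
  p <- E$p; pnd <- E$pnd; cfg <- E$cfg; tl <- E$tl

  ## (1) diffusion of the ligand
  if (p$D > 0) {
    ## spectral radius of the discrete diffusion operator is <= ~1.7x the
    ## Gershgorin row-sum scale on these meshes; cap also by the classical
    ## h_min^2 bound
    dt_diff <- min(cfg$safety * 1.15 / (p$D * mesh$geom$lam_scale),
                   0.9 * mesh$geom$h_min^2 / (4 * p$D))
    msub <- max(1L, ceiling(dt / dt_diff))
    dtau <- dt / msub
    L <- E$X[, 1L]
    for (k in seq_len(msub)) {
      L <- L + dtau * p$D * laplace_beltrami(mesh, L)
    }
    E$X[, 1L] <- L
    engine_check(L, "diffusion")
  }

  ## (2) growth: transport to the new spheroid, conservative dilution.
  ## Geometry updates are quantized (relative axis change above 5e-4, or an
  ## exact sync requested at snapshot times) to avoid rebuilding metric terms
  ## every step; the dilution factor is applied at each update, so growth
  ## transport stays exactly conservative.
  ax1 <- tl_axes(tl, t1)
  geom_updated <- FALSE
  if (abs(ax1$a - mesh$a) > E$geom_tol * mesh$a ||
      abs(ax1$b - mesh$b) > E$geom_tol * mesh$b) {
    area_old <- mesh$geom$area
    mesh <- remesh_to(mesh, ax1$a, ax1$b)
    E$mesh <- mesh
    E$tab <- arc_tables(mesh$a, mesh$b)
    E$X <- E$X * (area_old / mesh$geom$area)
    geom_updated <- TRUE
    engine_check(E$X, "growth")
  }

  ## Time-dependent auxiliary fields (shift fluxes, source, follicle mask)
  ## are refreshed when the geometry updates or after a short staleness
  ## interval; they vary smoothly on those scales.
  if (geom_updated || is.null(E$aux) || t1 - E$aux_t > 0.05) {
    tab <- E$tab
    shift_prep <- NULL
    shift_trigger <- Inf
    if (cfg$fc_shift && abs(fc_edge_eta_rate(tl, t1)) > 1e-14) {
      Q <- face_flux_velocity_fun(mesh, function(xyz) fc_shift_velocity(tl, t1, xyz, tab = tab))
      shift_prep <- prepare_advection(mesh, Q)
      wmax <- abs(fc_edge_eta_rate(tl, t1)) * max(mesh$a, mesh$b)
      shift_trigger <- min(0.01, 0.3 * mesh$geom$h_min / wmax)
    }
    E$aux <- list(
      shift = shift_prep,
      shift_trigger = shift_trigger,
      Vn = source_flux(E$src, tl, mesh, t1, tab = tab) / E$scale,
      mask = mesh$cells$eta <= tl_eta_fc(tl, t1, cfg$fc_shift) + 1e-12
    )
    E$aux_t <- t1
  }

  ## (3) follicle-cell shift (all species except the ligand); applications
  ## are batched over a few macro steps under a CFL bound
  if (!is.null(E$aux$shift)) {
    E$shift_due <- (E$shift_due %||% 0) + dt
    if (E$shift_due >= E$aux$shift_trigger || geom_updated) {
      E$X[, 2:7] <- E$X[, 2:7] -
        E$shift_due * advection_apply(mesh, E$aux$shift, E$X[, 2:7])
      E$shift_due <- 0
    }
  }

  ## (4) reactions + source
  Vn <- E$aux$Vn
  mask <- E$aux$mask
  gs <- p$gamma_STY
  if (!is.null(cfg$gamma_sty_zero_after) && t1 > cfg$gamma_sty_zero_after) gs <- 0
  X <- E$X
  d <- rx_core(pnd, X[, 1L], X[, 2L], X[, 3L], X[, 4L], X[, 5L], X[, 6L], X[, 7L],
               Qr = E$Qr_nd * mask, gamma_STY = gs)
  X[, 1L] <- X[, 1L] + dt * (d$L + Vn)
  X[, 2L] <- X[, 2L] + dt * d$C
  X[, 3L] <- X[, 3L] + dt * d$Ci
  X[, 4L] <- X[, 4L] + dt * d$R
  X[, 5L] <- X[, 5L] + dt * d$S
  X[, 6L] <- X[, 6L] + dt * d$STY
  X[, 7L] <- X[, 7L] + dt * d$KEK1
  neg <- X < 0
  nneg <- sum(neg)
  if (nneg > 0L) {
    X[neg] <- 0
    E$clip_count <- E$clip_count + nneg
  }
  if (any(!mask)) X[!mask, 2:7] <- 0
  engine_check(X, "reactions")
  E$X <- X
  E$t <- t1
  E$steps <- E$steps + 1L
  invisible(E)
}

## Apply any pending batched shift transport (called before snapshots).
engine_flush_shift <- function(E) {
  if (!is.null(E$aux$shift) && (E$shift_due %||% 0) > 0) {
    E$X[, 2:7] <- E$X[, 2:7] -
      E$shift_due * advection_apply(E$mesh, E$aux$shift, E$X[, 2:7])
    E$shift_due <- 0
  }
  invisible(E)
}

engine_record <- function(E) {
  masses <- 2 * colSums(E$X * E$mesh$geom$area) * E$scale
  E$diag[[length(E$diag) + 1L]] <- c(
    time_hr = E$t, setNames(masses, paste0("mass_", SPECIES)),
    max_S = max(E$X[, 5L]) * E$scale, clip_count = E$clip_count, steps = E$steps
  )
  invisible(E)
}

#' Run the full egg-chamber simulation
#'
#' Integrates the coupled transport-reaction-diffusion system from the start
#' to the end of the geometry timeline with operator splitting (forward Euler;
#' four sub-steps per macro step: ligand diffusion, growth transport, the
#' follicle-cell shift and the local reactions with the moving secretion
#' source). The macro step is chosen from the reaction rates and diffusion is
#' sub-cycled under the explicit stability bound; the solver is deterministic.
#'
#' @param config A [simulation_config()].
#' @param quiet Suppress the per-snapshot progress messages.
#' @return An object of class `chamber_sim` with elements `snapshots` (one
#'   dimensional species matrix per output time), `mesh` (at the final axes),
#'   `diagnostics` (per-snapshot mass/extreme/clip tibble) and the resolved
#'   configuration.
#' @export
simulate_chamber <- function(config, quiet = TRUE) {
  E <- engine_init(config)
  E$geom_tol <- 5e-4
  outs <- config$output_times
  snaps <- list()
  meshes_ab <- list()
  take_snapshot <- function() {
    engine_flush_shift(E)
    ## sync the geometry exactly to the snapshot time
    ax <- tl_axes(E$tl, E$t)
    if (ax$a != E$mesh$a || ax$b != E$mesh$b) {
      area_old <- E$mesh$geom$area
      E$mesh <- remesh_to(E$mesh, ax$a, ax$b)
      E$tab <- arc_tables(ax$a, ax$b)
      E$X <- E$X * (area_old / E$mesh$geom$area)
    }
    engine_record(E)
    st <- E$X * E$scale
    colnames(st) <- SPECIES
    snaps[[as.character(E$t)]] <<- st
    meshes_ab[[as.character(E$t)]] <<- c(a = E$mesh$a, b = E$mesh$b)
  }
  if (abs(outs[1] - E$t) < 1e-9) {
    take_snapshot()
    outs <- outs[-1]
  }
  for (tout in outs) {
    while (E$t < tout - 1e-9) {
      dt <- min(engine_dt(E), tout - E$t)
      engine_step(E, dt)
    }
    E$t <- tout
    take_snapshot()
    if (!quiet) message("snapshot at t = ", tout, " hr (", E$steps, " steps)")
  }
  diag <- tibble::as_tibble(do.call(rbind, E$diag))
  structure(list(
    snapshots = snaps,
    snapshot_axes = meshes_ab,
    mesh = E$mesh,
    diagnostics = diag,
    config = config,
    timeline = E$tl,
    params = E$p,
    source = E$src,
    n_steps = E$steps,
    clip_count = E$clip_count
  ), class = "chamber_sim")
}

#' @export
print.chamber_sim <- function(x, ...) {
  cat("<chamber_sim> ", length(x$snapshots), " snapshots, n=", x$config$n,
      ", ", x$n_steps, " macro steps, ", x$clip_count, " clipped values\n", sep = "")
  invisible(x)
}

#' Advance a field state by one macro step
#'
#' Applies the four splitting sub-steps once, starting from an arbitrary state
#' at time `t`. Mainly useful for testing sub-step behavior in isolation.
#'
#' @param config A [simulation_config()].
#' @param state Species matrix (mol/um^2) as from [initial_state()].
#' @param t Current time (hours).
#' @param dt Step size (hours).
#' @return A list with the new `state`, `mesh` and `time`.
#' @export
step_chamber <- function(config, state, t, dt) {
  E <- engine_init(config)
  rs <- resolve_config(config)
  d <- dims_at(rs$timeline, t)
  E$mesh <- remesh_to(E$mesh, d$L_AP, d$L_DV)
  E$X <- state[, SPECIES, drop = FALSE] / E$scale
  E$t <- t
  engine_step(E, dt)
  st <- E$X * E$scale
  colnames(st) <- SPECIES
  list(state = st, mesh = E$mesh, time = E$t)
}

## Snapshot accessor: dimensional species matrix and the mesh at that time.
snapshot_at <- function(sim, t) {
  key <- as.character(t)
  if (!key %in% names(sim$snapshots)) {
    keys <- as.numeric(names(sim$snapshots))
    hit <- which(abs(keys - t) < 1e-6)
    if (length(hit) == 0L) abort(paste0("no snapshot at t = ", t, " hr"))
    key <- names(sim$snapshots)[hit[1]]
  }
  ab <- sim$snapshot_axes[[key]]
  list(fields = sim$snapshots[[key]],
       mesh = remesh_to(sim$mesh, ab[["a"]], ab[["b"]]),
       time = as.numeric(key))
}
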