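test_that("the initial state has resting receptors over the follicle region and nothing else", {
  cfg <- simulation_config(n = 8)
  X <- initial_state(cfg)
  p <- cfg$params
  m <- cubed_spheroid(8, dims_at(cfg$timeline, 3)$L_AP, dims_at(cfg$timeline, 3)$L_DV)
  expect_equal(integrate_surface(m, X[, "R"]), p$R0 * surface_area(m), tolerance = 1e-12)
  for (sp in c("L", "C", "Ci", "S", "STY", "KEK1")) {
    expect_equal(max(abs(X[, sp])), 0, info = sp)
  }
  cfg2 <- simulation_config(n = 8, egfr_fraction = 0.5)
  expect_equal(max(initial_state(cfg2)[, "R"]), 0.5 * p$R0)
})

test_that("a macro step with only reactions equals one scalar forward-Euler update", {
  cfg <- simulation_config(
    n = 4, params = kinetic_params(D = 0),
    growth_stop_time = 3, fc_shift = FALSE, grk_multiplier = 0,
    init_uniform = c(L = 3e-22, R = 6.7e-22, S = 1e-27)
  )
  X0 <- initial_state(cfg)
  dt <- 1e-3
  out <- step_chamber(cfg, X0, 3, dt)
  ## uniform stays uniform
  for (sp in colnames(out$state)) {
    expect_lt(diff(range(out$state[, sp])), 1e-30 + 1e-9 * max(out$state[, sp]))
  }
  ## and matches the hand-rolled Euler update of the local kinetics
  p <- cfg$params
  st <- list(L = 3e-22, C = 0, Ci = 0, R = 6.7e-22, S = 1e-27, STY = 0, KEK1 = 0)
  d <- reaction_rhs(p, st)
  for (sp in names(st)) {
    expect_equal(unname(out$state[1, sp]), st[[sp]] + dt * d[[sp]],
                 tolerance = 1e-12, info = sp)
  }
})

test_that("sub-step isolation: the cell shift moves receptors posterior but not the ligand", {
  cfg <- simulation_config(
    n = 8, params = silent_params(),
    growth_stop_time = 14, fc_shift = TRUE, grk_multiplier = 0
  )
  tl0 <- cfg$timeline
  tl0$growth_stop_time <- 14
  d <- dims_at(tl0, 14)
  m <- cubed_spheroid(8, d$L_AP, d$L_DV)
  X <- matrix(0, m$N, 7, dimnames = list(NULL, c("L", "C", "Ci", "R", "S", "STY", "KEK1")))
  ## a bump well inside the follicle-cell region (so the receptor mask is inert)
  X[, "L"] <- exp(-(m$cells$eta - 1.0)^2 / 0.05)
  X[, "R"] <- X[, "L"]
  out <- step_chamber(cfg, X, 14, 5e-3)
  expect_equal(out$state[, "L"], X[, "L"])  # ligand is not shifted
  cen <- function(f) sum(m$cells$eta * f * m$geom$area) / sum(f * m$geom$area)
  expect_lt(cen(out$state[, "R"]), cen(X[, "R"]))  # receptors move toward eta = 0
  ## shift transport conserves receptor mass (up to the far-tail mask)
  expect_equal(integrate_surface(m, out$state[, "R"]), integrate_surface(m, X[, "R"]),
               tolerance = 1e-7)
})

test_that("growth plus diffusion conserve ligand mass without sources or reactions", {
  cfg <- simulation_config(
    n = 8, params = silent_params(D = 50), fc_shift = FALSE, grk_multiplier = 0,
    output_times = c(3, 5, 7.5),
    init_uniform = c(L = 1e-21)
  )
  ## make the initial ligand nonuniform
  E <- grksim:::engine_init(cfg)
  E$geom_tol <- 5e-4
  E$X[, 1] <- 1 + sin(2 * E$mesh$cells$eta)
  m0 <- integrate_surface(E$mesh, E$X[, 1])
  while (E$t < 7.5 - 1e-9) grksim:::engine_step(E, min(grksim:::engine_dt(E), 7.5 - E$t))
  expect_equal(integrate_surface(E$mesh, E$X[, 1]), m0, tolerance = 1e-9)
})

test_that("no ligand means no signal anywhere, and receptors equilibrate", {
  cfg <- simulation_config(n = 6, dt = 0.01, grk_multiplier = 0)
  sim <- simulate_chamber(cfg)
  for (t in c(7.5, 13.5, 19.5)) {
    sn <- grksim:::snapshot_at(sim, t)
    for (sp in c("L", "C", "Ci", "S", "STY", "KEK1")) {
      expect_equal(max(abs(sn$fields[, sp])), 0, info = paste(sp, t))
    }
  }
})

test_that("the solver is deterministic: identical configurations give identical results", {
  cfg <- simulation_config(n = 6, output_times = c(3, 7.5))
  s1 <- simulate_chamber(cfg)
  s2 <- simulate_chamber(cfg)
  expect_identical(s1$snapshots, s2$snapshots)
  expect_identical(s1$diagnostics, s2$diagnostics)
})

test_that("solver divergence is reported with the offending sub-step", {
  cfg <- simulation_config(n = 4)
  X <- initial_state(cfg)
  X[1, "L"] <- NaN
  expect_error(step_chamber(cfg, X, 3, 1e-3), "diverged")
})

test_that("the nondimensionalized stability bound matches the dimensional one", {
  p <- kinetic_params()
  Lsc <- 153.5
  nd <- nondimensionalize(p, conc_scale = p$R0, length_scale = Lsc)
  m_dim <- cubed_spheroid(8, 35.5, 22.5)
  m_nd <- cubed_spheroid(8, 35.5 / Lsc, 22.5 / Lsc)
  dt_dim <- 1 / (p$D * m_dim$geom$lam_scale)
  dt_nd <- 1 / (nd$params$D * m_nd$geom$lam_scale)
  expect_equal(dt_dim, dt_nd, tolerance = 1e-10)
})

test_that("configuration validation rejects malformed inputs", {
  expect_error(simulation_config(output_times = c(1, 19.5)), "within the timeline")
  expect_error(simulation_config(dt = -1), "positive")
  expect_error(simulation_config(sty_fraction = 1.5), "\\(0, 1\\]")
  expect_error(simulation_config(init_uniform = c(Z = 1)), "unknown species")
  expect_warning(simulation_config(safety = 1.2), "0.9")
})

test_that("operator-splitting error is first order in the macro step", {
  ## frozen geometry, all couplings active: one step of dt versus two of dt/2
  cfg <- simulation_config(n = 6, growth_stop_time = 13.5)
  X0 <- initial_state(cfg)
  X0[, "L"] <- 1e-21 * exp(-(cubed_spheroid(6, 95, 48)$cells$eta - 1)^2)
  adv <- function(dt, nsub) {
    X <- X0; t <- 13.5
    for (i in seq_len(nsub)) {
      out <- step_chamber(cfg, X, t, dt / nsub)
      X <- out$state; t <- out$time
    }
    X
  }
  dt <- 0.02
  d1 <- max(abs(adv(dt, 1L) - adv(dt, 2L)))
  d2 <- max(abs(adv(dt / 2, 1L) - adv(dt / 2, 2L)))
  expect_gt(d1 / d2, 1.5)  # halving dt at least ~halves the splitting error
  expect_lt(d1 / d2, 3.5)
})

test_that("the stage-10A signal profile is grid-converged", {
  prof_of <- function(n) {
    sim <- cached_sim(simulation_config(n = n, output_times = c(3, 19.5)))
    extract_ap_profile(sim, 19.5)
  }
  err <- l1_relative_error(prof_of(16), prof_of(24))
  expect_lt(err, 0.05)
})
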