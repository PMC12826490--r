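make_const_sim <- function(value = 2, n = 8, t = 19.5) {
  tl <- chamber_timeline()
  d <- dims_at(tl, t)
  m <- cubed_spheroid(n, d$L_AP, d$L_DV)
  fake_sim(m, rep(value, m$N), t = t, timeline = tl)
}

test_that("AP profiles sample the dorsal midline over the follicle-cell extent", {
  sim <- make_const_sim(2)
  pr <- extract_ap_profile(sim, 19.5)
  expect_equal(nrow(pr), 100L)
  expect_equal(pr$value, rep(2, 100))
  expect_true(all(diff(pr$position_um) > 0))
  m <- sim$mesh
  tl <- sim$timeline
  s_fc <- grksim:::meridian_arc(m$a, m$b, grksim:::fc_extent_eta(tl, 19.5))
  expect_equal(max(pr$position_um), s_fc)
  expect_equal(range(pr$position_frac), c(0, 1))
  ## while the cells are cuboidal the profile spans the whole chamber
  sim8 <- make_const_sim(2, t = 7.5)
  pr8 <- extract_ap_profile(sim8, 7.5)
  half <- grksim:::meridian_arc(sim8$mesh$a, sim8$mesh$b, pi)
  expect_equal(max(pr8$position_um), half)
})

test_that("DV profiles cover the central 30% of the transverse ring", {
  sim <- make_const_sim(3)
  pr <- extract_dv_profile(sim, 19.5)
  expect_equal(nrow(pr), 50L)
  expect_equal(pr$value, rep(3, 50))
  m <- sim$mesh
  ring_circ <- 2 * pi * m$b * sin(pr$eta[1])
  expect_equal(max(pr$position_um) - min(pr$position_um), 0.30 * ring_circ,
               tolerance = 1e-10)
  ## a dorsoventrally symmetric field gives a symmetric profile
  m2 <- sim$mesh
  f <- sin(m2$cells$eta) * (1 + cos(m2$cells$theta)^2)
  sim2 <- fake_sim(m2, f, t = 19.5)
  pr2 <- extract_dv_profile(sim2, 19.5)
  expect_equal(pr2$value, rev(pr2$value), tolerance = 1e-12)
})

test_that("elongation measures thresholded meridian arc-length", {
  sim <- make_const_sim(0)
  expect_equal(elongation(sim, 19.5), 0)
  ## synthetic top-hat between two meridian arc positions (both sides)
  tl <- chamber_timeline()
  d <- dims_at(tl, 19.5)
  m <- cubed_spheroid(32, d$L_AP, d$L_DV)
  tab <- grksim:::arc_tables(m$a, m$b)
  arc <- grksim:::meridian_arc(m$a, m$b, m$cells$eta, tab = tab)
  f <- as.numeric(arc >= 40 & arc <= 120)
  simt <- fake_sim(m, f, t = 19.5, timeline = tl)
  cell_h <- 2 * pi * m$a / (4 * m$n)
  expect_equal(elongation(simt, 19.5, threshold = 0.6), 2 * 80,
               tolerance = 2 * cell_h / 160)
  ## monotone nonincreasing in the threshold
  g <- exp(-(m$cells$eta - 1)^2) * (1 + 0.3 * cos(m$cells$theta))
  simg <- fake_sim(m, g, t = 19.5, timeline = tl)
  els <- vapply(c(0.2, 0.4, 0.6, 0.8), function(th) elongation(simg, 19.5, th), 0)
  expect_true(all(diff(els) <= 0))
  ## max_signal of a constant field
  expect_equal(max_signal(make_const_sim(7), 19.5), 7)
})

test_that("L1 relative error behaves like a relative integral metric", {
  x <- seq(0, 1, length.out = 100)
  ref <- tibble::tibble(position_frac = x, value = 1 + sin(2 * pi * x)^2)
  expect_equal(l1_relative_error(ref, ref), 0)
  sim2 <- ref; sim2$value <- 2 * ref$value
  expect_equal(l1_relative_error(sim2, ref), 1, tolerance = 1e-12)
  ## constant offset: error = c * T / integral(ref)
  c0 <- 0.37
  simc <- ref; simc$value <- ref$value + c0
  trap <- sum((ref$value[-1] + ref$value[-100]) / 2 * diff(x))
  expect_equal(l1_relative_error(simc, ref), c0 / trap, tolerance = 1e-12)
  ## scale covariance
  sims <- ref; sims$value <- ref$value * 1.3
  expect_equal(l1_relative_error(sims, ref),
               {
                 r5 <- ref; r5$value <- 5 * r5$value
                 s5 <- sims; s5$value <- 5 * s5$value
                 l1_relative_error(s5, r5)
               })
  zero <- ref; zero$value <- 0
  expect_error(l1_relative_error(ref, zero), "zero")
})

test_that("normalization anchors the wild-type AP curve at 20% of its length", {
  x <- seq(0, 1, length.out = 50)
  prof <- tibble::tibble(axis = "AP", time_hr = 19.5, position_frac = x,
                         value = 1 + x^2, dosage = 1)
  same <- normalize_to_reference(prof, prof)
  expect_equal(attr(same, "factor"), 1)
  ref3 <- prof; ref3$value <- 3 * prof$value
  scaled <- normalize_to_reference(prof, ref3)
  expect_equal(attr(scaled, "factor"), 3)
  expect_equal(scaled$value, 3 * prof$value)
  v_s <- approx(scaled$position_frac, scaled$value, xout = 0.2)$y
  v_r <- approx(ref3$position_frac, ref3$value, xout = 0.2)$y
  expect_equal(v_s, v_r)
  expect_error(normalize_to_reference(prof[prof$axis == "DV", ], prof), "anchor")
})

test_that("synthetic reference curves are reproducible and noiseless by default", {
  cfg <- simulation_config(n = 6, output_times = c(3, 13.5))
  r0 <- synth_reference_curves(cfg, dosages = 1, times = 13.5, noise_sd = 0)
  sim <- simulate_chamber(cfg)
  direct <- grksim:::profiles_of(sim, 13.5)
  expect_equal(r0$value, direct$value)
  r1 <- synth_reference_curves(cfg, dosages = 1, times = 13.5, noise_sd = 0.05, seed = 7)
  r2 <- synth_reference_curves(cfg, dosages = 1, times = 13.5, noise_sd = 0.05, seed = 7)
  r3 <- synth_reference_curves(cfg, dosages = 1, times = 13.5, noise_sd = 0.05, seed = 8)
  expect_identical(r1$value, r2$value)
  expect_false(identical(r1$value, r3$value))
  expect_false(identical(r1$value, r0$value))
  ## CSV round trip
  f <- tempfile(fileext = ".csv")
  synth_reference_curves(cfg, dosages = 1, times = 13.5, path = f)
  expect_true(file.exists(f))
  back <- read.csv(f)
  expect_equal(nrow(back), nrow(r0))
  unlink(f)
})

test_that("a degenerate one-point gamma grid is returned as the optimum", {
  cfg <- simulation_config(n = 6, output_times = c(3, 13.5))
  ref <- synth_reference_curves(cfg, dosages = 1, times = 13.5)
  cal <- calibrate_gammas(5e4, 1e3, ref, cfg, dosages = 1, times = 13.5)
  expect_equal(unname(cal$best), c(5e4, 1e3))
  expect_equal(nrow(cal$errors), 1L)
  expect_lt(cal$errors$l1_error, 1e-10)
  expect_error(calibrate_gammas(numeric(0), 1e3, ref, cfg), "nonempty")
})
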