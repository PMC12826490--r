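test_that("effective rates implement the inhibitor feedback formulas", {
  p <- kinetic_params()
  expect_equal(effective_rates(p, STY = 0, KEK1 = 0),
               list(k_on_eff = p$k_on, k_s_eff = p$k_s))
  ## gamma * KEK1 / K = 1 halves the binding rate
  r <- effective_rates(p, STY = p$K_sty / p$gamma_STY, KEK1 = p$K_kek / p$gamma_KEK1)
  expect_equal(r$k_on_eff, p$k_on / 2)
  expect_equal(r$k_s_eff, p$k_s / 2)
  ## strictly decreasing in the inhibitor
  ks <- effective_rates(p, STY = c(0, 1e-26, 1e-25), KEK1 = 0)$k_s_eff
  expect_true(all(diff(ks) < 0))
  expect_error(effective_rates(p, STY = -1e-30, KEK1 = 0), "nonnegative")
})

test_that("receptor-only steady state sits at Q_r / k_er, consistent with R0", {
  p <- kinetic_params()
  Rstar <- p$Q_r / p$k_er
  st <- list(L = 0, C = 0, Ci = 0, R = Rstar, S = 0, STY = 0, KEK1 = 0)
  d <- reaction_rhs(p, st)
  expect_lt(max(abs(unlist(d))), 1e-35)
  expect_lt(abs(Rstar - p$R0) / Rstar, 0.005)
  ## signal fixed point given held Ci and no feedback
  st2 <- list(L = 0, C = 0, Ci = 3e-22, R = Rstar,
              S = p$k_s * 3e-22 / p$k_d, STY = 0, KEK1 = 0)
  expect_equal(reaction_rhs(p, st2)$S, 0)
})

test_that("binding bookkeeping: the L + C + Ci pool only leaks via degradation", {
  p <- kinetic_params(k_on = 3e23, k_off = 4, k_ec = 9)
  set.seed(7)
  for (i in 1:20) {
    st <- as.list(setNames(abs(rnorm(7, 0, 1e-22)), c("L", "C", "Ci", "R", "S", "STY", "KEK1")))
    d <- reaction_rhs(p, st)
    expect_equal(d$L + d$C + d$Ci, -p$alpha_deg * p$k_deg * st$Ci, tolerance = 1e-12)
  }
})

test_that("the reaction field points inward on the nonnegative orthant boundary", {
  p <- kinetic_params()
  set.seed(11)
  for (i in 1:25) {
    st <- as.list(setNames(abs(rnorm(7, 0, 1e-22)), c("L", "C", "Ci", "R", "S", "STY", "KEK1")))
    zero_sp <- sample(names(st), 1)
    st[[zero_sp]] <- 0
    d <- reaction_rhs(p, st)
    expect_gte(d[[zero_sp]], 0)
  }
})

test_that("depletion variants rescale exactly the documented parameters", {
  p <- kinetic_params()
  expect_equal(depletion_variant(p, "sty", 1), p)
  ps <- depletion_variant(p, "sty", 0.5)
  expect_equal(ps$k_STY, p$k_STY * 0.5)
  expect_equal(ps$gamma_STY, p$gamma_STY)
  pe <- depletion_variant(p, "egfr", 0.25)
  expect_equal(pe$R0, p$R0 * 0.25)
  expect_equal(pe$Q_r, p$Q_r * 0.25)
  expect_equal(pe$k_STY, p$k_STY)
  expect_error(depletion_variant(p, "sty", 0), "fraction")
  expect_error(depletion_variant(p, "sty", 1.5), "fraction")
  expect_error(depletion_variant(p, "arg", 0.5))
})

test_that("parameter validation flags range violations and alpha imbalance", {
  expect_error(kinetic_params(k_off = -1), "nonnegative")
  expect_warning(kinetic_params(alpha_rec = 0.6, alpha_deg = 0.5), "not 1")
  expect_error(kinetic_params(alpha_rec = 0.7, alpha_deg = 0.7), "1.25")
  expect_warning(grksim:::validate_params(kinetic_params(D = 10), warn_ranges = TRUE),
                 "literature range")
  ## the lower bound of the published diffusion range passes silently
  expect_silent(grksim:::validate_params(kinetic_params(D = 36), warn_ranges = TRUE))
})

test_that("steady-state feedback is monotone in the inhibitor strengths", {
  skip_if_not_installed("deSolve")
  run_ss <- function(gamma_STY, gamma_KEK1) {
    p <- kinetic_params(gamma_STY = gamma_STY, gamma_KEK1 = gamma_KEK1)
    pn <- p
    pn$kon_over_H <- p$k_on / p$H
    rhs <- function(t, y, parms) {
      st <- as.list(y)
      d <- grksim:::rx_core(pn, st$L, st$C, st$Ci, st$R, st$S, st$STY, st$KEK1,
                            Qr = p$Q_r, gamma_STY = p$gamma_STY)
      d$L <- d$L + 2e-21  # constant secretion input
      list(unlist(d))
    }
    y0 <- c(L = 0, C = 0, Ci = 0, R = p$R0, S = 0, STY = 0, KEK1 = 0)
    out <- deSolve::lsoda(y0, times = c(0, 50), func = rhs, parms = NULL,
                          rtol = 1e-8, atol = 1e-32, maxsteps = 1e5)
    out[2, -1]
  }
  base <- run_ss(5e4, 1e3)
  more_sty <- run_ss(2e5, 1e3)
  more_kek <- run_ss(5e4, 1e4)
  expect_lte(more_sty[["S"]], base[["S"]])
  expect_lte(more_kek[["C"]], base[["C"]])
})

test_that("nondimensionalization round-trips exactly and normalizes R to one", {
  p <- kinetic_params()
  nd <- nondimensionalize(p, conc_scale = p$R0, length_scale = 153.5)
  expect_equal(nd$params$R0, 1)
  back <- redimensionalize(nd)
  for (k in names(unclass(p))) {
    if (is.numeric(p[[k]])) expect_equal(back[[k]], p[[k]], tolerance = 1e-12, info = k)
  }
})
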