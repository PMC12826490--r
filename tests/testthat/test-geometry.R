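test_that("dims_at reproduces every measured table cell exactly at stage times", {
  tl <- chamber_timeline()
  d <- stage_dimensions()
  got <- dims_at(tl, d$time_hr)
  for (col in c("L_E", "L_O", "L_FC", "W_E", "W_O")) {
    expect_equal(got[[col]], d[[col]], info = col)
  }
  ## piecewise-linear midpoint between S8E and S8L
  expect_equal(dims_at(tl, 9)$L_E, (99 + 132) / 2)
  expect_error(dims_at(tl, 2.9), "range")
  expect_error(dims_at(tl, 20), "range")
})

test_that("overall growth factors match a four-fold AP and three-fold DV expansion", {
  tl <- chamber_timeline()
  d0 <- dims_at(tl, tl$t_start)
  d1 <- dims_at(tl, tl$t_end)
  expect_equal(round(d1$L_E / d0$L_E), 4)
  expect_equal(round(d1$W_E / d0$W_E), 3)
})

test_that("growth stop freezes all dimensions", {
  tl <- chamber_timeline(growth_stop_time = 10.5)
  d_late <- dims_at(tl, 19.5)
  d_stop <- dims_at(tl, 10.5)
  expect_equal(d_late[setdiff(names(d_late), "time_hr")],
               d_stop[setdiff(names(d_stop), "time_hr")], tolerance = 1e-12)
  v <- growth_velocity(tl, 15, matrix(c(0, 0, 66), 1))
  expect_equal(max(abs(v)), 0)
})

test_that("growth velocity maps the spheroid onto its later self", {
  tl <- chamber_timeline()
  m <- cubed_spheroid(6, dims_at(tl, 9)$L_AP, dims_at(tl, 9)$L_DV)
  xyz <- m$geom$cell_xyz
  dt <- 1e-5
  v <- growth_velocity(tl, 9, xyz)
  moved <- xyz + dt * v
  d1 <- dims_at(tl, 9 + dt)
  res <- (moved[, 1] / d1$L_DV)^2 + (moved[, 2] / d1$L_DV)^2 + (moved[, 3] / d1$L_AP)^2 - 1
  expect_lt(max(abs(res)), 1e-8)
  ## posterior pole moves with the AP semi-axis
  vp <- growth_velocity(tl, 9, matrix(c(0, 0, dims_at(tl, 9)$L_AP), 1))
  expect_equal(vp[3], (132 - 99) / 2 / 3, tolerance = 1e-3)
})

test_that("nucleus trajectory: posterior through late S8, dorsal-anterior anchor afterwards", {
  tl <- chamber_timeline()
  expect_equal(nucleus_position(tl, 3)$eta, 0)
  expect_equal(nucleus_position(tl, 10.5)$eta, 0)
  expect_gt(nucleus_position(tl, 12)$eta, 0)
  ## anchored at the oocyte anterior boundary from anchor_time on
  for (t in c(13.5, 16.5, 19.5)) {
    np <- nucleus_position(tl, t)
    expect_equal(np$eta, grksim:::oocyte_eta(tl, t), tolerance = 1e-10)
    expect_equal(np$theta, 0)
  }
  ## freeze semantics: angular position constant after the stop time
  tls <- chamber_timeline(nucleus_stop_time = 10.5)
  expect_equal(nucleus_position(tls, 19.5)$eta, nucleus_position(tls, 10.5)$eta)
  expect_equal(nucleus_position(tls, 19.5)$eta, 0)
})

test_that("follicle-cell shift velocity is tangent, meridional and pole-fixed", {
  tl <- chamber_timeline()
  t <- 14
  d <- dims_at(tl, t)
  m <- cubed_spheroid(6, d$L_AP, d$L_DV)
  xyz <- m$geom$cell_xyz
  w <- fc_shift_velocity(tl, t, xyz)
  expect_gt(max(abs(w)), 0)
  nrm <- cbind(xyz[, 1] / d$L_DV^2, xyz[, 2] / d$L_DV^2, xyz[, 3] / d$L_AP^2)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  tang <- abs(rowSums(w * nrm)) / pmax(sqrt(rowSums(w^2)), 1e-300)
  expect_lt(max(tang[rowSums(w^2) > 0]), 1e-10)
  ## zero when disabled, zero at the pole, zero while cells cover everything
  expect_equal(max(abs(fc_shift_velocity(tl, t, xyz, shift_enabled = FALSE))), 0)
  wp <- fc_shift_velocity(tl, t, matrix(c(0, 0, d$L_AP), 1))
  expect_lt(max(abs(wp)), 1e-8)
  expect_equal(max(abs(fc_shift_velocity(tl, 5, xyz))), 0)
})

test_that("shift velocity tracks the follicle-cell anterior edge", {
  tl <- chamber_timeline()
  t <- 14; dt <- 1e-4
  d <- dims_at(tl, t)
  eta_fc <- grksim:::fc_extent_eta(tl, t)
  edge <- matrix(c(d$L_DV * sin(eta_fc), 0, d$L_AP * cos(eta_fc)), 1)
  w <- fc_shift_velocity(tl, t, edge)
  v <- growth_velocity(tl, t, edge)
  moved <- edge + dt * (w + v)
  d1 <- dims_at(tl, t + dt)
  eta_moved <- acos(moved[3] / d1$L_AP)
  expect_equal(eta_moved, grksim:::fc_extent_eta(tl, t + dt), tolerance = 1e-6)
})

test_that("meridian circumference matches the elliptic perimeter", {
  ## sphere
  expect_equal(meridian_circumference(list(L_E = 10, W_E = 10)), 10 * pi,
               tolerance = 1e-8)
  ## independent Ramanujan-II approximation as oracle
  ram2 <- function(a, b) {
    h <- ((a - b) / (a + b))^2
    pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
  }
  for (dims in list(list(L_E = 307, W_E = 129), list(L_E = 132, W_E = 74))) {
    expect_equal(meridian_circumference(dims), ram2(dims$L_E / 2, dims$W_E / 2),
                 tolerance = 1e-5)
  }
})

test_that("timeline validation rejects inconsistent dimension tables", {
  d <- stage_dimensions()
  check_bad <- function(mutate_fn, pattern) {
    bad <- mutate_fn(d)
    f <- tempfile(fileext = ".csv")
    on.exit(unlink(f), add = TRUE)
    write.csv(bad, f, row.names = FALSE)
    expect_error(stage_dimensions(f), pattern)
  }
  check_bad(function(x) { x$L_O[3] <- x$L_E[3] + 1; x }, "cannot exceed")
  check_bad(function(x) { x$L_E[2] <- -5; x }, "positive")
  check_bad(function(x) { x$time_hr[2] <- 3; x }, "increasing")
  ## standard-deviation columns are carried but harmless
  expect_true(all(c("sd_L_E", "sd_W_O") %in% names(d)))
})
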