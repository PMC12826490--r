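#' Measured egg-chamber stage dimensions
#'
#' Returns the packaged six-stage dimension table: egg chamber length `L_E`,
#' oocyte length `L_O`, columnar follicle-cell extent `L_FC`, egg chamber width
#' `W_E` and oocyte width `W_O` (all straight-line lengths in micrometers), at
#' the model times 3, 7.5, 10.5, 13.5, 16.5 and 19.5 hours (stages S7 to S10A).
#' `L_O` and `W_O` are not measurable at S7 and are `NA` there.
#'
#' @param path Optional path to a CSV with the same columns; defaults to the
#'   packaged table. Standard-deviation columns (prefix `sd_`) are accepted and
#'   carried along but ignored by the simulator.
#' @return A tibble with one row per stage.
#' @export
#' @examples
#' stage_dimensions()
stage_dimensions <- function(path = NULL) {
  path <- path %||% system.file("extdata", "stage_dimensions.csv", package = "grksim")
  df <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  need <- c("stage", "time_hr", "L_E", "L_O", "L_FC", "W_E", "W_O")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0L) {
    abort(paste0("stage dimension table is missing columns: ", paste(miss, collapse = ", ")))
  }
  df <- arrange(df, .data$time_hr)
  if (any(diff(df$time_hr) <= 0)) abort("stage times must be strictly increasing")
  for (col in c("L_E", "L_FC", "W_E")) {
    if (any(!is.finite(df[[col]]) | df[[col]] <= 0)) {
      abort(paste0("column ", col, " must be positive at every stage"))
    }
  }
  ok <- function(x, y) all(is.na(x) | x <= y)
  if (!ok(df$L_O, df$L_E) || !ok(df$L_FC, df$L_E) || !ok(df$W_O, df$W_E)) {
    abort("oocyte/FC dimensions cannot exceed the egg chamber dimensions")
  }
  df
}

#' Continuous-time egg-chamber geometry timeline
#'
#' Wraps the stage dimension table into a timeline object providing
#' piecewise-linear interpolation of all dimensions, the oocyte-nucleus
#' trajectory along the dorsal meridian, and the growth / follicle-cell shift
#' velocity fields. Optional freeze switches reproduce the mechanistic
#' perturbations: `growth_stop_time` holds every dimension at its value at that
#' time, `nucleus_stop_time` freezes the nucleus' angular position.
#'
#' The nucleus sits at the posterior pole (`eta = 0`) until `nucleus_start`,
#' then travels along the dorsal meridian (`theta = 0`), reaching its
#' dorsal-anterior anchor at `anchor_time`; thereafter it tracks the anterior
#' boundary of the oocyte (meridian position where the oocyte cap of axial
#' length `L_O(t)` ends).
#'
#' @param dims Stage table as from [stage_dimensions()].
#' @param growth_stop_time,nucleus_stop_time Optional freeze times in hours.
#' @param nucleus_start Hour at which the nucleus leaves the posterior pole
#'   (default 10.5, late S8).
#' @param anchor_time Hour at which the nucleus reaches its dorsal-anterior
#'   anchor (default 13.5, early S9).
#' @param oocyte_floor Minimal axial oocyte length (um) used when extrapolating
#'   the unmeasured early-stage oocyte.
#' @return An object of class `egg_timeline`.
#' @export
chamber_timeline <- function(dims = stage_dimensions(),
                             growth_stop_time = NULL,
                             nucleus_stop_time = NULL,
                             nucleus_start = 10.5,
                             anchor_time = 13.5,
                             oocyte_floor = 5) {
  if (!is.null(growth_stop_time)) stopifnot(is.numeric(growth_stop_time), length(growth_stop_time) == 1L)
  if (!is.null(nucleus_stop_time)) stopifnot(is.numeric(nucleus_stop_time), length(nucleus_stop_time) == 1L)
  tl <- structure(
    list(
      dims = dims,
      t_start = min(dims$time_hr),
      t_end = max(dims$time_hr),
      growth_stop_time = growth_stop_time,
      nucleus_stop_time = nucleus_stop_time,
      nucleus_start = nucleus_start,
      anchor_time = anchor_time,
      oocyte_floor = oocyte_floor
    ),
    class = "egg_timeline"
  )
  tl$cache <- timeline_cache(dims)
  tl
}

## Plain closures for the piecewise-linear dimension columns; the hot path of
## the integrator goes through these instead of the tibble-returning verbs.
timeline_cache <- function(dims) {
  mk <- function(col) {
    keep <- !is.na(dims[[col]])
    stats::approxfun(dims$time_hr[keep], dims[[col]][keep], rule = 2)
  }
  keep <- !is.na(dims$L_O)
  tm <- dims$time_hr[keep]; vm <- dims$L_O[keep]
  list(
    L_E = mk("L_E"), L_FC = mk("L_FC"), W_E = mk("W_E"),
    L_O = mk("L_O"),
    L_O_tmin = tm[1],
    L_O_slope = (vm[2] - vm[1]) / (tm[2] - tm[1]),
    L_O_v1 = vm[1]
  )
}

## Fast accessors (vectorized over t, plain numeric output). Growth stop is
## applied here.
tl_eff_time <- function(tl, t) {
  if (!is.null(tl$growth_stop_time)) pmin(t, tl$growth_stop_time) else t
}

tl_axes <- function(tl, t) {
  te <- tl_eff_time(tl, t)
  list(a = tl$cache$L_E(te) / 2, b = tl$cache$W_E(te) / 2)
}

tl_L_FC <- function(tl, t) tl$cache$L_FC(tl_eff_time(tl, t))

tl_L_O <- function(tl, t) {
  te <- tl_eff_time(tl, t)
  out <- tl$cache$L_O(te)
  early <- te < tl$cache$L_O_tmin
  if (any(early)) {
    out[early] <- tl$cache$L_O_v1 + tl$cache$L_O_slope * (te[early] - tl$cache$L_O_tmin)
  }
  pmax(out, tl$oocyte_floor)
}

tl_eta_oo <- function(tl, t) {
  ax <- tl_axes(tl, t)
  cap_eta(tl_L_O(tl, t), ax$a)
}

tl_eta_fc <- function(tl, t, shift_enabled = TRUE) {
  if (!shift_enabled) return(rep(pi, length(t)))
  ax <- tl_axes(tl, t)
  cap_eta(tl_L_FC(tl, t), ax$a)
}

tl_eta_nucleus <- function(tl, t) {
  teff <- t
  if (!is.null(tl$nucleus_stop_time)) teff <- pmin(teff, tl$nucleus_stop_time)
  frac <- pmin(1, pmax(0, (teff - tl$nucleus_start) / (tl$anchor_time - tl$nucleus_start)))
  frac * tl_eta_oo(tl, teff)
}

#' @export
print.egg_timeline <- function(x, ...) {
  cat("<egg_timeline> ", x$t_start, "-", x$t_end, " hr, ",
      nrow(x$dims), " stages\n", sep = "")
  if (!is.null(x$growth_stop_time)) cat("  growth stopped at ", x$growth_stop_time, " hr\n", sep = "")
  if (!is.null(x$nucleus_stop_time)) cat("  nucleus frozen at ", x$nucleus_stop_time, " hr\n", sep = "")
  invisible(x)
}

check_time_range <- function(timeline, t) {
  if (any(t < timeline$t_start - 1e-9 | t > timeline$t_end + 1e-9)) {
    abort(paste0("time out of range [", timeline$t_start, ", ", timeline$t_end, "] hr"))
  }
}

#' Interpolated egg-chamber dimensions at a given time
#'
#' Piecewise-linear interpolation of every dimension column; exact table values
#' at the six stage times. With a `growth_stop_time` set on the timeline, all
#' dimensions are held constant from that time on. Also reports the prolate
#' spheroid semi-axes `L_AP = L_E / 2` and `L_DV = W_E / 2`.
#'
#' @param timeline An [chamber_timeline()] object.
#' @param t Time(s) in hours, within the timeline range.
#' @return A tibble with one row per requested time.
#' @export
#' @examples
#' dims_at(chamber_timeline(), c(3, 9, 19.5))
dims_at <- function(timeline, t) {
  check_time_range(timeline, t)
  teff <- t
  if (!is.null(timeline$growth_stop_time)) {
    teff <- pmin(teff, timeline$growth_stop_time)
  }
  d <- timeline$dims
  interp_col <- function(col) {
    v <- d[[col]]
    keep <- !is.na(v)
    if (sum(keep) < 2L) return(rep(NA_real_, length(teff)))
    out <- rep(NA_real_, length(teff))
    inside <- teff >= min(d$time_hr[keep]) - 1e-9 & teff <= max(d$time_hr[keep]) + 1e-9
    if (any(inside)) {
      out[inside] <- approx(d$time_hr[keep], v[keep], xout = pmax(pmin(teff[inside], max(d$time_hr[keep])), min(d$time_hr[keep])))$y
    }
    out
  }
  tibble::tibble(
    time_hr = t,
    L_E = interp_col("L_E"),
    L_O = interp_col("L_O"),
    L_FC = interp_col("L_FC"),
    W_E = interp_col("W_E"),
    W_O = interp_col("W_O")
  ) |>
    mutate(L_AP = .data$L_E / 2, L_DV = .data$W_E / 2)
}

## Axial oocyte length with early-stage linear back-extrapolation from the
## first two measured stages, floored at `oocyte_floor`.
oocyte_extent <- function(timeline, t) {
  check_time_range(timeline, t)
  tl_L_O(timeline, t)
}

## Polar angle (from the posterior pole) of the anterior boundary of a
## posterior cap of axial length len on a spheroid with AP semi-axis a:
## z = a - len  =>  cos(eta) = 1 - len / a.
cap_eta <- function(len, a) {
  acos(pmin(1, pmax(-1, 1 - len / a)))
}

## Meridian polar angle of the oocyte anterior boundary.
oocyte_eta <- function(timeline, t) tl_eta_oo(timeline, t)

## Meridian polar angle of the columnar follicle-cell anterior edge. With the
## shift disabled the cells keep covering the whole chamber.
fc_extent_eta <- function(timeline, t, shift_enabled = TRUE) {
  tl_eta_fc(timeline, t, shift_enabled)
}

#' Oocyte nucleus position
#'
#' The nucleus stays at the posterior pole until late S8, then moves along the
#' dorsal meridian (`theta = 0`) and anchors at the dorsal-anterior boundary of
#' the oocyte; after anchoring it keeps tracking that boundary as the oocyte
#' grows. With `nucleus_stop_time` set on the timeline, the angular position is
#' frozen at its value at that time (and is afterwards only advected with
#' growth, i.e. constant in `(eta, theta)`).
#'
#' @inheritParams dims_at
#' @return A tibble with columns `time_hr`, `eta`, `theta`, `x`, `y`, `z`
#'   (positions in um on the time-`t` spheroid).
#' @export
nucleus_position <- function(timeline, t) {
  check_time_range(timeline, t)
  eta <- tl_eta_nucleus(timeline, t)
  ax <- tl_axes(timeline, t)  # current axes: frozen nucleus still rides growth
  tibble::tibble(
    time_hr = t,
    eta = eta,
    theta = 0,
    x = ax$b * sin(eta),
    y = 0,
    z = ax$a * cos(eta)
  )
}

## Time derivatives of the semi-axes (um/hr), respecting growth stop.
axis_rates <- function(timeline, t, h = 1e-4) {
  if (!is.null(timeline$growth_stop_time) && t >= timeline$growth_stop_time - 1e-12) {
    return(list(da = 0, db = 0))
  }
  tm <- max(timeline$t_start, t - h)
  tp <- min(timeline$t_end, t + h)
  if (!is.null(timeline$growth_stop_time)) tp <- min(tp, timeline$growth_stop_time)
  ax1 <- tl_axes(timeline, tm)
  ax2 <- tl_axes(timeline, tp)
  list(da = (ax2$a - ax1$a) / (tp - tm), db = (ax2$b - ax1$b) / (tp - tm))
}

#' Growth velocity field
#'
#' Velocity (um/hr) of surface points under the coordinate-preserving growth
#' map: a point keeps its angular coordinates `(eta, theta)` while the
#' semi-axes change, so `v = (db/dt * x/b, db/dt * y/b, da/dt * z/a)`.
#' Vanishes identically when growth is stopped.
#'
#' @inheritParams dims_at
#' @param nodes Numeric matrix (m x 3) of points on the time-`t` spheroid (um).
#' @return An m x 3 matrix of velocities in um/hr.
#' @export
growth_velocity <- function(timeline, t, nodes) {
  check_time_range(timeline, t)
  nodes <- rbind(nodes)
  ax <- tl_axes(timeline, t)
  r <- axis_rates(timeline, t)
  cbind(r$db / ax$b * nodes[, 1],
        r$db / ax$b * nodes[, 2],
        r$da / ax$a * nodes[, 3])
}

#' Follicle-cell shift velocity field
#'
#' Tangential, meridionally directed velocity (um/hr) that carries the
#' follicle-cell layer toward the posterior pole so that the anterior edge of
#' the columnar-cell domain tracks the measured extent `L_FC(t)`. The magnitude
#' is zero at the posterior pole, grows linearly with meridian arc-length up to
#' the follicle-cell anterior edge, and is constant beyond it. Because node
#' angular coordinates are preserved by the growth map, the whole angular drift
#' of the edge is carried by `w`. Returns zero when `shift_enabled = FALSE` or
#' while the cells cover the full chamber (`L_FC = L_E`).
#'
#' @inheritParams growth_velocity
#' @param shift_enabled Logical switch for the perturbation that removes the
#'   cuboidal-to-columnar transition.
#' @return An m x 3 matrix of tangent velocities in um/hr.
#' @export
fc_shift_velocity <- function(timeline, t, nodes, shift_enabled = TRUE, tab = NULL) {
  check_time_range(timeline, t)
  nodes <- rbind(nodes)
  m <- nrow(nodes)
  if (!shift_enabled) return(matrix(0, m, 3))
  ax <- tl_axes(timeline, t)
  a <- ax$a; b <- ax$b
  deta <- fc_edge_eta_rate(timeline, t)
  if (abs(deta) < 1e-14) return(matrix(0, m, 3))
  eta_fc <- fc_extent_eta(timeline, t)
  eta <- acos(pmin(1, pmax(-1, nodes[, 3] / a)))
  theta <- atan2(nodes[, 2], nodes[, 1])
  ## meridian tangent d r / d eta (unnormalized), pointing anterior
  tu <- cbind(b * cos(eta) * cos(theta), b * cos(eta) * sin(theta), -a * sin(eta))
  tun <- sqrt(rowSums(tu^2))
  tab <- tab %||% arc_tables(a, b)
  arc <- meridian_arc(a, b, c(eta, eta_fc), tab = tab)
  s_edge <- arc[m + 1L]
  speed_edge <- abs(deta) * sqrt(b^2 * cos(eta_fc)^2 + a^2 * sin(eta_fc)^2)
  mag <- speed_edge * pmin(1, arc[seq_len(m)] / s_edge)
  dirsign <- if (deta < 0) -1 else 1  # posterior shift: eta decreasing
  tu * (dirsign * mag / pmax(tun, 1e-300))
}

## d eta_FC / dt by centered finite difference (zero when the cells cover the
## whole chamber on both sides of t).
## Backward-looking difference: the columnar-cell edge detaches from the
## anterior pole with a square-root-singular speed, and a centered window
## would smear that onset backward in time.
fc_edge_eta_rate <- function(timeline, t, h = 1e-4) {
  tm <- max(timeline$t_start, t - h)
  tp <- t
  if (tp - tm < h / 2) tp <- min(timeline$t_end, tm + h)
  e <- tl_eta_fc(timeline, c(tm, tp))
  (e[2] - e[1]) / (tp - tm)
}

#' Meridian circumference of the egg chamber
#'
#' Perimeter of the full anterior-posterior meridian ellipse with semi-axes
#' `L_E / 2` and `W_E / 2`, computed from the complete elliptic integral
#' (adaptive quadrature, relative error below 1e-8).
#'
#' @param dims A one-row dimension tibble (as from [dims_at()]) or any list
#'   with elements `L_E` and `W_E`.
#' @return Perimeter in um.
#' @export
#' @examples
#' meridian_circumference(list(L_E = 307, W_E = 129))
meridian_circumference <- function(dims) {
  ellipse_perimeter(dims$L_E / 2, dims$W_E / 2)
}

ellipse_perimeter <- function(a, b) {
  4 * integrate(function(th) sqrt(a^2 * sin(th)^2 + b^2 * cos(th)^2),
                0, pi / 2, rel.tol = 1e-10)$value
}

## Cumulative meridian arc-length and cap-area tables for semi-axes (a, b),
## with fast findInterval-based interpolation (the integrator rebuilds these
## once per step as the chamber grows).
arc_tables <- function(a, b, ngrid = 1024L) {
  grid <- seq(0, pi, length.out = ngrid)
  ds <- sqrt(b^2 * cos(grid)^2 + a^2 * sin(grid)^2)
  dg <- diff(grid)
  arc <- c(0, cumsum((ds[-1] + ds[-ngrid]) / 2 * dg))
  da <- 2 * pi * b * sin(grid) * ds
  ar <- c(0, cumsum((da[-1] + da[-ngrid]) / 2 * dg))
  list(a = a, b = b, grid = grid, arc = arc, area = ar, h = grid[2] - grid[1])
}

tab_lookup <- function(xg, yg, x) {
  x <- pmin(xg[length(xg)], pmax(xg[1], x))
  i <- findInterval(x, xg, all.inside = TRUE)
  t <- (x - xg[i]) / (xg[i + 1L] - xg[i])
  yg[i] * (1 - t) + yg[i + 1L] * t
}

## Meridian arc-length from the posterior pole to polar angle eta on the
## spheroid with semi-axes a (AP) and b (DV). Vectorized over eta.
meridian_arc <- function(a, b, eta, tab = NULL) {
  tab <- tab %||% arc_tables(a, b)
  tab_lookup(tab$grid, tab$arc, eta)
}

## Inverse of meridian_arc: polar angle at a given arc-length from the pole.
eta_at_arc <- function(a, b, s, tab = NULL) {
  tab <- tab %||% arc_tables(a, b)
  tab_lookup(tab$arc, tab$grid, s)
}

## Surface area (um^2) of the posterior cap eta <= eta0 of the spheroid
## (surface of revolution quadrature). Vectorized over eta0.
spheroid_cap_area <- function(a, b, eta0, tab = NULL) {
  tab <- tab %||% arc_tables(a, b)
  tab_lookup(tab$grid, tab$area, eta0)
}

## Closed-form prolate spheroid surface area (a >= b).
spheroid_area_analytic <- function(a, b) {
  if (abs(a - b) < 1e-12 * a) return(4 * pi * a^2)
  e <- sqrt(1 - (b / a)^2)
  2 * pi * b^2 + 2 * pi * a * b * asin(e) / e
}
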