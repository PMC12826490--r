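#' Ligand secretion source specification
#'
#' Describes the T-shaped Gurken secretion footprint that tracks the oocyte
#' nucleus: a dorsal stripe running posterior from the nucleus along the
#' dorsal midline (length a stage-dependent fraction of the oocyte's curved
#' meridian length, transverse half-width a fraction of the half-ring) plus a
#' transverse band at the nucleus. Total secretion is proportional to the
#' oocyte surface area, `Q(t) = V0 * A_oocyte(t)`, distributed uniformly over
#' the support, so `V0` is the per-area flux when the support covers the
#' oocyte.
#'
#' The stage-resolved shape ratios default to the packaged table. The packaged
#' values are stage-constant placeholders (0.5) standing in for unpublished
#' measurements and should be overridden for production use.
#'
#' @param V0 Reference secretion flux, mol um^-2 hr^-1.
#' @param ratios Tibble with columns `time_hr`, `ratio_dorsal_length`,
#'   `ratio_posterior_width`, `ratio_anterior_width` (all in (0, 1]).
#' @param bar_thickness Meridional thickness of the transverse band as a
#'   fraction of the oocyte curved length.
#' @return An object of class `source_spec`.
#' @export
source_spec <- function(V0 = kinetic_params()$V0,
                        ratios = NULL,
                        bar_thickness = 0.1) {
  if (is.null(ratios)) {
    path <- system.file("extdata", "source_ratios.csv", package = "grksim")
    ratios <- tibble::as_tibble(read.csv(path, stringsAsFactors = FALSE))
  }
  need <- c("time_hr", "ratio_dorsal_length", "ratio_posterior_width", "ratio_anterior_width")
  if (!all(need %in% names(ratios))) {
    abort("ratios must have columns time_hr, ratio_dorsal_length, ratio_posterior_width, ratio_anterior_width")
  }
  for (col in need[-1]) {
    v <- ratios[[col]]
    if (any(v <= 0 | v > 1)) abort(paste0(col, " must lie in (0, 1]"))
  }
  if (V0 < 0) abort("V0 must be nonnegative")
  structure(list(V0 = V0, ratios = arrange(ratios, .data$time_hr),
                 bar_thickness = bar_thickness),
            class = "source_spec")
}

#' Scale the ligand dosage
#'
#' Returns the source with `V0` multiplied (1x / 2x / 4x gurken gene-copy
#' simulations use multipliers 0.5, 1 and 2); shape ratios are unchanged.
#'
#' @param spec A [source_spec()].
#' @param multiplier Positive dosage multiplier.
#' @return A modified `source_spec`.
#' @export
dosage_variant <- function(spec, multiplier) {
  if (!is.numeric(multiplier) || length(multiplier) != 1L || multiplier <= 0) {
    abort("multiplier must be positive")
  }
  spec$V0 <- spec$V0 * multiplier
  spec
}

## Interpolated shape ratios at time t (constant extrapolation at the ends).
source_ratios_at <- function(spec, t) {
  r <- spec$ratios
  g <- function(col) approx(r$time_hr, r[[col]], xout = t, rule = 2)$y
  list(
    dorsal_length = g("ratio_dorsal_length"),
    posterior_width = g("ratio_posterior_width"),
    anterior_width = g("ratio_anterior_width")
  )
}

#' Secretion flux field at a given time
#'
#' Nonnegative per-area flux (mol um^-2 hr^-1) on the mesh cells: uniform on
#' the T-shaped support anchored at the current nucleus position, zero
#' elsewhere, normalized so that its surface integral equals
#' `V0 * A_oocyte(t)` (total secretion proportional to the oocyte surface).
#' With growth stopped on the timeline, the oocyte area and hence the total
#' flux stay constant.
#'
#' @param spec A [source_spec()].
#' @param timeline An [chamber_timeline()].
#' @param mesh A [cubed_spheroid()] mesh at the time-`t` semi-axes.
#' @param t Time in hours.
#' @return Numeric vector of per-cell flux values.
#' @export
source_flux <- function(spec, timeline, mesh, t, tab = NULL) {
  check_time_range(timeline, t)
  N <- mesh$N
  if (spec$V0 == 0) return(numeric(N))
  a <- mesh$a; b <- mesh$b
  tab <- tab %||% arc_tables(a, b)
  rt <- source_ratios_at(spec, t)
  eta_oo <- tl_eta_oo(timeline, t)
  eta_n <- tl_eta_nucleus(timeline, t)
  arcs <- meridian_arc(a, b, c(eta_oo, eta_n), tab = tab)
  oo_arc <- arcs[1]; nuc_arc <- arcs[2]
  stem_lo <- eta_at_arc(a, b, max(0, nuc_arc - rt$dorsal_length * oo_arc), tab = tab)
  half_bar <- spec$bar_thickness * oo_arc / 2
  bar_lo <- eta_at_arc(a, b, max(0, nuc_arc - half_bar), tab = tab)
  bar_hi <- eta_at_arc(a, b, nuc_arc + half_bar, tab = tab)
  th_stem <- rt$posterior_width * pi / 2
  th_bar <- rt$anterior_width * pi / 2
  eta <- mesh$cells$eta
  th <- abs(mesh$cells$theta)
  support <- (eta >= stem_lo & eta <= eta_n & th <= th_stem) |
             (eta >= bar_lo & eta <= bar_hi & th <= th_bar)
  Q <- spec$V0 * spheroid_cap_area(a, b, eta_oo, tab = tab)
  if (!any(support)) {
    ## degenerate support on a coarse mesh: deposit into the cell nearest the
    ## nucleus
    d2 <- (eta - eta_n)^2 + th^2
    support <- d2 == min(d2)
  }
  flux <- numeric(N)
  A_support <- 2 * sum(mesh$geom$area[support])
  flux[support] <- Q / A_support
  flux
}
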