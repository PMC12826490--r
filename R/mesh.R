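## Cubed-spheroid surface mesh.
##
## The prolate spheroid (semi-axes L_DV, L_DV, L_AP along x, y, z; posterior
## pole at +z) is meshed by projecting regular grids on the faces of the
## inscribed cube radially onto the reference unit sphere and then scaling onto
## the spheroid. Prolate spheroidal coordinates are degenerate at the poles;
## the cubed construction keeps the stencils regular there. The problem is
## mirror-symmetric in the xz-plane, so only the half y >= 0 is represented:
## 8 logically square n x n zones (two pole half-faces, six quarter side
## faces), cell-centered so that no cell sits on a zone edge. All cross-zone
## coupling happens through (a) ghost-cell values obtained by 4x4 Lagrange
## interpolation in the neighbouring chart and (b) uniquely valued fluxes on
## the shared zone-boundary faces, whose partitions coincide exactly between
## adjacent zones. Ghost positions, interpolation weights and face pairings
## live on the reference sphere and are therefore reused unchanged as the
## spheroid grows; only the metric terms depend on the semi-axes.

CUBE_HALF <- 1 / sqrt(3)

## zone table: face axis/sign and parameter ranges (units of the half-side).
## zones 1-2: posterior/anterior pole half-faces; 3-4 dorsal (+x), 5-6 lateral
## (+y), 7-8 ventral (-x), each split into posterior (z>=0) / anterior halves.
zone_table <- function() {
  a <- CUBE_HALF
  list(
    list(axis = 3L, sgn = +1, ua = 1L, va = 2L, u0 = -a, u1 = a, v0 = 0, v1 = a),
    list(axis = 3L, sgn = -1, ua = 1L, va = 2L, u0 = -a, u1 = a, v0 = 0, v1 = a),
    list(axis = 1L, sgn = +1, ua = 2L, va = 3L, u0 = 0, u1 = a, v0 = 0, v1 = a),
    list(axis = 1L, sgn = +1, ua = 2L, va = 3L, u0 = 0, u1 = a, v0 = -a, v1 = 0),
    list(axis = 2L, sgn = +1, ua = 1L, va = 3L, u0 = -a, u1 = a, v0 = 0, v1 = a),
    list(axis = 2L, sgn = +1, ua = 1L, va = 3L, u0 = -a, u1 = a, v0 = -a, v1 = 0),
    list(axis = 1L, sgn = -1, ua = 2L, va = 3L, u0 = 0, u1 = a, v0 = 0, v1 = a),
    list(axis = 1L, sgn = -1, ua = 2L, va = 3L, u0 = 0, u1 = a, v0 = -a, v1 = 0)
  )
}

## cube point for zone z at parameters (u, v); u, v equal-length vectors.
zone_cube_point <- function(zd, u, v) {
  m <- length(u)
  p <- matrix(0, m, 3)
  p[, zd$axis] <- zd$sgn * CUBE_HALF
  p[, zd$ua] <- u
  p[, zd$va] <- v
  p
}

## unit-sphere chart: radial projection of the cube point and its u/v
## derivatives (analytic).
zone_chart <- function(zd, u, v) {
  p <- zone_cube_point(zd, u, v)
  rho <- sqrt(rowSums(p^2))
  s <- p / rho
  su <- -s * s[, zd$ua]
  su[, zd$ua] <- su[, zd$ua] + 1
  su <- su / rho
  sv <- -s * s[, zd$va]
  sv[, zd$va] <- sv[, zd$va] + 1
  sv <- sv / rho
  list(s = s, su = su, sv = sv)
}

## metric building blocks that depend only on the unit-sphere chart; the
## first-fundamental-form coefficients on the spheroid with semi-axes (A, B)
## are E = B^2*E1 + A^2*E3 etc.
chart_combos <- function(ch) {
  su <- ch$su; sv <- ch$sv
  list(
    E1 = su[, 1]^2 + su[, 2]^2, E3 = su[, 3]^2,
    G1 = sv[, 1]^2 + sv[, 2]^2, G3 = sv[, 3]^2,
    F1 = su[, 1] * sv[, 1] + su[, 2] * sv[, 2], F3 = su[, 3] * sv[, 3]
  )
}

## Map unit-sphere points (rows of s, assumed y >= 0) to (zone, fractional
## cell index) in the owning zone's grid.
locate_unit_points <- function(s, n) {
  zt <- zone_table()
  axv <- max.col(abs(s), ties.method = "first")
  zone <- integer(nrow(s))
  zone[axv == 3L & s[, 3] >= 0] <- 1L
  zone[axv == 3L & s[, 3] < 0] <- 2L
  zone[axv == 1L & s[, 1] >= 0] <- ifelse(s[axv == 1L & s[, 1] >= 0, 3] >= 0, 3L, 4L)
  zone[axv == 2L] <- ifelse(s[axv == 2L, 3] >= 0, 5L, 6L)
  zone[axv == 1L & s[, 1] < 0] <- ifelse(s[axv == 1L & s[, 1] < 0, 3] >= 0, 7L, 8L)
  scale <- CUBE_HALF / abs(s[cbind(seq_len(nrow(s)), axv)])
  cp <- s * scale
  u <- v <- numeric(nrow(s))
  fu <- fv <- numeric(nrow(s))
  for (z in seq_len(8L)) {
    k <- zone == z
    if (!any(k)) next
    zd <- zt[[z]]
    hu <- (zd$u1 - zd$u0) / n
    hv <- (zd$v1 - zd$v0) / n
    u[k] <- cp[k, zd$ua]
    v[k] <- cp[k, zd$va]
    fu[k] <- (u[k] - zd$u0) / hu + 0.5
    fv[k] <- (v[k] - zd$v0) / hv + 0.5
  }
  list(zone = zone, fu = fu, fv = fv)
}

## 4-point Lagrange weights on a uniform unit-spaced grid, window clamped to
## [1, n]; `fi` is the fractional node coordinate (node k at fi = k).
lagrange4 <- function(fi, n) {
  i0 <- pmin(pmax(floor(fi) - 1, 1), n - 3)
  t <- fi - i0
  w <- cbind(
    -(t - 1) * (t - 2) * (t - 3) / 6,
    t * (t - 2) * (t - 3) / 2,
    -t * (t - 1) * (t - 3) / 2,
    t * (t - 1) * (t - 2) / 6
  )
  list(i0 = i0, w = w)
}

linear2 <- function(fi, n) {
  i0 <- pmin(pmax(floor(fi), 1), n - 1)
  t <- fi - i0
  list(i0 = i0, w = cbind(1 - t, t))
}

cell_index <- function(i, j, z, n) i + (j - 1L) * n + (z - 1L) * n * n

#' Build a cubed-spheroid surface mesh
#'
#' Constructs the multi-zone cubed-spheroid mesh of the half prolate spheroid
#' `y >= 0` with semi-axes `L_AP` (anterior-posterior, along z) and `L_DV`
#' (dorsal-ventral, along x and y): regular grids on the inscribed cube's
#' faces are projected radially onto the sphere of radius `L_AP` and then onto
#' the spheroid orthogonally to the z-axis. The mesh is cell-centered with
#' `8 n^2` cells; surface integrals double the represented half. Ghost-cell
#' interpolation operators, zone-interface flux pairings and mirror
#' (Neumann-by-symmetry) closures at the `y = 0` plane are precomputed on the
#' reference sphere so that the same mesh object can be rescaled cheaply as
#' the chamber grows (see [remesh_to()]).
#'
#' @param n Cells per zone edge (at least 4).
#' @param L_AP,L_DV Semi-axes in um.
#' @return An object of class `cubed_spheroid`.
#' @export
#' @examples
#' m <- cubed_spheroid(8, 35.5, 22.5)
#' surface_area(m)
cubed_spheroid <- function(n, L_AP, L_DV) {
  if (n < 4) abort("mesh resolution n must be at least 4")
  stopifnot(L_AP > 0, L_DV > 0)
  zt <- zone_table()
  N <- 8L * n * n

  hu <- vapply(zt, function(z) (z$u1 - z$u0) / n, 0)
  hv <- vapply(zt, function(z) (z$v1 - z$v0) / n, 0)

  grids <- function(kind) {
    ## kind: "c" cell centers, "u" u-faces, "v" v-faces
    out <- vector("list", 8L)
    for (z in seq_len(8L)) {
      zd <- zt[[z]]
      uc <- zd$u0 + (seq_len(n) - 0.5) * hu[z]
      vc <- zd$v0 + (seq_len(n) - 0.5) * hv[z]
      uf <- zd$u0 + (0:n) * hu[z]
      vf <- zd$v0 + (0:n) * hv[z]
      if (kind == "c") { uu <- rep(uc, times = n); vv <- rep(vc, each = n) }
      if (kind == "u") { uu <- rep(uf, times = n); vv <- rep(vc, each = n + 1L) }
      if (kind == "v") { uu <- rep(uc, times = n + 1L); vv <- rep(vf, each = n) }
      out[[z]] <- list(u = uu, v = vv)
    }
    out
  }

  assemble <- function(kind) {
    gs <- grids(kind)
    ss <- su <- sv <- NULL
    zidx <- integer(0)
    for (z in seq_len(8L)) {
      ch <- zone_chart(zt[[z]], gs[[z]]$u, gs[[z]]$v)
      ss <- rbind(ss, ch$s); su <- rbind(su, ch$su); sv <- rbind(sv, ch$sv)
      zidx <- c(zidx, rep(z, length(gs[[z]]$u)))
    }
    ch <- list(s = ss, su = su, sv = sv)
    c(ch, list(combos = chart_combos(ch), zone = zidx,
               hu = hu[zidx], hv = hv[zidx]))
  }

  cells <- assemble("c")
  uf <- assemble("u")
  vf <- assemble("v")
  cells$eta <- acos(pmin(1, pmax(-1, cells$s[, 3])))
  cells$theta <- atan2(cells$s[, 2], cells$s[, 1])

  mesh <- structure(list(
    n = n, a = L_AP, b = L_DV, N = N,
    hu = hu, hv = hv,
    cells = cells, uf = uf, vf = vf
  ), class = "cubed_spheroid")
  mesh$halo <- build_halo(mesh)
  mesh$pairs <- build_pairs(mesh)
  mesh$geom <- mesh_geom(mesh)
  mesh
}

#' @export
print.cubed_spheroid <- function(x, ...) {
  cat("<cubed_spheroid> n=", x$n, " (", x$N, " cells, half-surface), ",
      "semi-axes L_AP=", signif(x$a, 5), " L_DV=", signif(x$b, 5), " um\n", sep = "")
  invisible(x)
}

## Ghost-cell machinery: one ring of ghost cells (including corners) around
## each zone; ghost positions extend the zone's own chart beyond its face,
## values are interpolated from the owning neighbour zone (reflected through
## y = 0 where the ghost falls in the unrepresented half).
build_halo <- function(mesh) {
  n <- mesh$n
  zt <- zone_table()
  gi <- gj <- gz <- integer(0)
  for (z in seq_len(8L)) {
    ii <- c(0:(n + 1L), 0:(n + 1L), rep(0L, n), rep(n + 1L, n))
    jj <- c(rep(0L, n + 2L), rep(n + 1L, n + 2L), 1:n, 1:n)
    gi <- c(gi, ii); gj <- c(gj, jj); gz <- c(gz, rep(z, length(ii)))
  }
  NH <- length(gi)
  us <- vs <- numeric(NH)
  for (z in seq_len(8L)) {
    k <- gz == z
    zd <- zt[[z]]
    us[k] <- zd$u0 + (gi[k] - 0.5) * mesh$hu[z]
    vs[k] <- zd$v0 + (gj[k] - 0.5) * mesh$hv[z]
  }
  p <- matrix(0, NH, 3)
  for (z in seq_len(8L)) {
    k <- gz == z
    p[k, ] <- zone_cube_point(zt[[z]], us[k], vs[k])
  }
  s <- p / sqrt(rowSums(p^2))
  mirror <- s[, 2] < 0
  s[mirror, 2] <- -s[mirror, 2]
  loc <- locate_unit_points(s, n)
  wu <- lagrange4(loc$fu, n)
  wv <- lagrange4(loc$fv, n)
  rows <- rep(seq_len(NH), each = 16L)
  cols <- integer(NH * 16L)
  vals <- numeric(NH * 16L)
  k <- 1L
  for (dv in 0:3) for (du in 0:3) {
    idx <- cell_index(wu$i0 + du, wv$i0 + dv, loc$zone, n)
    sel <- seq(k, by = 16L, length.out = NH)
    cols[sel] <- idx
    vals[sel] <- wu$w[, du + 1L] * wv$w[, dv + 1L]
    k <- k + 1L
  }
  H <- sparseMatrix(i = rows, j = cols, x = vals, dims = c(NH, mesh$N))
  np <- n + 2L
  pad_halo <- (gi + 1L) + gj * np + (gz - 1L) * np * np
  ci <- rep(seq_len(n), times = n * 8L)
  cj <- rep(rep(seq_len(n), each = n), times = 8L)
  cz <- rep(seq_len(8L), each = n * n)
  pad_int <- (ci + 1L) + cj * np + (cz - 1L) * np * np
  list(H = H, mirror = mirror, pad_halo = pad_halo, pad_int = pad_int, np = np,
       pos = s)
}

## Zone-boundary face bookkeeping: faces on the same physical interface are
## paired (their cube-edge partitions coincide exactly); faces on the y = 0
## symmetry plane carry no flux. Indices address the concatenated flux vector
## c(Fu, Fv).
build_pairs <- function(mesh) {
  n <- mesh$n
  zt <- zone_table()
  NU <- 8L * (n + 1L) * n
  fid <- sgn <- cell <- integer(0)
  pos <- NULL
  for (z in seq_len(8L)) {
    zd <- zt[[z]]
    vc <- zd$v0 + (seq_len(n) - 0.5) * mesh$hv[z]
    uc <- zd$u0 + (seq_len(n) - 0.5) * mesh$hu[z]
    ## u-direction boundary faces, i = 1 and i = n+1
    for (side in c(1L, 2L)) {
      i <- if (side == 1L) 1L else n + 1L
      uval <- if (side == 1L) zd$u0 else zd$u1
      idx <- i + (seq_len(n) - 1L) * (n + 1L) + (z - 1L) * (n + 1L) * n
      p <- zone_cube_point(zd, rep(uval, n), vc)
      pos <- rbind(pos, p / sqrt(rowSums(p^2)))
      fid <- c(fid, idx)
      sgn <- c(sgn, rep(if (side == 1L) -1L else 1L, n))
      cell <- c(cell, cell_index(rep(if (side == 1L) 1L else n, n), seq_len(n), z, n))
    }
    ## v-direction boundary faces, j = 1 and j = n+1
    for (side in c(1L, 2L)) {
      j <- if (side == 1L) 1L else n + 1L
      vval <- if (side == 1L) zd$v0 else zd$v1
      idx <- NU + seq_len(n) + (j - 1L) * n + (z - 1L) * n * (n + 1L)
      p <- zone_cube_point(zd, uc, rep(vval, n))
      pos <- rbind(pos, p / sqrt(rowSums(p^2)))
      fid <- c(fid, idx)
      sgn <- c(sgn, rep(if (side == 1L) -1L else 1L, n))
      cell <- c(cell, cell_index(seq_len(n), rep(if (side == 1L) 1L else n, n), z, n))
    }
  }
  sym <- abs(pos[, 2]) < 1e-9
  key <- paste(round(pos[, 1], 9), round(pos[, 2], 9), round(pos[, 3], 9))
  grp <- split(seq_along(key)[!sym], key[!sym])
  sizes <- lengths(grp)
  if (any(sizes != 2L)) abort("internal error: unmatched zone-interface faces")
  A <- vapply(grp, `[`, 0L, 1L)
  B <- vapply(grp, `[`, 0L, 2L)
  list(
    pA = fid[A], pB = fid[B], sA = as.numeric(sgn[A]), sB = as.numeric(sgn[B]),
    cellA = cell[A], cellB = cell[B], sym = fid[sym], NU = NU
  )
}

## Metric-dependent quantities for the current semi-axes: per-cell area
## elements, flux-coefficient arrays for the Laplace-Beltrami operator,
## contravariant projection vectors for advective fluxes, face positions on
## the spheroid, and the stable-diffusion time-step scale.
mesh_geom <- function(mesh) {
  A <- mesh$a; B <- mesh$b
  n <- mesh$n
  met <- function(loc) {
    cb <- loc$combos
    E <- B^2 * cb$E1 + A^2 * cb$E3
    G <- B^2 * cb$G1 + A^2 * cb$G3
    FF <- B^2 * cb$F1 + A^2 * cb$F3
    sg <- sqrt(pmax(E * G - FF^2, 0))
    list(E = E, G = G, FF = FF, sg = sg)
  }
  mc <- met(mesh$cells)
  mu <- met(mesh$uf)
  mv <- met(mesh$vf)
  area <- mc$sg * mesh$cells$hu * mesh$cells$hv
  spheroid_xyz <- function(s) cbind(B * s[, 1], B * s[, 2], A * s[, 3])
  ru_u <- cbind(B * mesh$uf$su[, 1], B * mesh$uf$su[, 2], A * mesh$uf$su[, 3])
  rv_u <- cbind(B * mesh$uf$sv[, 1], B * mesh$uf$sv[, 2], A * mesh$uf$sv[, 3])
  ru_v <- cbind(B * mesh$vf$su[, 1], B * mesh$vf$su[, 2], A * mesh$vf$su[, 3])
  rv_v <- cbind(B * mesh$vf$sv[, 1], B * mesh$vf$sv[, 2], A * mesh$vf$sv[, 3])
  ## diffusive flux coefficients (flux through a u-face:
  ## Cu1 * (f_R - f_L) + Cu2 * cross-difference)
  Cu1 <- mu$G / mu$sg * mesh$uf$hv / mesh$uf$hu
  Cu2 <- -mu$FF / mu$sg / 4
  Cv1 <- mv$E / mv$sg * mesh$vf$hu / mesh$vf$hv
  Cv2 <- -mv$FF / mv$sg / 4
  ## advective flux projectors: flux q = W . adv  (W Cartesian face velocity)
  advu <- (mu$G * ru_u - mu$FF * rv_u) / mu$sg * mesh$uf$hv
  advv <- (mv$E * rv_v - mv$FF * ru_v) / mv$sg * mesh$vf$hu
  h_min <- min(min(sqrt(mc$E) * mesh$cells$hu), min(sqrt(mc$G) * mesh$cells$hv))
  ## Gershgorin-type bound for the diffusion operator spectral radius / D
  Cu1a <- array(Cu1, c(n + 1L, n, 8L))
  Cv1a <- array(Cv1, c(n, n + 1L, 8L))
  rowsum_c <- array(Cu1a[1:n, , , drop = FALSE] + Cu1a[2:(n + 1L), , , drop = FALSE] +
                    Cv1a[, 1:n, , drop = FALSE] + Cv1a[, 2:(n + 1L), , drop = FALSE],
                    c(mesh$N))
  lam_scale <- max(rowsum_c / area)
  list(
    area = area, invA = 1 / area, sqrtg = mc$sg,
    Cu1 = Cu1, Cu2 = Cu2, Cv1 = Cv1, Cv2 = Cv2,
    advu = advu, advv = advv,
    uf_xyz = spheroid_xyz(mesh$uf$s), vf_xyz = spheroid_xyz(mesh$vf$s),
    cell_xyz = spheroid_xyz(mesh$cells$s),
    h_min = h_min, lam_scale = lam_scale
  )
}

#' Rescale a mesh onto new semi-axes
#'
#' Returns the mesh with identical logical structure (same cells, same angular
#' coordinates) on a spheroid with new semi-axes; field vectors carry over
#' index-wise. This realizes the coordinate-preserving growth map; the
#' associated area-dilution factor of transported concentrations is applied by
#' the integrator, not here.
#'
#' @param mesh A [cubed_spheroid()] mesh.
#' @param L_AP,L_DV New semi-axes in um.
#' @return A `cubed_spheroid` with updated geometry.
#' @export
remesh_to <- function(mesh, L_AP, L_DV) {
  if (L_AP == mesh$a && L_DV == mesh$b) return(mesh)
  mesh$a <- L_AP
  mesh$b <- L_DV
  mesh$geom <- mesh_geom(mesh)
  mesh
}

#' Total spheroid surface area of a mesh
#'
#' Sum of the per-cell area elements over the represented half, doubled for
#' the full closed surface.
#'
#' @param mesh A [cubed_spheroid()] mesh.
#' @return Area in um^2.
#' @export
surface_area <- function(mesh) {
  2 * sum(mesh$geom$area)
}

#' Mesh cells as a tibble
#'
#' One row per cell with zone, logical indices, spheroid coordinates (um),
#' angular coordinates and area element, convenient for plotting and tidy
#' post-processing.
#'
#' @param mesh A [cubed_spheroid()] mesh.
#' @return A tibble with `8 n^2` rows.
#' @export
mesh_nodes <- function(mesh) {
  n <- mesh$n
  xyz <- mesh$geom$cell_xyz
  tibble::tibble(
    cell = seq_len(mesh$N),
    zone = mesh$cells$zone,
    i = rep(rep(seq_len(n), times = n), times = 8L),
    j = rep(rep(seq_len(n), each = n), times = 8L),
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    eta = mesh$cells$eta,
    theta = mesh$cells$theta,
    area = mesh$geom$area
  )
}

## Interpolate a cell field at arbitrary surface points given by angular
## coordinates (eta from the posterior pole, theta = 0 dorsal). Points with
## theta outside [0, pi] are folded through the y = 0 mirror.
mesh_interp <- function(mesh, eta, theta, field) {
  s <- cbind(sin(eta) * cos(theta), abs(sin(eta) * sin(theta)), cos(eta))
  loc <- locate_unit_points(s, mesh$n)
  wu <- linear2(loc$fu, mesh$n)
  wv <- linear2(loc$fv, mesh$n)
  out <- numeric(length(eta))
  for (dv in 0:1) for (du in 0:1) {
    idx <- cell_index(wu$i0 + du, wv$i0 + dv, loc$zone, mesh$n)
    out <- out + wu$w[, du + 1L] * wv$w[, dv + 1L] * field[idx]
  }
  out
}

## Fill the padded (n+2) x (n+2) x 8 array for a scalar cell field.
padded_field <- function(mesh, field, halo_values = NULL) {
  h <- mesh$halo
  P <- numeric(h$np * h$np * 8L)
  P[h$pad_int] <- field
  if (is.null(halo_values)) halo_values <- as.numeric(h$H %*% field)
  P[h$pad_halo] <- halo_values
  dim(P) <- c(h$np, h$np, 8L)
  P
}

## Ghost values for a Cartesian vector field (m x 3): interpolation plus the
## y-mirror sign flip on the y-component for ghosts reflected through y = 0.
halo_vector <- function(mesh, vfield) {
  h <- mesh$halo
  out <- cbind(as.numeric(h$H %*% vfield[, 1]),
               as.numeric(h$H %*% vfield[, 2]),
               as.numeric(h$H %*% vfield[, 3]))
  out[h$mirror, 2] <- -out[h$mirror, 2]
  out
}
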