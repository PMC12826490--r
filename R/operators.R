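## Discrete surface operators on the cubed-spheroid mesh. Both the diffusion
## and the transport operator are written in flux form: per-zone fluxes are
## computed from ghost-padded fields, every zone-interface face is given a
## single shared value (the average of the two one-sided diffusive estimates,
## or the upwind flux evaluated with the paired interior cells), and faces on
## the y = 0 symmetry plane carry no flux. The surface integral of either
## operator over the closed surface is therefore zero to rounding, and pure
## diffusion / pure transport conserve mass exactly. The flux loops run in
## compiled code (src/kernels.cpp).

#' Discrete Laplace-Beltrami operator
#'
#' Second-order finite-volume Laplace-Beltrami operator of the spheroid
#' surface at the mesh's current semi-axes. Constants map to (numerical) zero
#' and the operator conserves mass exactly: the surface integral of the output
#' vanishes to rounding because interface fluxes are single-valued.
#'
#' @param mesh A [cubed_spheroid()] mesh.
#' @param field Numeric vector of cell values (length `8 n^2`).
#' @return Numeric vector, the discrete Laplacian in units of `field / um^2`.
#' @export
laplace_beltrami <- function(mesh, field) {
  if (length(field) != mesh$N) abort("field length does not match the mesh")
  P <- padded_field(mesh, field)
  g <- mesh$geom
  p <- mesh$pairs
  diff_flux_div_cpp(P, mesh$n, g$Cu1, g$Cu2, g$Cv1, g$Cv2, g$invA,
                    p$pA, p$pB, p$sA, p$sB, p$sym)
}

## Precompute the state-independent pieces of upwind advection for face flux
## velocities Qall (concatenated u/v face arrays of q = w-dot-n times face
## length): positive/negative parts and the single-valued interface outflow.
prepare_advection <- function(mesh, Qall) {
  p <- mesh$pairs
  list(Qp = pmax(Qall, 0), Qn = pmin(Qall, 0),
       qo = (Qall[p$pA] * p$sA - Qall[p$pB] * p$sB) / 2)
}

## Upwind advective flux divergence of the columns of Xmat (N x k) given
## prepared face velocities; interface fluxes use the paired interior cells.
advection_apply <- function(mesh, prep, Xmat) {
  if (is.null(dim(Xmat))) Xmat <- matrix(Xmat, ncol = 1L)
  k <- ncol(Xmat)
  h <- mesh$halo
  np <- h$np
  halo <- as.matrix(h$H %*% Xmat)
  P <- numeric(np * np * 8L * k)
  off <- rep((seq_len(k) - 1L) * np * np * 8L, each = mesh$N)
  P[rep(h$pad_int, k) + off] <- as.numeric(Xmat)
  offh <- rep((seq_len(k) - 1L) * np * np * 8L, each = length(h$pad_halo))
  P[rep(h$pad_halo, k) + offh] <- as.numeric(halo)
  p <- mesh$pairs
  adv_flux_div_cpp(P, mesh$n, k, prep$Qp, prep$Qn, prep$qo,
                   p$pA, p$pB, p$sA, p$sB, p$cellA, p$cellB, p$sym,
                   Xmat, mesh$geom$invA)
}

advective_divergence <- function(mesh, Qall, field) {
  as.numeric(advection_apply(mesh, prepare_advection(mesh, Qall), field))
}

## Face flux velocities q from a Cartesian velocity defined per cell
## (averaged to faces through the ghost machinery).
face_flux_velocity <- function(mesh, vfield) {
  n <- mesh$n
  g <- mesh$geom
  hv <- halo_vector(mesh, vfield)
  q_comp <- function(k) {
    P <- padded_field(mesh, vfield[, k], halo_values = hv[, k])
    Wu <- (P[1:(n + 1L), 2:(n + 1L), , drop = FALSE] +
           P[2:(n + 2L), 2:(n + 1L), , drop = FALSE]) / 2
    Wv <- (P[2:(n + 1L), 1:(n + 1L), , drop = FALSE] +
           P[2:(n + 1L), 2:(n + 2L), , drop = FALSE]) / 2
    list(u = as.numeric(Wu), v = as.numeric(Wv))
  }
  c1 <- q_comp(1); c2 <- q_comp(2); c3 <- q_comp(3)
  Qu <- c1$u * g$advu[, 1] + c2$u * g$advu[, 2] + c3$u * g$advu[, 3]
  Qv <- c1$v * g$advv[, 1] + c2$v * g$advv[, 2] + c3$v * g$advv[, 3]
  c(Qu, Qv)
}

## Face flux velocities from an analytic Cartesian velocity function
## f(xyz_matrix) -> m x 3, evaluated directly at face midpoints.
face_flux_velocity_fun <- function(mesh, velocity_fun) {
  g <- mesh$geom
  Wu <- velocity_fun(g$uf_xyz)
  Wv <- velocity_fun(g$vf_xyz)
  c(rowSums(Wu * g$advu), rowSums(Wv * g$advv))
}

#' Conservative surface transport operator
#'
#' Discrete divergence of `vector_field * field` on the spheroid surface, in
#' conservative (finite-volume, upwind) form: the surface integral of the
#' output over the closed surface is zero to rounding, so transport conserves
#' mass exactly. The velocity must be tangent to the surface.
#'
#' @param mesh A [cubed_spheroid()] mesh.
#' @param vector_field Numeric matrix (`8 n^2` x 3) of Cartesian tangent
#'   velocities at cell centers (um/hr).
#' @param field Numeric vector of cell values.
#' @param tangency_tol Maximum allowed `|u . n| / |u|`.
#' @return Numeric vector, the discrete `div(vector_field * field)`.
#' @export
surface_divergence_transport <- function(mesh, vector_field, field,
                                         tangency_tol = 1e-8) {
  if (length(field) != mesh$N) abort("field length does not match the mesh")
  if (!is.matrix(vector_field) || nrow(vector_field) != mesh$N || ncol(vector_field) != 3L) {
    abort("vector_field must be an N x 3 matrix of Cartesian velocities")
  }
  xyz <- mesh$geom$cell_xyz
  nrm <- cbind(xyz[, 1] / mesh$b^2, xyz[, 2] / mesh$b^2, xyz[, 3] / mesh$a^2)
  nrm <- nrm / sqrt(rowSums(nrm^2))
  speed <- sqrt(rowSums(vector_field^2))
  dt <- abs(rowSums(vector_field * nrm)) / pmax(speed, 1e-300)
  if (max(dt[speed > 0], 0) > tangency_tol) {
    abort("vector_field is not tangent to the surface within tolerance")
  }
  advective_divergence(mesh, face_flux_velocity(mesh, vector_field), field)
}

#' Surface integral of a field
#'
#' Sum of value times area element over the represented half, doubled for the
#' full closed surface.
#'
#' @param mesh A [cubed_spheroid()] mesh.
#' @param field Numeric vector of cell values.
#' @return The integral (units of `field` times um^2).
#' @export
integrate_surface <- function(mesh, field) {
  if (length(field) != mesh$N) abort("field length does not match the mesh")
  2 * sum(field * mesh$geom$area)
}
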