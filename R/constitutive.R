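#' Algebraic constitutive relations of the TEVP blood model
#'
#' These functions evaluate, pointwise in state, every algebraic ingredient of
#' the model: the linear Phan-Thien--Tanner (PTT) stress function, the
#' thixotropic plastic viscosity and relaxation time, the stress-controlled
#' flow parameter, the structure-kinetics rate, the viscoplastic part of the
#' deformation-rate tensor, and the assembled stress-rate right-hand side for
#' homogeneous flows.
#'
#' @name constitutive
NULL

#' Linear PTT stress function
#'
#' `f = 1 + eps_ptt * tr(tau) / G`. Equal to 1 when `eps_ptt = 0` or the
#' stress is traceless; it bounds the extensional viscosity at high strain
#' rates.
#'
#' @param tau stress `sym_tensor` (Pa).
#' @param p [tevp_parameters()].
#' @return dimensionless scalar.
#' @export
ptt_factor <- function(tau, p) {
  1 + p$eps_ptt * tensor_trace(tau) / p$G
}

#' Thixotropic plastic viscosity and relaxation time
#'
#' `eta_t(lambda) = eta0 * lambda^m1` and `chi(lambda) = chi0 * lambda^m1`
#' with `chi0 = eta0 / G`. `lambda = 1` is the fully structured state (jammed
#' rouleaux); the viscosity decays as the microstructure is destroyed.
#'
#' @param lam structure parameter in `[0, 1]`.
#' @param p [tevp_parameters()].
#' @return Pa s (`thixotropic_viscosity`) or s (`relaxation_time`).
#' @export
thixotropic_viscosity <- function(lam, p) {
  if (any(lam < 0 | lam > 1)) stop("'lam' must lie in [0, 1]")
  p$eta0 * lam^p$m1
}

#' @rdname thixotropic_viscosity
#' @export
relaxation_time <- function(lam, p) {
  if (any(lam < 0 | lam > 1)) stop("'lam' must lie in [0, 1]")
  p$chi0 * lam^p$m1
}

#' Stress-controlled flow parameter
#'
#' `phi = max(0, sigma_eff - tau_y)`: the stress excess over yield driving
#' both the flow-induced rebuild and the breakdown of rouleaux. Zero at and
#' below the yield surface.
#'
#' @param sigma_eff effective stress (Pa), non-negative.
#' @param p [tevp_parameters()].
#' @return Pa, non-negative.
#' @export
flow_parameter <- function(sigma_eff, p) {
  stopifnot(all(sigma_eff >= 0))
  pmax(0, sigma_eff - p$tau_y)
}

#' Structure-parameter kinetics
#'
#' `dlambda/dt = (k1 + k2 phi^n1) (1 - lambda) - k3 phi^n2 lambda^n3`.
#' The first (rebuild) term collects Brownian collisions of individual RBCs
#' (`k1`) and flow-induced aggregation (`k2 phi^n1`), both proportional to the
#' unstructured fraction `1 - lambda`; the second (breakdown) term grows with
#' the stress excess and the structured fraction.
#'
#' @param lam structure parameter in `[0, 1]`.
#' @param sigma_eff effective stress (Pa).
#' @param p [tevp_parameters()].
#' @return 1/s.
#' @export
structure_rate <- function(lam, sigma_eff, p) {
  if (any(lam < 0 | lam > 1)) stop("'lam' must lie in [0, 1]")
  phi <- flow_parameter(sigma_eff, p)
  (p$k1 + p$k2 * phi^p$n1) * (1 - lam) - p$k3 * phi^p$n2 * lam^p$n3
}

#' Steady structure parameter at fixed stress excess
#'
#' Solves the algebraic balance rebuild = breakdown for `lambda` at a fixed
#' flow parameter `phi`, by bisection. The balance has a unique root in
#' `(0, 1]`; `phi = 0` gives `lambda = 1`.
#'
#' @param phi flow parameter (Pa), non-negative scalar.
#' @param p [tevp_parameters()].
#' @param tol bisection tolerance on `lambda`.
#' @return scalar in `(0, 1]`.
#' @export
structure_fixed_point <- function(phi, p, tol = 1e-12) {
  stopifnot(phi >= 0)
  if (phi == 0) return(1)
  g <- function(l) (p$k1 + p$k2 * phi^p$n1) * (1 - l) -
    p$k3 * phi^p$n2 * l^p$n3
  # g(0) = rebuild > 0, g(1) = -breakdown < 0: bracketed
  lo <- 0; hi <- 1
  while (hi - lo > tol) {
    mid <- (lo + hi) / 2
    if (g(mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Viscoplastic part of the deformation-rate tensor
#'
#' `Dvp = f[tr tau] * max(0, (sigma_eff - tau_y) / (2 eta_t sigma_eff)) * tau`.
#' Identically zero at and below the yield surface (von Mises criterion);
#' above it, proportional to the stress tensor, so component ratios equal
#' stress-component ratios. The scalar multiplier is evaluated without ever
#' forming `0/0` at `sigma_eff = 0`.
#'
#' @param tau stress `sym_tensor` (Pa).
#' @param lam structure parameter in `(0, 1]`.
#' @param p [tevp_parameters()].
#' @param eta_floor lower guard on the thixotropic viscosity (Pa s) protecting
#'   the multiplier as `lambda -> 0`; the dynamics themselves keep
#'   `lambda > 0`.
#' @return `sym_tensor`, 1/s.
#' @export
viscoplastic_deformation <- function(tau, lam, p, eta_floor = 1e-12) {
  m <- vp_multiplier(tau, lam, p, eta_floor)
  sym_tensor(xx = m * tau[1], yy = m * tau[2], zz = m * tau[3],
             xy = m * tau[4], xz = m * tau[5], yz = m * tau[6])
}

# scalar multiplier of tau in Dvp: f * (sigma_eff - tau_y) / (2 eta_t sigma_eff)
# clamped to 0 at/below yield (and hence never evaluated at sigma_eff = 0,
# since tau_y > 0)
vp_multiplier <- function(tau, lam, p, eta_floor = 1e-12) {
  se <- effective_stress(tau)
  if (se <= p$tau_y) return(0)
  etat <- max(p$eta0 * max(lam, 0)^p$m1, eta_floor)
  ptt_factor(tau, p) * (se - p$tau_y) / (2 * etat * se)
}

#' Material state of a homogeneous TEVP flow
#'
#' Bundles time, the viscoelastic stress tensor and the structure parameter.
#' The default is the rest state: zero stress and a fully structured sample.
#'
#' @param t time (s).
#' @param tau stress `sym_tensor` (Pa).
#' @param lam structure parameter in `[0, 1]`.
#' @return object of class `material_state`.
#' @export
material_state <- function(t = 0, tau = sym_tensor(), lam = 1) {
  stopifnot(inherits(tau, "sym_tensor") || (is.numeric(tau) &&
                                              length(tau) == 6L))
  if (lam < 0 || lam > 1) stop("'lam' must lie in [0, 1]")
  structure(list(t = t, tau = sym_tensor(tau[1], tau[2], tau[3],
                                         tau[4], tau[5], tau[6]),
                 lam = lam),
            class = "material_state")
}

#' @export
print.material_state <- function(x, ...) {
  cat(sprintf("material_state at t = %g s, lambda = %.6g\n", x$t, x$lam))
  cat("  tau (Pa):", paste(sprintf("%s=%.4g", names(x$tau), x$tau),
                           collapse = " "), "\n")
  invisible(x)
}

#' Stress-rate right-hand side for homogeneous flow
#'
#' For a spatially homogeneous flow with velocity gradient `L`
#' (`L[i, j] = du_i/dx_j`), the upper-convected elastic relation
#' `De = (1/2G) * (dtau/dt - L tau - tau L^T)` combined with the additive
#' split `D = De + Dvp` gives
#' `dtau/dt = L tau + tau L^T + 2 G (D - Dvp)`, `D = (L + L^T)/2`.
#' At zero stress this reduces to the neo-Hookean rate `2 G D`.
#'
#' @param state a [material_state()].
#' @param L 3x3 velocity-gradient matrix (1/s).
#' @param p [tevp_parameters()].
#' @return `sym_tensor`, Pa/s.
#' @export
stress_rate <- function(state, L, p) {
  taum <- as_tensor_matrix(state$tau)
  D <- (L + t(L)) / 2
  m <- vp_multiplier(state$tau, state$lam, p)
  dtau <- L %*% taum + taum %*% t(L) + 2 * p$G * (D - m * taum)
  as_sym_tensor(dtau)
}

# Fast internal right-hand side on the packed 7-state
# y = (txx, tyy, tzz, txy, txz, tyz, lam), with L a 3x3 matrix.
# Scalar algebra only; this is the hot path of the integrator.
tevp_rhs <- function(y, L, p, eta_floor = 1e-12) {
  y <- unname(y)
  txx <- y[1]; tyy <- y[2]; tzz <- y[3]
  txy <- y[4]; txz <- y[5]; tyz <- y[6]
  lam <- y[7]
  trt <- txx + tyy + tzz
  tr3 <- trt / 3
  se <- sqrt(((txx - tr3)^2 + (tyy - tr3)^2 + (tzz - tr3)^2) / 2 +
               txy^2 + txz^2 + tyz^2)
  phi <- se - p$tau_y
  if (phi > 0) {
    etat <- max(p$eta0 * max(lam, 0)^p$m1, eta_floor)
    m <- (1 + p$eps_ptt * trt / p$G) * phi / (2 * etat * se)
    dlam <- (p$k1 + p$k2 * phi^p$n1) * (1 - lam) -
      p$k3 * phi^p$n2 * max(lam, 0)^p$n3
  } else {
    m <- 0
    dlam <- p$k1 * (1 - lam)
  }
  L11 <- L[1, 1]; L12 <- L[1, 2]; L13 <- L[1, 3]
  L21 <- L[2, 1]; L22 <- L[2, 2]; L23 <- L[2, 3]
  L31 <- L[3, 1]; L32 <- L[3, 2]; L33 <- L[3, 3]
  twoG <- 2 * p$G
  # A = L %*% tau; dtau = A + t(A) + 2G(D - m*tau)
  A11 <- L11 * txx + L12 * txy + L13 * txz
  A12 <- L11 * txy + L12 * tyy + L13 * tyz
  A13 <- L11 * txz + L12 * tyz + L13 * tzz
  A21 <- L21 * txx + L22 * txy + L23 * txz
  A22 <- L21 * txy + L22 * tyy + L23 * tyz
  A23 <- L21 * txz + L22 * tyz + L23 * tzz
  A31 <- L31 * txx + L32 * txy + L33 * txz
  A32 <- L31 * txy + L32 * tyy + L33 * tyz
  A33 <- L31 * txz + L32 * tyz + L33 * tzz
  c(2 * A11 + twoG * (L11 - m * txx),
    2 * A22 + twoG * (L22 - m * tyy),
    2 * A33 + twoG * (L33 - m * tzz),
    A12 + A21 + twoG * ((L12 + L21) / 2 - m * txy),
    A13 + A31 + twoG * ((L13 + L31) / 2 - m * txz),
    A23 + A32 + twoG * ((L23 + L32) / 2 - m * tyz),
    dlam)
}
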