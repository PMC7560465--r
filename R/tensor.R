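#' Symmetric second-order tensors
#'
#' Stress and deformation-rate tensors are stored as named numeric vectors of
#' the six independent components `xx, yy, zz, xy, xz, yz` (stress in Pa,
#' rates in 1/s). `sym_tensor()` builds one, `as_tensor_matrix()` expands it
#' to a full 3x3 matrix and `as_sym_tensor()` collapses a (numerically)
#' symmetric matrix back to six components.
#'
#' @param xx,yy,zz,xy,xz,yz tensor components.
#' @return `sym_tensor()` and `as_sym_tensor()` return a named length-6
#'   numeric vector of class `sym_tensor`; `as_tensor_matrix()` a 3x3 matrix.
#' @export
#' @examples
#' s <- sym_tensor(xy = 1.5)
#' effective_stress(s)  # pure shear: equals the shear component
sym_tensor <- function(xx = 0, yy = 0, zz = 0, xy = 0, xz = 0, yz = 0) {
  v <- c(xx = unname(xx), yy = unname(yy), zz = unname(zz),
         xy = unname(xy), xz = unname(xz), yz = unname(yz))
  stopifnot(is.numeric(v), length(v) == 6L, all(is.finite(v)))
  structure(v, class = "sym_tensor")
}

#' @rdname sym_tensor
#' @param z a `sym_tensor` (or bare length-6 vector in the same order).
#' @export
as_tensor_matrix <- function(z) {
  z <- unclass(z)
  matrix(c(z[1], z[4], z[5],
           z[4], z[2], z[6],
           z[5], z[6], z[3]), 3L, 3L)
}

#' @rdname sym_tensor
#' @param m a numerically symmetric 3x3 matrix.
#' @param tol asymmetry tolerance relative to the largest entry.
#' @export
as_sym_tensor <- function(m, tol = 1e-8) {
  stopifnot(is.matrix(m), all(dim(m) == 3L))
  asym <- max(abs(m - t(m)))
  if (asym > tol * max(1, max(abs(m))))
    stop("matrix is not symmetric to tolerance")
  sym_tensor(xx = m[1, 1], yy = m[2, 2], zz = m[3, 3],
             xy = (m[1, 2] + m[2, 1]) / 2,
             xz = (m[1, 3] + m[3, 1]) / 2,
             yz = (m[2, 3] + m[3, 2]) / 2)
}

#' Trace and deviatoric part
#'
#' The deviatoric part of a tensor `z` is `z - (tr z / 3) I`; it is traceless
#' and the operation is idempotent.
#'
#' @param z a `sym_tensor`.
#' @return `tensor_trace()` a scalar; `deviatoric()` a traceless `sym_tensor`.
#' @export
tensor_trace <- function(z) {
  z <- unname(unclass(z))
  z[1] + z[2] + z[3]
}

#' @rdname tensor_trace
#' @export
deviatoric <- function(z) {
  tr3 <- tensor_trace(z) / 3
  z <- unclass(z)
  sym_tensor(xx = z[1] - tr3, yy = z[2] - tr3, zz = z[3] - tr3,
             xy = z[4], xz = z[5], yz = z[6])
}

#' Double contraction of two symmetric tensors
#'
#' `a : b = sum_ij a_ij b_ij`, accounting for the doubled off-diagonal terms.
#'
#' @param a,b `sym_tensor` objects.
#' @return scalar.
#' @export
double_dot <- function(a, b) {
  a <- unclass(a); b <- unclass(b)
  sum(a[1:3] * b[1:3]) + 2 * sum(a[4:6] * b[4:6])
}

#' Effective (von Mises) stress
#'
#' `sigma_eff = sqrt((tauD : tauD) / 2)` where `tauD` is the deviatoric part
#' of the stress. In pure shear it equals the shear component; it is invariant
#' under addition of any isotropic tensor.
#'
#' @param tau stress `sym_tensor` (Pa).
#' @return scalar, Pa.
#' @export
effective_stress <- function(tau) {
  d <- deviatoric(tau)
  sqrt(double_dot(d, d) / 2)
}
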