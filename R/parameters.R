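#' TEVP model parameters
#'
#' Construct and validate the set of eleven material constants of the
#' thixotropic elasto-visco-plastic (TEVP) blood model, plus the derived
#' relaxation-time scale `chi0 = eta0 / G`.
#'
#' The parameters are, in strict SI units:
#' \describe{
#'   \item{G}{elastic modulus (Pa).}
#'   \item{eta0}{plastic (structural) viscosity at full structure, Pa s;
#'     `eta_t(lambda) = eta0 * lambda^m1`.}
#'   \item{tau_y}{yield stress (Pa) entering the von Mises criterion.}
#'   \item{eps_ptt}{linear Phan-Thien--Tanner mobility (dimensionless);
#'     bounds the extensional viscosity at high strain rates.}
#'   \item{k1}{Brownian structure-rebuild rate (1/s).}
#'   \item{k2}{flow-induced rebuild coefficient (acts on `phi^n1`).}
#'   \item{k3}{structure-breakdown coefficient (acts on `phi^n2`).}
#'   \item{n1, n2, n3, m1}{positive dimensionless exponents; `n1`, `n2`
#'     shape the dependence of the kinetics on the flow parameter `phi`,
#'     `n3` the breakdown dependence on `lambda`, and `m1` the nonlinearity
#'     of the thixotropic viscosity.}
#' }
#'
#' For sets obtained by fitting rheometric data the breakdown should dominate
#' the flow-induced rebuild (`k3 > k2`) and `n1 < n2`; user-supplied sets that
#' violate this raise a warning, not an error.
#'
#' @param G,eta0,tau_y,eps_ptt,k1,k2,k3,n1,n2,n3,m1 numeric scalars, see
#'   Details.
#' @return An object of class `tevp_parameters` (a named list including the
#'   derived `chi0`).
#' @seealso [tevp_preset()] for the two bundled donor parameter sets.
#' @export
#' @examples
#' p <- tevp_preset("mcmillan1987_subject")
#' p$chi0  # eta0 / G, about 31.4 ms
tevp_parameters <- function(G, eta0, tau_y, eps_ptt, k1, k2, k3,
                            n1, n2, n3, m1) {
  p <- list(G = G, eta0 = eta0, tau_y = tau_y, eps_ptt = eps_ptt,
            k1 = k1, k2 = k2, k3 = k3, n1 = n1, n2 = n2, n3 = n3, m1 = m1)
  for (nm in names(p)) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("parameter '", nm, "' must be a finite numeric scalar")
  }
  strict_pos <- c("G", "eta0", "tau_y", "k1", "k2", "k3",
                  "n1", "n2", "n3", "m1")
  for (nm in strict_pos)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  if (eps_ptt < 0) stop("'eps_ptt' must be non-negative")
  if (n1 >= n2)
    warning("fitted TEVP sets are expected to satisfy n1 < n2")
  if (k3 <= k2)
    warning("fitted TEVP sets are expected to satisfy k3 > k2 ",
            "(breakdown dominating flow-induced rebuild)")
  p$chi0 <- eta0 / G
  structure(p, class = "tevp_parameters")
}

#' Bundled TEVP parameter presets
#'
#' Two fitted parameter sets for healthy human blood at 45% hematocrit:
#' `"mcmillan1987_subject"` (fitted on steady shear plus intermittent
#' rectangular shear steps) and `"armstrong2018_donor1"` (fitted on steady
#' shear, triangular ramp and oscillatory data).
#'
#' @param name preset name.
#' @return A [tevp_parameters()] object.
#' @export
tevp_preset <- function(name = c("mcmillan1987_subject",
                                 "armstrong2018_donor1")) {
  name <- match.arg(name)
  switch(name,
    mcmillan1987_subject = tevp_parameters(
      G = 0.382, eta0 = 0.012, tau_y = 0.0035, eps_ptt = 0.001,
      k1 = 0.0918, k2 = 7.249, k3 = 6974.9,
      n1 = 3.03, n2 = 4.068, n3 = 3.03, m1 = 0.701),
    armstrong2018_donor1 = tevp_parameters(
      G = 0.15, eta0 = 0.035, tau_y = 0.006, eps_ptt = 0.001,
      k1 = 0.092, k2 = 0.45, k3 = 1720,
      n1 = 1.67, n2 = 3.41, n3 = 1.67, m1 = 0.91))
}

#' @export
print.tevp_parameters <- function(x, ...) {
  cat("TEVP model parameters\n")
  cat(sprintf("  G       %10.4g Pa    (elastic modulus)\n", x$G))
  cat(sprintf("  eta0    %10.4g Pa.s  (structural viscosity)\n", x$eta0))
  cat(sprintf("  tau_y   %10.4g Pa    (yield stress)\n", x$tau_y))
  cat(sprintf("  eps_ptt %10.4g       (PTT mobility)\n", x$eps_ptt))
  cat(sprintf("  k1      %10.4g 1/s   (Brownian rebuild)\n", x$k1))
  cat(sprintf("  k2      %10.4g       (flow-induced rebuild)\n", x$k2))
  cat(sprintf("  k3      %10.4g       (breakdown)\n", x$k3))
  cat(sprintf("  n1, n2, n3, m1: %.4g, %.4g, %.4g, %.4g\n",
              x$n1, x$n2, x$n3, x$m1))
  cat(sprintf("  chi0    %10.4g s     (relaxation time eta0/G, derived)\n",
              x$chi0))
  invisible(x)
}

#' Read / write TEVP parameters as flat key-value config
#'
#' Serialisation uses the same field names as [tevp_parameters()]; the derived
#' `chi0` is written for reference but recomputed (never trusted) on reading.
#' The format is chosen from the file extension (`.yaml`/`.yml` or `.json`).
#'
#' @param path file path.
#' @param p a `tevp_parameters` object.
#' @return `read_tevp_parameters()` returns a `tevp_parameters` object;
#'   `write_tevp_parameters()` returns `path` invisibly.
#' @export
read_tevp_parameters <- function(path) {
  x <- read_config(path)
  need <- c("G", "eta0", "tau_y", "eps_ptt", "k1", "k2", "k3",
            "n1", "n2", "n3", "m1")
  miss <- setdiff(need, names(x))
  if (length(miss))
    stop("parameter file is missing fields: ", paste(miss, collapse = ", "))
  do.call(tevp_parameters, lapply(x[need], as.numeric))
}

#' @rdname read_tevp_parameters
#' @export
write_tevp_parameters <- function(p, path) {
  stopifnot(inherits(p, "tevp_parameters"))
  x <- unclass(p)
  write_config(x, path)
  invisible(path)
}

read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path)
  else
    jsonlite::read_json(path, simplifyVector = TRUE)
}

write_config <- function(x, path) {
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::write_yaml(x, path)
  else
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
  invisible(path)
}
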