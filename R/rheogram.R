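#' Rheograms
#'
#' A rheogram is the time-indexed output of [integrate_protocol()]: a
#' data.frame with one row per accepted integration step holding the state
#' (six stress components, Pa, and the structure parameter `lam`) together
#' with derived channels recomputable from the state:
#' \describe{
#'   \item{rate}{imposed shear / elongation rate (1/s).}
#'   \item{sigma_eff}{effective (von Mises) stress (Pa).}
#'   \item{eta_t, chi}{thixotropic viscosity (Pa s) and relaxation time (s).}
#'   \item{f_ptt}{linear PTT factor (dimensionless).}
#'   \item{dvp_xx, dvp_yy, dvp_zz, dvp_xy}{viscoplastic deformation-rate
#'     components (1/s).}
#'   \item{de_xx, de_yy, de_zz, de_xy}{elastic deformation-rate components
#'     `D - Dvp` (1/s).}
#'   \item{strain}{accumulated imposed strain (trapezoidal integral of
#'     `rate`).}
#' }
#' The protocol, parameters, controls and integration method are kept as
#' attributes.
#'
#' @name rheogram
NULL

new_rheogram <- function(time, Y, spec, p, ctrl, method) {
  colnames(Y) <- c("txx", "tyy", "tzz", "txy", "txz", "tyz", "lam")
  df <- data.frame(time = time, Y)
  n <- nrow(df)
  df$rate <- vapply(pmin(df$time, spec$t_end), spec$rate, numeric(1))
  tr <- df$txx + df$tyy + df$tzz
  tr3 <- tr / 3
  df$sigma_eff <- sqrt(((df$txx - tr3)^2 + (df$tyy - tr3)^2 +
                          (df$tzz - tr3)^2) / 2 +
                         df$txy^2 + df$txz^2 + df$tyz^2)
  df$eta_t <- p$eta0 * pmax(df$lam, 0)^p$m1
  df$chi <- p$chi0 * pmax(df$lam, 0)^p$m1
  df$f_ptt <- 1 + p$eps_ptt * tr / p$G
  mult <- ifelse(df$sigma_eff > p$tau_y,
                 df$f_ptt * (df$sigma_eff - p$tau_y) /
                   (2 * pmax(df$eta_t, ctrl$eta_floor) * df$sigma_eff), 0)
  df$dvp_xx <- mult * df$txx
  df$dvp_yy <- mult * df$tyy
  df$dvp_zz <- mult * df$tzz
  df$dvp_xy <- mult * df$txy
  if (spec$mode == "uniaxial") {
    df$de_xx <- df$rate - df$dvp_xx
    df$de_yy <- -df$rate / 2 - df$dvp_yy
    df$de_zz <- -df$rate / 2 - df$dvp_zz
    df$de_xy <- -df$dvp_xy
  } else {
    df$de_xx <- -df$dvp_xx
    df$de_yy <- -df$dvp_yy
    df$de_zz <- -df$dvp_zz
    df$de_xy <- df$rate / 2 - df$dvp_xy
  }
  dtv <- diff(df$time)
  df$strain <- c(0, cumsum(dtv * (utils::head(df$rate, -1) + df$rate[-1]) / 2))
  structure(df, class = c("rheogram", "data.frame"),
            protocol = spec, parameters = p, controls = ctrl,
            method = method)
}

#' @export
print.rheogram <- function(x, ...) {
  spec <- attr(x, "protocol")
  cat(sprintf("rheogram: %d samples over %.4g s (%s protocol, method %s)\n",
              nrow(x), max(x$time), spec$kind, attr(x, "method")))
  cat(sprintf("  final: tau_xy = %.4g Pa, tau_xx = %.4g Pa, lambda = %.4g\n",
              x$txy[nrow(x)], x$txx[nrow(x)], x$lam[nrow(x)]))
  invisible(x)
}

#' Final state of a rheogram
#'
#' @param r a [rheogram].
#' @return a [material_state()].
#' @export
final_state <- function(r) {
  n <- nrow(r)
  material_state(t = r$time[n],
                 tau = sym_tensor(r$txx[n], r$tyy[n], r$tzz[n],
                                  r$txy[n], r$txz[n], r$tyz[n]),
                 lam = r$lam[n])
}

#' Interpolate rheogram channels at given times
#'
#' Linear interpolation of selected channels on the (strictly increasing)
#' time grid of the rheogram.
#'
#' @param r a [rheogram].
#' @param t times (s).
#' @param channels character vector of column names.
#' @return data.frame with `time` and the requested channels.
#' @export
rheogram_at <- function(r, t, channels = c("txy", "txx", "lam")) {
  out <- data.frame(time = t)
  for (ch in channels)
    out[[ch]] <- stats::approx(r$time, r[[ch]], xout = t, rule = 2)$y
  out
}

#' Export a rheogram as tidy CSV plus JSON metadata
#'
#' Writes one row per sample with labelled channels (SI units) and, next to
#' it, a JSON file describing the protocol, the model parameters, the
#' integrator controls and a content hash sufficient to reproduce the run.
#'
#' @param r a [rheogram].
#' @param path CSV output path; metadata goes to `sub(".csv", ".json", path)`
#'   unless `meta_path` is given.
#' @param meta_path optional metadata path.
#' @param overwrite allow overwriting existing files.
#' @return invisibly, the two paths.
#' @export
write_rheogram <- function(r, path, meta_path = NULL, overwrite = FALSE) {
  if (is.null(meta_path))
    meta_path <- sub("\\.csv$", ".json", path)
  for (f in c(path, meta_path))
    if (file.exists(f) && !overwrite)
      stop("refusing to overwrite ", f, " (use overwrite = TRUE)")
  utils::write.csv(as.data.frame(r), path, row.names = FALSE)
  spec <- attr(r, "protocol"); p <- attr(r, "parameters")
  ctrl <- attr(r, "controls")
  meta <- list(protocol = c(list(kind = spec$kind, t_end = spec$t_end,
                                 mode = spec$mode), spec$params),
               parameters = unclass(p),
               controls = unclass(ctrl)[!vapply(unclass(ctrl), is.null,
                                                logical(1))],
               method = attr(r, "method"),
               n_samples = nrow(r),
               run_hash = rheogram_hash(r))
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(path, meta_path))
}

rheogram_hash <- function(r) {
  v <- c(nrow(r), r$time[nrow(r)], r$txy[nrow(r)], r$lam[nrow(r)])
  paste0("h", paste(format(v, digits = 12), collapse = "-"))
}
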