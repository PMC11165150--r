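#' Model variants
#'
#' Three variants share the production-cycle machinery and differ only in how
#' utilities and thresholds are moderated:
#' \describe{
#'   \item{`"cmf"`}{computational model of fatigue: utility
#'     `upsilon * lambda^N_ml * (1 + t)^rho`, threshold `tau * (1 + t)^kappa`,
#'     with `t` the time-on-task in minutes.}
#'   \item{`"gamma1"`}{binned gamma-power motivation: utility
#'     `upsilon * lambda^N_ml * zeta` with one zeta per 2-minute bin;
#'     threshold fixed at `tau`.}
#'   \item{`"gamma2"`}{single-trial gamma-power motivation: as `"gamma1"` but
#'     with one zeta per trial.}
#' }
#' @name model-variants
#' @keywords internal
NULL

MODEL_VARIANTS <- c("cmf", "gamma1", "gamma2")

variant_code <- function(variant) {
  match(match.arg(variant, MODEL_VARIANTS), MODEL_VARIANTS) - 1L
}

#' Construct a validated parameter set for one model variant
#'
#' Bounds follow the published parameter table: `upsilon > 0`,
#' `lambda` in (0, 1], `phi` in (0.01, 0.1), `rho` in (-1, 0) and
#' `kappa` in (-1, 0] (CMF only; both are forced to 0 for the gamma
#' variants). The utility threshold `tau` is fixed at 2.0 by default.
#'
#' @param upsilon initial production utility (unitless, > 0).
#' @param lambda microlapse penalty factor in (0, 1].
#' @param phi conflict-resolution cycle time in seconds, in (0.01, 0.1).
#' @param rho utility time-on-task exponent in (-1, 0); CMF only.
#' @param kappa threshold time-on-task exponent in (-1, 0]; CMF only.
#' @param tau initial utility threshold (> 0), fixed at 2.0 in all reported
#'   fits.
#' @param s logistic utility-noise scale (>= 0); the noise variance is
#'   `pi^2/3 * s^2`. A configuration constant, not a fitted parameter.
#' @param t_microlapse time penalty per microlapse in seconds.
#' @param t_motor motor execution time in seconds, added to every key press.
#' @param mismatch additive utility penalty applied to a state-inappropriate
#'   candidate (responding before the stimulus). Keeps false starts rare, as
#'   in partial matching; not a fitted parameter.
#' @param variant one of `"cmf"`, `"gamma1"`, `"gamma2"`.
#' @return an object of class `model_params`.
#' @examples
#' model_params(upsilon = 3.82, lambda = 0.88, phi = 0.057,
#'              rho = -0.20, kappa = -0.15, variant = "cmf")
#' @export
model_params <- function(upsilon, lambda, phi,
                         rho = 0, kappa = 0,
                         tau = 2.0, s = 0.45,
                         t_microlapse = 0.050, t_motor = 0.100,
                         mismatch = 6.0,
                         variant = c("cmf", "gamma1", "gamma2")) {
  variant <- match.arg(variant)
  chk <- function(ok, what) {
    if (!isTRUE(ok)) stop("model_params: ", what, call. = FALSE)
  }
  chk(is.numeric(upsilon) && length(upsilon) == 1 && upsilon > 0,
      "`upsilon` must be > 0 (bound (0, Inf))")
  chk(is.numeric(lambda) && length(lambda) == 1 && lambda > 0 && lambda <= 1,
      "`lambda` must lie in (0, 1]")
  chk(is.numeric(phi) && length(phi) == 1 && phi > 0.01 && phi < 0.1,
      "`phi` must lie in (0.01, 0.1) seconds")
  chk(is.numeric(tau) && length(tau) == 1 && tau > 0, "`tau` must be > 0")
  chk(is.numeric(s) && length(s) == 1 && s >= 0, "`s` must be >= 0")
  chk(t_microlapse >= 0, "`t_microlapse` must be >= 0")
  chk(t_motor >= 0, "`t_motor` must be >= 0")
  chk(mismatch >= 0, "`mismatch` must be >= 0")
  if (variant == "cmf") {
    chk(is.numeric(rho) && length(rho) == 1 && rho > -1 && rho <= 0,
        "`rho` must lie in (-1, 0]")
    chk(is.numeric(kappa) && length(kappa) == 1 && kappa > -1 && kappa <= 0,
        "`kappa` must lie in (-1, 0]")
  } else {
    if (!missing(rho) && !identical(rho, 0)) {
      stop("model_params: `rho` is not a gamma-variant parameter (must be absent or 0)",
           call. = FALSE)
    }
    if (!missing(kappa) && !identical(kappa, 0)) {
      stop("model_params: `kappa` is not a gamma-variant parameter (must be absent or 0)",
           call. = FALSE)
    }
    rho <- 0
    kappa <- 0
  }
  structure(
    list(upsilon = upsilon, tau = tau, lambda = lambda, phi = phi,
         rho = rho, kappa = kappa, s = s,
         t_microlapse = t_microlapse, t_motor = t_motor,
         mismatch = mismatch, variant = variant),
    class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("PVT production-model parameters (", x$variant, ")\n", sep = "")
  cat(sprintf("  upsilon = %.4g  tau = %.4g  lambda = %.4g  phi = %.4g s\n",
              x$upsilon, x$tau, x$lambda, x$phi))
  if (x$variant == "cmf") {
    cat(sprintf("  rho = %.4g  kappa = %.4g\n", x$rho, x$kappa))
  }
  cat(sprintf("  s = %.3g  t_microlapse = %.3g s  t_motor = %.3g s  mismatch = %.3g\n",
              x$s, x$t_microlapse, x$t_motor, x$mismatch))
  invisible(x)
}

#' Fitting bounds per variant
#'
#' Free parameters are `upsilon`, `lambda`, `phi` for the gamma variants plus
#' `rho`, `kappa` for the CMF; `tau` is fixed at 2.0. `upsilon`'s published
#' bound is (0, Inf); the fitting box caps it at `upsilon_max` so the uniform
#' prior is proper.
#'
#' @param variant model variant.
#' @param upsilon_max finite upper bound used for fitting.
#' @return data.frame with columns `param`, `lower`, `upper`.
#' @export
param_bounds <- function(variant = c("cmf", "gamma1", "gamma2"),
                         upsilon_max = 20) {
  variant <- match.arg(variant)
  b <- data.frame(
    param = c("upsilon", "lambda", "phi"),
    lower = c(1e-6, 1e-6, 0.01 + 1e-6),
    upper = c(upsilon_max, 1, 0.1 - 1e-6),
    stringsAsFactors = FALSE)
  if (variant == "cmf") {
    b <- rbind(b, data.frame(
      param = c("rho", "kappa"),
      lower = c(-1 + 1e-6, -1 + 1e-6),
      upper = c(-1e-6, 0),   # kappa may equal 0, rho may not
      stringsAsFactors = FALSE))
  }
  b
}

#' Running fatigue state of a session
#'
#' Tracks the cumulative microlapse count and the time-on-task; both are
#' non-decreasing within a session.
#'
#' @param n_ml cumulative microlapse count (integer >= 0).
#' @param t_minutes time-on-task in minutes (>= 0).
#' @export
fatigue_state <- function(n_ml = 0L, t_minutes = 0) {
  if (n_ml < 0 || n_ml != round(n_ml)) {
    stop("fatigue_state: `n_ml` must be a non-negative integer", call. = FALSE)
  }
  if (t_minutes < 0) stop("fatigue_state: `t_minutes` must be >= 0", call. = FALSE)
  structure(list(n_ml = as.integer(n_ml), t_minutes = t_minutes),
            class = "fatigue_state")
}

#' @export
print.fatigue_state <- function(x, ...) {
  cat(sprintf("fatigue state: n_ml = %d, t = %.3f min\n", x$n_ml, x$t_minutes))
  invisible(x)
}
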