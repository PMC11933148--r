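## Time-varying elastance ventricle and regularised valve law.

#' Elastance parameter set
#'
#' Parameters of the time-varying elastance chamber,
#' \eqn{P(t) = E(t)\,(V - V_0)} with
#' \eqn{E(t) = E_{min} + (E_{max}-E_{min})\,e(t)} and a double-cosine
#' normalised activation \eqn{e(t)}: a cosine rise over `[0, t_peak]`, a
#' cosine fall over `[t_peak, t_sys]`, and zero in diastole.
#'
#' @param E_max,E_min End-systolic and diastolic elastance (mmHg/mL);
#'   `E_max >= E_min > 0`.
#' @param T Cardiac period (s).
#' @param t_peak Time of peak activation within the cycle (s), `0 < t_peak < T`.
#' @param t_sys End of systole (s); defaults to `min(1.5 * t_peak, T)`.
#' @param V0 Unstressed volume (mL), `V0 >= 0`.
#' @return An object of class `elastance_params`.
#' @export
#' @examples
#' p <- elastance_params(E_max = 12, E_min = 0.22, T = 0.4, t_peak = 0.16)
#' elastance(seq(0, 0.4, by = 0.1), p)
elastance_params <- function(E_max, E_min, T, t_peak,
                             t_sys = min(1.5 * t_peak, T), V0 = 0) {
  if (!(is.finite(E_max) && is.finite(E_min) && E_min > 0 && E_max >= E_min))
    stop("configuration error: need E_max >= E_min > 0")
  if (!(is.finite(T) && T > 0 && t_peak > 0 && t_peak < T))
    stop("configuration error: need 0 < t_peak < T")
  if (!(t_sys > t_peak && t_sys <= T))
    stop("configuration error: need t_peak < t_sys <= T")
  if (!(is.finite(V0) && V0 >= 0))
    stop("configuration error: need V0 >= 0")
  structure(list(E_max = E_max, E_min = E_min, T = T, t_peak = t_peak,
                 t_sys = t_sys, V0 = V0),
            class = "elastance_params")
}

#' Time-varying elastance
#'
#' Evaluates \eqn{E(t)} for an [elastance_params()] set.  The activation is
#' periodic with period `T`, attains exactly `E_max` at `t_peak` (mod `T`) and
#' `E_min` throughout diastole.
#'
#' @param t Time(s) (s), vectorised.
#' @param p An `elastance_params` object.
#' @return Elastance (mmHg/mL), same length as `t`.
#' @export
elastance <- function(t, p) {
  stopifnot(inherits(p, "elastance_params"))
  if (any(!is.finite(t)) || any(t < 0)) stop("t must be finite and >= 0")
  u <- t %% p$T
  e <- numeric(length(u))
  rise <- u < p$t_peak
  fall <- !rise & u < p$t_sys
  e[rise] <- 0.5 * (1 - cos(pi * u[rise] / p$t_peak))
  e[fall] <- 0.5 * (1 + cos(pi * (u[fall] - p$t_peak) / (p$t_sys - p$t_peak)))
  p$E_min + (p$E_max - p$E_min) * e
}

#' Valve parameter set
#'
#' @param R_open Forward (open-valve) resistance (mmHg.s/mL), `> 0`.
#' @param eps Regularisation width (mmHg); `0` gives the ideal diode.
#' @return An object of class `valve_params`.
#' @export
valve_params <- function(R_open, eps = 0) {
  if (!(is.finite(R_open) && R_open > 0))
    stop("configuration error: need R_open > 0")
  if (!(is.finite(eps) && eps >= 0))
    stop("configuration error: need eps >= 0")
  structure(list(R_open = R_open, eps = eps), class = "valve_params")
}

#' Valve flow law
#'
#' Ideal diode `max(dP, 0) / R_open` when `eps = 0`; for `eps > 0` the smooth
#' regularisation \eqn{(dP + \sqrt{dP^2 + \epsilon^2})/(2R)}, which is
#' non-negative, monotone in `dP`, and bounded above by
#' `max(dP, 0)/R_open + eps/R_open`.
#'
#' @param dP Pressure difference across the valve (mmHg), vectorised.
#' @param v A [valve_params()] object.
#' @return Flow (mL/s).
#' @export
valve_flow <- function(dP, v) {
  stopifnot(inherits(v, "valve_params"))
  if (any(!is.finite(dP))) stop("dP must be finite")
  if (v$eps <= 0) pmax(dP, 0) / v$R_open
  else (dP + sqrt(dP^2 + v$eps^2)) / (2 * v$R_open)
}
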