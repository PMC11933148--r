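## Waveform containers and final-cycle analytics.

#' Waveform series
#'
#' A time-stamped signal over cardiac cycles.
#'
#' @param t Sample times (s), strictly increasing.
#' @param y Values, same length as `t`.
#' @param unit Unit string.
#' @param T Cardiac period (s), used to assign a per-sample cycle index;
#'   optional.
#' @return An object of class `waveform`.
#' @export
waveform <- function(t, y, unit = "", T = NULL) {
  if (length(t) != length(y)) stop("t and y must have equal lengths")
  if (any(diff(t) <= 0)) stop("t must be strictly increasing")
  structure(list(t = as.numeric(t), y = as.numeric(y), unit = unit,
                 cycle_index = if (!is.null(T)) floor(t / T) + 1L else NULL,
                 T = T),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("Waveform: %d samples on [%g, %g] s%s, range [%g, %g] %s\n",
              length(x$t), min(x$t), max(x$t),
              if (!is.null(x$T)) sprintf(" (T = %g s)", x$T) else "",
              min(x$y), max(x$y), x$unit))
  invisible(x)
}

#' Time-weighted mean of a waveform over a window
#'
#' Trapezoidal integral over `[window[1], window[2]]` (with interpolated
#' window endpoints) divided by the window length.
#'
#' @param w A [waveform()].
#' @param window Length-2 numeric, within the data support.
#' @return The mean value.
#' @export
cycle_average <- function(w, window = range(w$t)) {
  t0 <- window[1]; t1 <- window[2]
  if (!(is.finite(t0) && is.finite(t1) && t1 > t0))
    stop("argument error: empty averaging window")
  if (t0 < min(w$t) - 1e-9 || t1 > max(w$t) + 1e-9)
    stop("argument error: window outside the data support")
  if (sum(w$t >= t0 & w$t <= t1) < 2)
    stop("argument error: window contains fewer than 2 samples")
  inside <- w$t > t0 & w$t < t1
  tt <- c(t0, w$t[inside], t1)
  yy <- c(approx(w$t, w$y, t0, rule = 2)$y, w$y[inside],
          approx(w$t, w$y, t1, rule = 2)$y)
  pracma::trapz(tt, yy) / (t1 - t0)
}

#' Pulmonary-to-systemic flow ratio
#'
#' `Qp/Qs = Q_shunt / (Q_upper_body + Q_descending_aorta)`: in the parallel
#' Norwood circulation all pulmonary flow passes through the shunt, and
#' systemic flow is the sum of the upper-body and descending-aorta beds.
#'
#' @param q_sh_mean Mean shunt flow (mL/s), `>= 0`.
#' @param q_ub_mean,q_dao_mean Mean upper-body and descending-aorta flows
#'   (mL/s); their sum must be positive.
#' @return The ratio (dimensionless).
#' @export
#' @examples
#' round(qp_qs(10.18, 5.79, 6.04), 2)   # 0.86
qp_qs <- function(q_sh_mean, q_ub_mean, q_dao_mean) {
  qs <- q_ub_mean + q_dao_mean
  if (!is.finite(qs) || qs <= 0)
    stop("domain error: systemic flow (q_ub + q_dao) must be positive")
  q_sh_mean / qs
}

#' Absolute percent difference against a clinical value
#'
#' `100 * |model - clinical| / clinical`, rounded to one decimal place (the
#' reporting convention of the clinical-comparison table).
#'
#' @param model_val Model value.
#' @param clinical_val Clinical reference value, non-zero.
#' @param digits Rounding digits (default 1); `NA` to skip rounding.
#' @return Percent difference.
#' @export
#' @examples
#' percent_difference(22.0, 21)    # 4.8
#' percent_difference(5.79, 5.6)   # 3.4
percent_difference <- function(model_val, clinical_val, digits = 1) {
  if (!is.finite(clinical_val) || clinical_val == 0)
    stop("domain error: clinical value must be non-zero")
  pd <- abs(100 * (model_val - clinical_val) / clinical_val)
  if (is.na(digits)) pd else round(pd, digits)
}

#' Range-normalised RMSE between two waveforms
#'
#' Both signals are linearly resampled onto the finer of the two grids over
#' their common time support; the RMSE of the difference is divided by the
#' peak-to-peak range of the reference and expressed in percent.
#'
#' @param sim,ref [waveform()] objects with overlapping time support; `ref`
#'   must not be flat.
#' @return Percent error (`>= 0`).
#' @export
normalized_rmse <- function(sim, ref) {
  lo <- max(min(sim$t), min(ref$t))
  hi <- min(max(sim$t), max(ref$t))
  if (!(hi > lo)) stop("waveforms have no overlapping time support")
  finer <- if (stats::median(diff(sim$t)) <= stats::median(diff(ref$t))) sim else ref
  grid <- unique(c(lo, finer$t[finer$t > lo & finer$t < hi], hi))
  ys <- approx(sim$t, sim$y, grid)$y
  yr <- approx(ref$t, ref$y, grid)$y
  rng <- max(yr) - min(yr)
  if (rng <= 0) stop("normalization error: reference waveform is flat")
  100 * sqrt(mean((ys - yr)^2)) / rng
}

#' Pressure-volume loop metrics
#'
#' Stroke volume as the volume excursion and loop area (stroke work) by the
#' shoelace formula on the sampled closed loop.
#'
#' @param P_v,V_v Ventricular pressure and volume [waveform()]s on a common
#'   time base.
#' @param window Length-2 window (s) spanning one full cycle.
#' @return List with `stroke_volume` (mL), `loop_area` (mmHg.mL), and
#'   `closed` (whether the loop returns to its start within 2% of the signal
#'   ranges; an open loop triggers a warning).
#' @export
pv_loop_metrics <- function(P_v, V_v, window = range(V_v$t)) {
  sel_p <- P_v$t >= window[1] & P_v$t <= window[2]
  sel_v <- V_v$t >= window[1] & V_v$t <= window[2]
  if (sum(sel_p) < 3 || sum(sel_v) < 3)
    stop("argument error: window must contain a sampled loop")
  tt <- P_v$t[sel_p]
  P <- P_v$y[sel_p]
  V <- approx(V_v$t[sel_v], V_v$y[sel_v], tt, rule = 2)$y
  gap_v <- abs(V[length(V)] - V[1]) / max(diff(range(V)), 1e-12)
  gap_p <- abs(P[length(P)] - P[1]) / max(diff(range(P)), 1e-12)
  closed <- gap_v < 0.02 && gap_p < 0.02
  if (!closed)
    warning(sprintf("pressure-volume loop does not close (gaps: V %.1f%%, P %.1f%%)",
                    100 * gap_v, 100 * gap_p))
  nxt <- c(seq_along(tt)[-1], 1L)
  area <- 0.5 * abs(sum(V * P[nxt] - V[nxt] * P))
  list(stroke_volume = max(V) - min(V), loop_area = area, closed = closed)
}
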