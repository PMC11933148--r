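## Results I/O and analytic verification fixtures.

#' Write simulation results to disk
#'
#' Emits one CSV per monitored signal (`t_s, value, cycle`), a boundary
#' exchange-log CSV (`t_s, dt_s`, then `Q_<boundary>` and `P_<boundary>`
#' columns), and a JSON run summary (final-cycle averages, Qp/Qs, macro-step
#' statistics, volume drift, seed).  Numbers are written with 17 significant
#' digits so a written series reloads bitwise.
#'
#' @param res A `cardio_sim`.
#' @param dir Output directory (created if needed).
#' @param monitors Signal names to write (default: the four headline
#'   waveforms plus the ventricular state).
#' @return Character vector of written paths (the manifest), invisibly.
#' @export
write_results <- function(res, dir,
                          monitors = c("Q_aortic_root", "P_aortic_root",
                                       "P_dao", "Qbr_shunt", "P_sv", "V_sv")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("I/O error: cannot create directory ", dir)
  fmt <- function(x) formatC(x, digits = 17, format = "g")
  manifest <- character()
  for (nm in monitors) {
    w <- sim_signal(res, nm)
    path <- file.path(dir, paste0(nm, ".csv"))
    df <- data.frame(t_s = fmt(w$t), value = fmt(w$y),
                     cycle = w$cycle_index)
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
    manifest <- c(manifest, path)
  }
  ex <- exchange_log(res)
  ex_path <- file.path(dir, "exchange_log.csv")
  ex_out <- as.data.frame(lapply(ex, fmt))
  names(ex_out) <- sub("^t$", "t_s", sub("^dt$", "dt_s", names(ex)))
  utils::write.csv(ex_out, ex_path, row.names = FALSE, quote = FALSE)
  manifest <- c(manifest, ex_path)

  sm <- summary(res)
  summary_path <- file.path(dir, "summary.json")
  jsonlite::write_json(list(
    mode = sm$mode,
    cycles = sm$cycles,
    averages = as.list(sm$averages),
    volume_drift_pct = sm$volume_drift_pct,
    dt_us = as.list(1e6 * sm$dt_stats),
    max_follower_substep_us = 1e6 * sm$max_h_sub,
    seed = res$cfg$seed
  ), summary_path, auto_unbox = TRUE, digits = NA)
  manifest <- c(manifest, summary_path)
  invisible(manifest)
}

#' Read back a written signal CSV
#'
#' @param path Path to a CSV written by [write_results()].
#' @return A [waveform()].
#' @export
read_signal_csv <- function(path) {
  df <- utils::read.csv(path)
  waveform(as.numeric(df$t_s), as.numeric(df$value))
}

#' Three-element Windkessel verification fixture
#'
#' An open-loop RCR vascular bed (proximal resistance `R` into a compliance
#' `C` draining through `R_d` to zero reference pressure) driven by a
#' prescribed periodic half-sine inflow
#' \eqn{Q(t) = A \sin(\pi t / T_s)} for \eqn{t < T_s = T/3}, zero otherwise.
#' The linear ODE for the stored pressure has a closed-form
#' periodic-steady-state solution, returned here alongside the right-hand
#' side, for verifying the RK4 integrator against an analytic reference.
#'
#' @param R Proximal resistance (mmHg.s/mL).
#' @param C Compliance (mL/mmHg).
#' @param R_d Distal resistance (mmHg.s/mL).
#' @param T Period (s).
#' @param amplitude Peak inflow `A` (mL/s).
#' @return List with `rhs` (`function(t, P)`, dP/dt of the stored pressure),
#'   `inflow(t)`, `pressure(t)` (analytic periodic inlet pressure
#'   `R*Q + P_c`), `stored_pressure(t)` (analytic periodic `P_c`), `P0` (the
#'   periodic initial stored pressure), and the parameters.
#' @export
make_windkessel_fixture <- function(R = 0.5, C = 0.4, R_d = 1.2, T = 0.4,
                                    amplitude = 30) {
  stopifnot(R > 0, C > 0, R_d > 0, T > 0, amplitude > 0)
  Ts <- T / 3
  w <- pi / Ts
  lam <- 1 / (R_d * C)
  inflow <- function(t) {
    u <- t %% T
    ifelse(u < Ts, amplitude * sin(w * u), 0)
  }
  ## particular solution a*sin + b*cos on the driven segment
  a <- (amplitude / C) * lam / (lam^2 + w^2)
  b <- -(amplitude / C) * w / (lam^2 + w^2)
  ## periodicity: P(0) = b + K;  P(Ts) = -b + K e^{-lam Ts}  (sin(pi)=0);
  ## decay over [Ts, T]; P(T) = P(Ts) e^{-lam (T - Ts)} = P(0)
  K <- b * (1 + exp(-lam * (T - Ts))) / (exp(-lam * T) - 1)
  P0 <- b + K
  stored_pressure <- function(t) {
    u <- t %% T
    ifelse(u < Ts,
           a * sin(w * u) + b * cos(w * u) + K * exp(-lam * u),
           (-b + K * exp(-lam * Ts)) * exp(-lam * (u - Ts)))
  }
  list(
    rhs = function(t, P) (inflow(t) - P / R_d) / C,
    inflow = inflow,
    pressure = function(t) R * inflow(t) + stored_pressure(t),
    stored_pressure = stored_pressure,
    P0 = P0,
    params = list(R = R, C = C, R_d = R_d, T = T, T_s = Ts,
                  amplitude = amplitude)
  )
}
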