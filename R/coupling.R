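## Orchestration of the coupled simulation: the leader advances first with
## the last-known follower boundary pressures, hands the resulting boundary
## flows to the follower through the slave interface, commands do_step, and
## reads back pressures for its next step (explicit staggered Gauss-Seidel
## exchange, one exchange per accepted macro step).  An optional inner
## exchange-iteration loop re-evaluates both subsystems within a step.

signal_columns <- function() {
  bn <- boundary_set()$name
  c("t", "dt", paste0("lpm_", lpm_state_names()),
    paste0("Q_", bn), paste0("P_", bn),
    paste0("Qbr_", branch_names()),
    paste0("Pj_", c("arch", "innominate_jct", "pulmonary_jct")),
    "P_sv", "V_sv", "P_atr", "V_atr", "Q_av", "Q_aov",
    "resid", "iterations", "err_est", "h_sub")
}

#' Run the coupled leader/follower simulation
#'
#' Advances the coupled system over `cfg$coupling$n_cycles` cardiac cycles
#' (default 8), exchanging boundary pressures and flows at every macro
#' timestep; the leader's adaptive step is subdivided inside the follower so
#' that its internal RK4 step never exceeds `cfg$lpm$h_max_us` microseconds.
#' Data from the final cycle feed the clinical comparison in
#' [sim_averages()].
#'
#' @param cfg A configuration list.
#' @param slave Optionally, a pre-built (e.g. FMU-loaded) `cosim_slave`;
#'   by default the follower is constructed from `cfg`.
#' @return An object of class `cardio_sim`.
#' @export
#' @examples
#' \donttest{
#' sim <- run_coupled(default_config())
#' summary(sim)
#' }
run_coupled <- function(cfg = default_config(), slave = NULL) {
  cfg <- validate_config(cfg)
  if (is.null(slave)) slave <- cosim_slave(build_norwood_lpm(cfg))
  ld <- build_leader(cfg)
  Tper <- cfg$heart$T
  t_end <- cfg$coupling$n_cycles * Tper
  n_inner <- cfg$coupling$exchange_iterations
  bn <- boundary_set()$name
  q_names <- paste0("Q_", bn)

  P_bound <- unname(slave$outputs[paste0("P_", bn)])
  lst <- leader_init(ld, P_bound)
  dt <- ld$dt_init

  cols <- signal_columns()
  rec <- matrix(NA_real_, nrow = 4096, ncol = length(cols),
                dimnames = list(NULL, cols))
  nrec <- 0
  t <- 0
  while (t < t_end - 1e-12) {
    dt_use <- min(dt, t_end - t)
    snap <- list(state = slave$state, clock = slave$clock,
                 q = slave$q, q_prev = slave$q_prev)
    Pb_iter <- P_bound
    for (pass in seq_len(1 + n_inner)) {
      lst2 <- leader_step(lst, Pb_iter, dt_use, ld)
      if (pass > 1) {   # rewind the follower before re-stepping
        slave$state <- snap$state; slave$clock <- snap$clock
        slave$q <- snap$q; slave$q_prev <- snap$q_prev
      }
      for (b in 1:7) set_input(slave, q_names[b], lst2$Q_bound[[b]])
      status <- do_step(slave, t, dt_use)
      if (status != "ok")
        stop(sprintf("follower failure at t = %.6g s (dt = %.3g): %s",
                     t, dt_use, status))
      Pb_iter <- unname(slave$outputs[paste0("P_", bn)])
    }
    if (any(!is.finite(Pb_iter)) || any(!is.finite(lst2$Q_bound)))
      stop(sprintf("numerical failure: non-finite exchange value at t = %.6g s", t))
    P_bound <- Pb_iter
    t <- t + dt_use
    lst <- lst2

    nrec <- nrec + 1
    if (nrec > nrow(rec))
      rec <- rbind(rec, matrix(NA_real_, nrow = nrow(rec), ncol = ncol(rec)))
    rec[nrec, ] <- c(t, dt_use, slave$state,
                     lst2$Q_bound, P_bound, lst2$Q, lst2$Pj,
                     slave$outputs[c("P_sv", "V_sv", "P_atr", "V_atr",
                                     "Q_av", "Q_aov")],
                     lst2$resid, lst2$iterations, lst2$err_est,
                     slave$last_h_sub)
    dt <- adapt_timestep(dt, lst2$err_est, ld$step_tol, ld$dt_min, ld$dt_max)
  }
  signals <- as.data.frame(rec[seq_len(nrec), , drop = FALSE])
  new_cardio_sim(signals, cfg, mode = "coupled")
}

#' Run the monolithic reference simulation
#'
#' Verification oracle for the co-simulation split: follower and leader are
#' merged into a single ODE system (rigid-junction constraint reduced to a
#' linear solve for the junction pressures) and integrated with fixed-step
#' RK4 at the follower's internal step limit, with no exchange staggering.
#' Same monitors as [run_coupled()].
#'
#' @param cfg A configuration list.
#' @param stride Record every `stride`-th internal step (default 2).
#' @return An object of class `cardio_sim`.
#' @export
run_monolithic <- function(cfg = default_config(), stride = 2L) {
  cfg <- validate_config(cfg)
  m <- build_norwood_lpm(cfg)
  ld <- build_leader(cfg)
  t_end <- cfg$coupling$n_cycles * cfg$heart$T
  s0 <- m$init
  P0 <- lpm_outputs(s0, numeric(7), 0, m)[1:7]
  lst0 <- leader_init(ld, P0)
  y0 <- c(as.numeric(s0), as.numeric(lst0$Q))
  out <- .mono_run_cpp(y0, 0, t_end, m$h_max, m$par, ld$R, ld$L, ld$k,
                       1e3, as.integer(stride))
  bn <- boundary_set()$name
  b2br <- c(1L, 3L, 4L, 5L, 6L, 8L, 9L)
  sig <- data.frame(t = out[, 1], dt = c(NA, diff(out[, 1])))
  sig[paste0("lpm_", lpm_state_names())] <- out[, 2:14]
  sig[paste0("Q_", bn)] <- out[, 14 + b2br]
  sig[paste0("P_", bn)] <- out[, 27:33]
  sig[paste0("Qbr_", branch_names())] <- out[, 15:23]
  sig[paste0("Pj_", c("arch", "innominate_jct", "pulmonary_jct"))] <- out[, 24:26]
  sig[c("P_sv", "P_atr", "Q_av", "Q_aov")] <- out[, 34:37]
  sig$V_sv <- out[, 2]
  sig$V_atr <- out[, 3]
  sig[c("resid", "iterations", "err_est")] <- NA_real_
  sig$h_sub <- m$h_max
  sig <- sig[signal_columns()]
  new_cardio_sim(sig, cfg, mode = "monolithic")
}

new_cardio_sim <- function(signals, cfg, mode) {
  Tper <- cfg$heart$T
  n_cycles <- cfg$coupling$n_cycles
  signals$cycle <- pmin(floor(signals$t / Tper - 1e-12) + 1L, n_cycles)
  structure(list(
    signals = signals,
    cfg = cfg,
    mode = mode,
    T = Tper,
    cycles_completed = n_cycles,
    final_cycle_window = c((n_cycles - 1) * Tper, n_cycles * Tper)
  ), class = "cardio_sim")
}

#' Extract a monitored signal as a waveform
#'
#' @param sim A `cardio_sim`.
#' @param name Signal name (a column of `sim$signals`, e.g. `"Q_aortic_root"`,
#'   `"P_dao"`, `"Qbr_shunt"`, `"P_sv"`, `"V_sv"`).
#' @param window Optional time window (s).
#' @return A [waveform()].
#' @export
sim_signal <- function(sim, name, window = NULL) {
  if (!name %in% names(sim$signals)) stop("unknown signal: ", name)
  t <- sim$signals$t; y <- sim$signals[[name]]
  if (!is.null(window)) {
    keep <- t >= window[1] - 1e-12 & t <= window[2] + 1e-12
    t <- t[keep]; y <- y[keep]
  }
  base <- sub("^lpm_", "", name)
  unit <- if (grepl("^[QV]", base)) {
    if (startsWith(base, "V")) "mL" else "mL/s"
  } else "mmHg"
  waveform(t, y, unit = unit, T = sim$T)
}

#' Boundary-exchange log of a coupled run
#'
#' One record per accepted macro step: time, step size, and the exchanged
#' flow and pressure at each boundary.
#'
#' @param sim A `cardio_sim`.
#' @return A data frame.
#' @export
exchange_log <- function(sim) {
  bn <- boundary_set()$name
  sim$signals[, c("t", "dt", paste0("Q_", bn), paste0("P_", bn)), drop = FALSE]
}

#' Final-cycle averages of the clinically reported variables
#'
#' Cycle-averages over the final cardiac cycle: cardiac output (aortic-root
#' boundary flow), upper-body flow (innominate + left carotid + left
#' subclavian), descending-aorta flow, shunt flow, Qp/Qs, mean aortic-root
#' pressure and mean pulmonary-junction pressure.
#'
#' @param sim A `cardio_sim`.
#' @return Named numeric vector: `CO`, `Q_UB`, `Q_DAO`, `Q_SH`, `Qp_Qs`,
#'   `P_AO`, `P_PUL`.
#' @export
sim_averages <- function(sim) {
  w <- sim$final_cycle_window
  avg <- function(nm) cycle_average(sim_signal(sim, nm), w)
  q_ub <- avg("Q_innominate") + avg("Q_l_carotid") + avg("Q_l_subclavian")
  q_dao <- avg("Q_dao")
  q_sh <- avg("Qbr_shunt")
  c(CO = avg("Q_aortic_root"),
    Q_UB = q_ub, Q_DAO = q_dao, Q_SH = q_sh,
    Qp_Qs = qp_qs(q_sh, q_ub, q_dao),
    P_AO = avg("P_aortic_root"),
    P_PUL = avg("Pj_pulmonary_jct"))
}

#' Total-stressed-volume waveform of the follower
#'
#' @param sim A `cardio_sim`.
#' @return A [waveform()] of the follower's total stressed volume (mL).
#' @export
volume_series <- function(sim) {
  m <- build_norwood_lpm(sim$cfg)
  st <- as.matrix(sim$signals[paste0("lpm_", lpm_state_names())])
  v <- apply(st, 1, total_volume, m = m)
  waveform(sim$signals$t, v, unit = "mL", T = sim$T)
}

#' @export
print.cardio_sim <- function(x, ...) {
  cat(sprintf("%s simulation: %d cycles of T = %g s, %d recorded steps\n",
              if (x$mode == "coupled") "Coupled co-" else "Monolithic",
              x$cycles_completed, x$T, nrow(x$signals)))
  invisible(x)
}

#' @export
summary.cardio_sim <- function(object, ...) {
  av <- sim_averages(object)
  vol <- volume_series(object)
  dts <- object$signals$dt
  out <- list(
    mode = object$mode,
    averages = av,
    volume_drift_pct = 100 * abs(vol$y[length(vol$y)] - vol$y[1]) / vol$y[1],
    dt_stats = c(min = min(dts, na.rm = TRUE), mean = mean(dts, na.rm = TRUE),
                 max = max(dts, na.rm = TRUE)),
    max_h_sub = max(object$signals$h_sub, na.rm = TRUE),
    cycles = object$cycles_completed
  )
  class(out) <- "summary.cardio_sim"
  out
}

#' @export
print.summary.cardio_sim <- function(x, ...) {
  cat(sprintf("%s run, %d cycles; final-cycle averages:\n", x$mode, x$cycles))
  print(round(x$averages, 3))
  cat(sprintf("volume drift over run: %.4f%%\n", x$volume_drift_pct))
  cat(sprintf("macro dt [min/mean/max]: %.1f / %.1f / %.1f us; max follower substep %.1f us\n",
              1e6 * x$dt_stats["min"], 1e6 * x$dt_stats["mean"],
              1e6 * x$dt_stats["max"], 1e6 * x$max_h_sub))
  invisible(x)
}

#' Plot key waveforms of a simulation
#'
#' Four panels over the final cycle: aortic-root (cardiac output) flow, the
#' ventricular pressure-volume loop, upper-body flow, and descending-aorta
#' pressure.
#'
#' @param x A `cardio_sim`.
#' @param ... Unused.
#' @return `x`, invisibly.
#' @export
plot.cardio_sim <- function(x, ...) {
  w <- x$final_cycle_window
  op <- graphics::par(mfrow = c(2, 2), mar = c(4, 4, 2, 1))
  on.exit(graphics::par(op))
  co <- sim_signal(x, "Q_aortic_root", w)
  graphics::plot(co$t - w[1], co$y, type = "l", xlab = "t (s)",
                 ylab = "CO (mL/s)", main = "Cardiac output")
  P <- sim_signal(x, "P_sv", w); V <- sim_signal(x, "V_sv", w)
  graphics::plot(V$y, P$y, type = "l", xlab = "V (mL)", ylab = "P (mmHg)",
                 main = "Ventricular PV loop")
  ub <- sim_signal(x, "Q_innominate", w)
  ub$y <- ub$y + sim_signal(x, "Q_l_carotid", w)$y +
    sim_signal(x, "Q_l_subclavian", w)$y
  graphics::plot(ub$t - w[1], ub$y, type = "l", xlab = "t (s)",
                 ylab = "Q (mL/s)", main = "Upper body flow")
  dao <- sim_signal(x, "P_dao", w)
  graphics::plot(dao$t - w[1], dao$y, type = "l", xlab = "t (s)",
                 ylab = "P (mmHg)", main = "Descending aorta pressure")
  invisible(x)
}
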