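## The follower subsystem: closed-loop univentricular circulation.
##
## Topology (fixed, parameters from config):
##   single ventricle (time-varying elastance) -> aortic valve -> aortic-root
##   compliance node -> [aortic_root boundary, into the leader domain];
##   six boundary-fed vascular beds (innominate / l_carotid / l_subclavian /
##   dao systemic, lpa / rpa pulmonary), each a proximal resistance into an
##   RC node draining through a distal resistance; systemic and pulmonary
##   venous compliances return through resistive-inertial branches to a
##   passive atrium, which fills the ventricle through the AV valve.

#' Build the closed-loop Norwood circulation model
#'
#' Constructs the follower subsystem from a configuration: a single elastance
#' ventricle, passive atrium, two valves, an aortic-root node, six
#' boundary-fed vascular beds and two venous return branches.  Every boundary
#' in [boundary_set()] is wired exactly once.
#'
#' @param cfg A configuration list ([default_config()], [load_config()]).
#' @return An object of class `circulation_model` with the parameter vector,
#'   state dimension and variable name map.
#' @export
#' @examples
#' m <- build_norwood_lpm(default_config())
#' m$n_state
build_norwood_lpm <- function(cfg = default_config()) {
  cfg <- validate_config(cfg)
  ep <- elastance_params(cfg$heart$E_max, cfg$heart$E_min, cfg$heart$T,
                         cfg$heart$t_peak, cfg$heart$t_sys, cfg$heart$V0)
  structure(list(
    cfg = cfg,
    par = lpm_param_vector(cfg),
    elastance = ep,
    boundaries = boundary_set(),
    state_names = lpm_state_names(),
    n_state = length(lpm_state_names()),
    h_max = cfg$lpm$h_max_us * 1e-6,
    init = lpm_initial_state(cfg)
  ), class = "circulation_model")
}

#' @export
print.circulation_model <- function(x, ...) {
  cat("Closed-loop univentricular circulation (follower subsystem)\n")
  cat(sprintf("  states: %d (%s)\n", x$n_state,
              paste(x$state_names, collapse = ", ")))
  cat(sprintf("  boundaries: %s\n", paste(x$boundaries$name, collapse = ", ")))
  cat(sprintf("  period T = %g s, E_max = %g, E_min = %g mmHg/mL\n",
              x$cfg$heart$T, x$cfg$heart$E_max, x$cfg$heart$E_min))
  cat(sprintf("  internal RK4 substep <= %g us\n", x$cfg$lpm$h_max_us))
  invisible(x)
}

check_state_q <- function(state, q_in, m) {
  if (length(state) != m$n_state)
    stop(sprintf("structural error: state has %d entries, model expects %d",
                 length(state), m$n_state))
  if (length(q_in) != nrow(m$boundaries))
    stop(sprintf("structural error: q_in has %d entries, expected %d (one per boundary)",
                 length(q_in), nrow(m$boundaries)))
}

#' Right-hand side of the follower ODE system
#'
#' Derivative of the circulation state under held boundary flows: chamber
#' volumes change by net valve/return flow, compliance-node pressures by net
#' inflow over capacitance, inductive return flows by pressure difference
#' minus resistive drop over inertance.  The net volume rate of the whole
#' follower equals the oriented sum of the boundary flows.
#'
#' @param state Numeric state vector (see `build_norwood_lpm()$state_names`).
#' @param q_in Exchanged boundary flows (mL/s), one per boundary in
#'   [boundary_set()] order, positive in the physiological direction.
#' @param t Time (s).
#' @param m A `circulation_model`.
#' @return Named derivative vector, d(state)/dt.
#' @export
lpm_rhs <- function(state, q_in, t, m) {
  check_state_q(state, q_in, m)
  d <- .lpm_rhs_cpp(as.numeric(state), as.numeric(q_in), t, m$par)
  setNames(d, m$state_names)
}

#' Boundary pressures and monitored internals
#'
#' The pressures presented to the leader at each boundary (node pressure
#' corrected across the proximal resistance for the currently held boundary
#' flow), plus ventricular/atrial pressure and valve flows.
#'
#' @inheritParams lpm_rhs
#' @return Named numeric vector: `P_<boundary>` (7), `P_sv`, `P_atr`, `Q_av`,
#'   `Q_aov`, `E`.
#' @export
lpm_outputs <- function(state, q_in, t, m) {
  check_state_q(state, q_in, m)
  out <- .lpm_outputs_cpp(as.numeric(state), as.numeric(q_in), t, m$par)
  setNames(out, c(paste0("P_", m$boundaries$name),
                  "P_sv", "P_atr", "Q_av", "Q_aov", "E"))
}

#' Total stressed blood volume of the follower
#'
#' Sum of chamber volumes plus the volume stored on every compliance node,
#' \eqn{\sum C_i (P_i - P_{ref,i})} with all reference pressures zero.  In a
#' closed loop with zero net boundary flow this is an invariant of the
#' dynamics.
#'
#' @param state State vector.
#' @param m A `circulation_model`.
#' @return Volume (mL).
#' @export
total_volume <- function(state, m) {
  stopifnot(length(state) == m$n_state)
  cfg <- m$cfg
  beds <- cfg$lpm$beds[bed_names()]
  Cb <- vapply(beds, function(b) b$C, 0)
  unname(sum(state[1:2]) +
         cfg$lpm$aortic_root$C * state[3] +
         sum(Cb * state[4:9]) +
         cfg$lpm$venous$systemic$C * state[10] +
         cfg$lpm$venous$pulmonary$C * state[11])
}
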