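# Shared fixtures and an independently coded follower RHS oracle.

# Memoised expensive runs, shared across test files.
.sim_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(.sim_cache[[key]])) .sim_cache[[key]] <- force(expr)
  .sim_cache[[key]]
}

default_sim <- function() cached("default_sim", run_coupled(default_config()))
default_mono <- function() cached("default_mono", run_monolithic(default_config()))

# A config whose pump has zero elastance amplitude and whose state sits at a
# pressure-equalised equilibrium: nothing should move.
static_equilibrium_config <- function(P = 10) {
  cfg <- default_config()
  cfg$heart$E_max <- cfg$heart$E_min
  E <- cfg$heart$E_min
  cfg$lpm$init <- list(
    V_sv = cfg$heart$V0 + P / E,
    V_a = cfg$atrium$V0 + cfg$atrium$C * P,
    P_ao = P, P_inn = P, P_car = P, P_sub = P, P_dao = P,
    P_lpa = P, P_rpa = P, P_svn = P, P_pvn = P,
    Q_svr = 0, Q_pvr = 0)
  cfg
}

# Independent re-implementation of the follower derivative from the circuit
# equations, written directly from the topology (not via the package's
# parameter-vector plumbing).
oracle_rhs <- function(state, q, t, cfg) {
  h <- cfg$heart
  u <- t %% h$T
  act <- if (u < h$t_peak) 0.5 * (1 - cos(pi * u / h$t_peak))
         else if (u < h$t_sys) 0.5 * (1 + cos(pi * (u - h$t_peak) / (h$t_sys - h$t_peak)))
         else 0
  E <- h$E_min + (h$E_max - h$E_min) * act
  P_sv <- E * (state[["V_sv"]] - h$V0)
  P_a <- (state[["V_a"]] - cfg$atrium$V0) / cfg$atrium$C
  dio <- function(dP, R) max(dP, 0) / R
  Q_av <- dio(P_a - P_sv, cfg$valves$R_av)
  Q_ao <- dio(P_sv - state[["P_ao"]], cfg$valves$R_ao)
  beds <- cfg$lpm$beds
  nodes <- c(innominate = "P_inn", l_carotid = "P_car", l_subclavian = "P_sub",
             dao = "P_dao", lpa = "P_lpa", rpa = "P_rpa")
  out <- numeric(13)
  names(out) <- names(state)
  outflow <- setNames(numeric(6), names(nodes))
  for (i in seq_along(nodes)) {
    b <- names(nodes)[i]
    ven <- if (i <= 4) state[["P_svn"]] else state[["P_pvn"]]
    outflow[b] <- (state[[nodes[i]]] - ven) / beds[[b]]$R_dist
    out[nodes[i]] <- (q[1 + i] - outflow[b]) / beds[[b]]$C
  }
  out["V_sv"] <- Q_av - Q_ao
  out["V_a"] <- state[["Q_svr"]] + state[["Q_pvr"]] - Q_av
  out["P_ao"] <- (Q_ao - q[1]) / cfg$lpm$aortic_root$C
  vs <- cfg$lpm$venous$systemic; vp <- cfg$lpm$venous$pulmonary
  out["P_svn"] <- (sum(outflow[1:4]) - state[["Q_svr"]]) / vs$C
  out["P_pvn"] <- (sum(outflow[5:6]) - state[["Q_pvr"]]) / vp$C
  out["Q_svr"] <- (state[["P_svn"]] - P_a - vs$R_ret * state[["Q_svr"]]) / vs$L_ret
  out["Q_pvr"] <- (state[["P_pvn"]] - P_a - vp$R_ret * state[["Q_pvr"]]) / vp$L_ret
  out
}

# Deterministic pseudo-random state/flow generator for property loops.
random_states <- function(n, seed = 42) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    list(state = setNames(c(runif(2, 5, 25), runif(9, 2, 80), runif(2, -20, 20)),
                          c("V_sv", "V_a", "P_ao", "P_inn", "P_car", "P_sub",
                            "P_dao", "P_lpa", "P_rpa", "P_svn", "P_pvn",
                            "Q_svr", "Q_pvr")),
         q = runif(7, -10, 40),
         t = runif(1, 0, 2))
  })
}
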