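## The follower contract: typed variable registry and do-step semantics.
##
## The slave is an environment (reference semantics, as the FMI calling
## pattern assumes): inputs are set by value reference, the clock advances
## only through do_step, outputs are readable at any time after creation.

flatten_cfg <- function(x, prefix = character()) {
  out <- list()
  for (nm in names(x)) {
    v <- x[[nm]]
    key <- paste(c(prefix, nm), collapse = ".")
    if (is.list(v)) out <- c(out, flatten_cfg(v, c(prefix, nm)))
    else if (is.numeric(v) && length(v) == 1) out[[key]] <- v
  }
  out
}

#' Variable registry of the Norwood follower
#'
#' One row per exposed variable: seven boundary-flow inputs, boundary-pressure
#' and internal-monitor outputs (ventricular pressure/volume, atrial
#' pressure/volume, valve flows, echoed boundary flows), and every scalar
#' follower parameter.  Value references are unique consecutive integers;
#' inputs and parameters carry start values.
#'
#' @param m A `circulation_model`.
#' @return Data frame with columns `name`, `value_reference`, `causality`,
#'   `unit`, `start`.
#' @export
variable_registry <- function(m) {
  bn <- m$boundaries$name
  vars <- data.frame(
    name = c(paste0("Q_", bn),
             paste0("P_", bn),
             "P_sv", "V_sv", "P_atr", "V_atr", "Q_av", "Q_aov",
             paste0("Qmon_", bn)),
    causality = c(rep("input", 7), rep("output", 7 + 6 + 7)),
    unit = c(rep("mL/s", 7), rep("mmHg", 7),
             "mmHg", "mL", "mmHg", "mL", "mL/s", "mL/s",
             rep("mL/s", 7)),
    start = c(rep(0, 7), rep(NA_real_, 7 + 6 + 7)),
    stringsAsFactors = FALSE
  )
  par <- flatten_cfg(m$cfg[c("heart", "atrium", "valves", "lpm")])
  par$lpm.hold <- NULL
  vars <- rbind(vars, data.frame(
    name = names(par), causality = "parameter",
    unit = NA_character_, start = as.numeric(unlist(par)),
    stringsAsFactors = FALSE
  ))
  vars$value_reference <- seq_len(nrow(vars))
  rownames(vars) <- NULL
  vars[, c("name", "value_reference", "causality", "unit", "start")]
}

#' Create a co-simulation slave from a circulation model
#'
#' @param m A `circulation_model` (default: the shipped configuration).
#' @return An object of class `cosim_slave` (an environment).
#' @export
#' @examples
#' sl <- cosim_slave(build_norwood_lpm())
#' do_step(sl, 0, 1e-3)
#' get_output(sl, "P_aortic_root")
cosim_slave <- function(m = build_norwood_lpm()) {
  stopifnot(inherits(m, "circulation_model"))
  e <- new.env(parent = emptyenv())
  e$model <- m
  e$variables <- variable_registry(m)
  e$clock <- 0
  e$state <- m$init
  e$q <- setNames(numeric(7), paste0("Q_", m$boundaries$name))
  e$q_prev <- e$q
  e$pending_par <- list()
  e$status <- "ok"
  class(e) <- "cosim_slave"
  refresh_outputs(e)
  e
}

#' @export
print.cosim_slave <- function(x, ...) {
  cat(sprintf("Co-simulation slave: %d variables (%d inputs, %d outputs, %d parameters), clock = %g s\n",
              nrow(x$variables), sum(x$variables$causality == "input"),
              sum(x$variables$causality == "output"),
              sum(x$variables$causality == "parameter"), x$clock))
  invisible(x)
}

resolve_ref <- function(slave, ref) {
  v <- slave$variables
  i <- if (is.character(ref)) match(ref, v$name) else match(ref, v$value_reference)
  if (is.na(i))
    stop(sprintf("interface error: unknown variable reference '%s'", ref))
  i
}

refresh_outputs <- function(slave) {
  out <- lpm_outputs(slave$state, slave$q, slave$clock, slave$model)
  slave$outputs <- c(out[1:7],
                     P_sv = unname(out["P_sv"]),
                     V_sv = unname(slave$state["V_sv"]),
                     P_atr = unname(out["P_atr"]),
                     V_atr = unname(slave$state["V_a"]),
                     Q_av = unname(out["Q_av"]),
                     Q_aov = unname(out["Q_aov"]),
                     setNames(as.numeric(slave$q),
                              paste0("Qmon_", slave$model$boundaries$name)))
  invisible(slave)
}

#' Set an input or parameter on a slave
#'
#' Values take effect at the next [do_step()].  Setting an output, or an
#' unknown value reference, is an error.
#'
#' @param slave A `cosim_slave`.
#' @param ref Value reference (integer) or variable name.
#' @param value New value.
#' @return The slave, invisibly.
#' @export
set_input <- function(slave, ref, value) {
  i <- resolve_ref(slave, ref)
  v <- slave$variables[i, ]
  if (v$causality == "output")
    stop(sprintf("causality error: '%s' is an output and cannot be set", v$name))
  if (!is.finite(value)) stop("interface error: value must be finite")
  if (v$causality == "input") {
    slave$q[v$name] <- value
  } else {
    slave$pending_par[[v$name]] <- value
  }
  invisible(slave)
}

#' Read an output (or any variable) from a slave
#'
#' @param slave A `cosim_slave`.
#' @param ref Value reference (integer) or variable name.
#' @return The current value.
#' @export
get_output <- function(slave, ref) {
  i <- resolve_ref(slave, ref)
  v <- slave$variables[i, ]
  switch(v$causality,
         input = unname(slave$q[v$name]),
         output = unname(slave$outputs[v$name]),
         parameter = {
           p <- flatten_cfg(slave$model$cfg[c("heart", "atrium", "valves", "lpm")])
           unname(unlist(p[v$name]))
         })
}

apply_pending_parameters <- function(slave) {
  if (!length(slave$pending_par)) return(invisible(slave))
  cfg <- slave$model$cfg
  for (key in names(slave$pending_par)) {
    path <- strsplit(key, ".", fixed = TRUE)[[1]]
    cfg[[path]] <- slave$pending_par[[key]]
  }
  slave$model <- build_norwood_lpm(cfg)
  slave$pending_par <- list()
  invisible(slave)
}

#' Advance a slave by one communication step
#'
#' Integrates the follower from `t_comm` to `t_comm + dt` with the internally
#' subdivided RK4 solver, holding the currently set boundary-flow inputs
#' (zero-order by default; linear ramp from the previous inputs under the
#' `first_order` hold option), then refreshes all outputs and advances the
#' clock.  Protocol violations and numerical failures are reported as an
#' error status, not an R condition.
#'
#' @param slave A `cosim_slave`.
#' @param t_comm Communication time (s); must equal the slave clock to within
#'   1e-12 s.
#' @param dt Communication step (s), `> 0`.
#' @return Status string: `"ok"` or `"error: <reason>"`.
#' @export
do_step <- function(slave, t_comm, dt) {
  if (!is.finite(dt) || dt <= 0)
    stop("argument error: dt must be positive")
  if (abs(t_comm - slave$clock) > 1e-12) {
    slave$status <- sprintf(
      "error: out-of-order stepping (t_comm = %.12g, slave clock = %.12g)",
      t_comm, slave$clock)
    return(slave$status)
  }
  apply_pending_parameters(slave)
  q0 <- if (slave$model$cfg$lpm$hold == "first_order") slave$q_prev else slave$q
  res <- tryCatch(
    .lpm_integrate_cpp(as.numeric(slave$state), slave$clock, dt,
                       slave$model$h_max, as.numeric(q0),
                       as.numeric(slave$q), slave$model$par),
    error = function(e) e)
  if (inherits(res, "error")) {
    slave$status <- paste0("error: ", conditionMessage(res))
    return(slave$status)
  }
  slave$last_h_sub <- attr(res, "h_sub")
  slave$last_n_sub <- attr(res, "n_sub")
  slave$state <- setNames(as.numeric(res), slave$model$state_names)
  slave$q_prev <- slave$q
  slave$clock <- t_comm + dt
  refresh_outputs(slave)
  slave$status <- "ok"
  slave$status
}
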