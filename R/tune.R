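## Deterministic derivative-free tuning of circulation parameters toward
## clinical haemodynamic targets.

#' Clinical haemodynamic targets
#'
#' The seven cycle-averaged variables used for clinical comparison.  The
#' defaults are the reference catheterisation values for a stage-1 Norwood
#' patient used throughout the package's examples and acceptance checks.
#'
#' @param CO Cardiac output (mL/s).
#' @param Q_UB Upper-body flow (mL/s).
#' @param Q_DAO Descending-aorta flow (mL/s).
#' @param Q_SH Shunt flow (mL/s).
#' @param Qp_Qs Pulmonary-to-systemic flow ratio.
#' @param P_AO Mean aortic pressure (mmHg).
#' @param P_PUL Mean pulmonary pressure (mmHg).
#' @return Named numeric vector of class `clinical_targets`.
#' @export
clinical_targets <- function(CO = 21, Q_UB = 5.6, Q_DAO = 5.7, Q_SH = 9.7,
                             Qp_Qs = 0.9, P_AO = 52, P_PUL = 12) {
  v <- c(CO = CO, Q_UB = Q_UB, Q_DAO = Q_DAO, Q_SH = Q_SH,
         Qp_Qs = Qp_Qs, P_AO = P_AO, P_PUL = P_PUL)
  if (any(!is.finite(v)) || any(v <= 0))
    stop("clinical targets must all be positive")
  structure(v, class = c("clinical_targets", "numeric"))
}

## The documented tunable set: multiplicative knobs on groups of circulation
## parameters.  Each entry maps a log-scale multiplier onto the config.
tunable_knobs <- function() {
  apply_bed_R <- function(cfg, beds, f) {
    for (b in beds) cfg$lpm$beds[[b]]$R_dist <- cfg$lpm$beds[[b]]$R_dist * f
    cfg
  }
  list(
    r_ub = function(cfg, f)
      apply_bed_R(cfg, c("innominate", "l_carotid", "l_subclavian"), f),
    r_dao = function(cfg, f) apply_bed_R(cfg, "dao", f),
    r_pul = function(cfg, f) apply_bed_R(cfg, c("lpa", "rpa"), f),
    k_shunt = function(cfg, f) {
      cfg$leader$branches$shunt$k <- cfg$leader$branches$shunt$k * f
      cfg$leader$branches$shunt$R <- cfg$leader$branches$shunt$R * f
      cfg
    },
    e_max = function(cfg, f) {
      cfg$heart$E_max <- cfg$heart$E_max * f
      cfg
    },
    volume = function(cfg, f) {
      for (nm in c("V_sv", "V_a", "P_svn", "P_pvn"))
        cfg$lpm$init[[nm]] <- cfg$lpm$init[[nm]] * f
      cfg
    }
  )
}

apply_multipliers <- function(cfg, mult) {
  knobs <- tunable_knobs()
  for (nm in names(mult)) cfg <- knobs[[nm]](cfg, mult[[nm]])
  cfg
}

target_differences <- function(av, targets, digits = NA) {
  vapply(names(targets), function(nm)
    percent_difference(av[[nm]], targets[[nm]], digits = digits),
    0)
}

#' Tune circulation parameters toward clinical targets
#'
#' Deterministic coordinate descent on log-scale multipliers over a
#' documented tunable subset (systemic/pulmonary bed resistances, shunt
#' impedance, maximal elastance, stressed volume), minimising the maximum
#' absolute percent difference of the seven cycle-averaged variables of
#' [sim_averages()] against `targets`.  Each objective evaluation is one
#' coupled run of `cfg$coupling$n_cycles` cycles.
#'
#' @param cfg Starting configuration.
#' @param targets A [clinical_targets()] vector.
#' @param budget Maximum number of coupled-run evaluations (default 200).
#' @param tunables Names of the knobs to move (default: all of
#'   `names(tunable_knobs())`).
#' @param threshold Success threshold on the max percent difference
#'   (default 10).
#' @param step0 Initial multiplicative trial step (default 1.3).
#' @return An object of class `cardio_tune`: the tuned config (`cfg`), the
#'   multipliers (`multipliers`), achieved per-target percent differences
#'   (`differences`, one decimal), the objective trace, evaluation count and
#'   a `converged` flag (max difference below `threshold`).
#' @export
tune_parameters <- function(cfg = default_config(), targets = clinical_targets(),
                            budget = 200, tunables = names(tunable_knobs()),
                            threshold = 10, step0 = 1.3) {
  cfg <- validate_config(cfg)
  stopifnot(budget >= 1, all(tunables %in% names(tunable_knobs())))
  evals <- 0
  cache <- new.env(parent = emptyenv())
  objective <- function(mult) {
    key <- paste(sprintf("%.12g", unlist(mult)), collapse = "|")
    if (!is.null(cache[[key]])) return(cache[[key]])
    if (evals >= budget) return(NULL)
    evals <<- evals + 1
    av <- sim_averages(run_coupled(apply_multipliers(cfg, mult)))
    val <- list(obj = max(target_differences(av, targets)), av = av)
    cache[[key]] <- val
    val
  }

  mult <- as.list(setNames(rep(1, length(tunables)), tunables))
  best <- objective(mult)
  trace <- best$obj
  step <- step0
  while (evals < budget && best$obj > 1e-9 && step > 1.005) {
    improved_this_sweep <- FALSE
    for (nm in tunables) {
      repeat {  # greedy line search along one knob
        moved <- FALSE
        for (f in c(step, 1 / step)) {
          trial <- mult
          trial[[nm]] <- trial[[nm]] * f
          cand <- objective(trial)
          if (is.null(cand)) break
          if (cand$obj < best$obj - 1e-12) {
            mult <- trial; best <- cand
            trace <- c(trace, best$obj)
            moved <- TRUE
            improved_this_sweep <- TRUE
            break
          }
        }
        if (!moved || evals >= budget || best$obj <= 1e-9) break
      }
      if (evals >= budget || best$obj <= 1e-9) break
    }
    if (!improved_this_sweep) step <- step^0.5
  }

  structure(list(
    cfg = apply_multipliers(cfg, mult),
    start_cfg = cfg,
    targets = targets,
    multipliers = unlist(mult),
    averages = best$av,
    differences = target_differences(best$av, targets, digits = 1),
    objective = best$obj,
    evaluations = evals,
    trace = trace,
    threshold = threshold,
    converged = best$obj < threshold
  ), class = "cardio_tune")
}

#' @export
print.cardio_tune <- function(x, ...) {
  cat(sprintf("Parameter tuning: %d coupled-run evaluations, max |%%diff| = %.2f%% (%s at %g%%)\n",
              x$evaluations, x$objective,
              if (x$converged) "within threshold" else "ABOVE threshold",
              x$threshold))
  tab <- data.frame(target = as.numeric(x$targets),
                    model = round(as.numeric(x$averages[names(x$targets)]), 3),
                    diff_pct = as.numeric(x$differences))
  rownames(tab) <- names(x$targets)
  print(tab)
  cat("multipliers:", paste(sprintf("%s=%.4g", names(x$multipliers),
                                    x$multipliers), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.cardio_tune <- function(object, ...) object$multipliers
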