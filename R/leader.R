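## Leader subsystem: 0D surrogate of the 3D aortic arch / shunt domain.
##
## Topology (fixed): a central arch junction fed from the aortic_root
## boundary; branches from the arch to the l_carotid, l_subclavian and dao
## boundaries and to an innominate junction; the innominate junction feeds
## the innominate boundary and, through the quadratic-loss shunt branch, a
## pulmonary junction that splits to the lpa and rpa boundaries.  Branch
## dynamics dQ/dt = (dP - R*Q - k*Q*|Q|)/L with rigid (zero-storage)
## junctions; each macro step is advanced implicitly with a Newton iteration
## on the junction pressures until the junction flow residual vanishes.

#' Build the leader surrogate
#'
#' @param cfg A configuration list; the `leader` section supplies branch
#'   R/L/k coefficients, the residual tolerance and iteration cap, and the
#'   adaptive macro-timestep bounds.
#' @return An object of class `leader_domain`.
#' @export
build_leader <- function(cfg = default_config()) {
  cfg <- validate_config(cfg)
  lp <- leader_param_list(cfg)
  structure(list(
    cfg = cfg,
    R = lp$R, L = lp$L, k = lp$k,
    branch_names = branch_names(),
    junction_names = c("arch", "innominate_jct", "pulmonary_jct"),
    tol = cfg$leader$tol_rel,
    max_iter = cfg$leader$max_iter,
    dt_min = cfg$leader$dt_min_us * 1e-6,
    dt_max = cfg$leader$dt_max_us * 1e-6,
    dt_init = cfg$leader$dt_init_us * 1e-6,
    step_tol = cfg$leader$step_tol
  ), class = "leader_domain")
}

#' @export
print.leader_domain <- function(x, ...) {
  cat("0D leader surrogate of the arch/shunt domain\n")
  cat(sprintf("  branches: %s\n", paste(x$branch_names, collapse = ", ")))
  cat(sprintf("  junction residual tol %g (cap %d iterations); dt in [%g, %g] us\n",
              x$tol, x$max_iter, x$dt_min * 1e6, x$dt_max * 1e6))
  invisible(x)
}

#' Initial leader state
#'
#' Branch flows and junction pressures from the steady network solution under
#' the given boundary pressures (`dQ/dt = 0` everywhere), so that the first
#' coupled macro step starts from mutually consistent subsystem states.
#'
#' @param ld A `leader_domain`.
#' @param P_bound Boundary pressures (mmHg), one per boundary.
#' @return A list of class `leader_state`: `Q` (9 branch flows), `Pj`
#'   (3 junction pressures), `Q_bound` (7 oriented boundary flows), `t`, `dt`.
#' @export
leader_init <- function(ld, P_bound) {
  stopifnot(length(P_bound) == 7)
  st <- .leader_steady_cpp(as.numeric(P_bound), ld$R, ld$L, ld$k,
                           ld$tol, as.integer(ld$max_iter))
  structure(list(Q = setNames(st$Q, ld$branch_names),
                 Pj = setNames(st$Pj, ld$junction_names),
                 Q_bound = setNames(st$Q_bound, boundary_set()$name),
                 t = 0, dt = ld$dt_init),
            class = "leader_state")
}

#' Advance the leader by one macro step
#'
#' Implicit update of the branch flows under held boundary pressures, with
#' the junction pressures iterated (Newton) until the largest junction flow
#' residual is below `tol` relative to the mean branch-flow magnitude.  The
#' step is computed once over `dt` and once as two half steps; the returned
#' state is the two-half-step solution and the difference provides the local
#' error estimate used by [adapt_timestep()].
#'
#' @param st A `leader_state`.
#' @param P_bound Boundary pressures (mmHg), one per boundary.
#' @param dt Macro step (s), `> 0`.
#' @param ld A `leader_domain`.
#' @return Updated `leader_state` with fields `Q_bound` (oriented boundary
#'   flows, mL/s), `resid`, `iterations`, `err_est`.
#' @export
leader_step <- function(st, P_bound, dt, ld) {
  stopifnot(inherits(st, "leader_state"), length(P_bound) == 7)
  if (!is.finite(dt) || dt <= 0) stop("argument error: dt must be positive")
  res <- .leader_macro_cpp(as.numeric(st$Q), as.numeric(st$Pj),
                           as.numeric(P_bound), dt, ld$R, ld$L, ld$k,
                           ld$tol, as.integer(ld$max_iter))
  if (res$resid >= ld$tol * (mean(abs(res$Q)) + 1e-9) * 10)
    stop(sprintf("non-convergence: junction residual %.3g after %d iterations",
                 res$resid, res$iterations))
  structure(list(Q = setNames(res$Q, ld$branch_names),
                 Pj = setNames(res$Pj, ld$junction_names),
                 Q_bound = setNames(res$Q_bound, boundary_set()$name),
                 t = st$t + dt, dt = dt,
                 resid = res$resid, iterations = res$iterations,
                 err_est = res$err_est),
            class = "leader_state")
}

#' Steady flow through a single branch element
#'
#' The unique real solution of \eqn{R Q + k Q |Q| = \Delta P} with
#' `sign(Q) = sign(dP)`.
#'
#' @param branch List with elements `R`, `k` (and optionally `L`, unused).
#' @param dP Pressure difference (mmHg).
#' @return Flow (mL/s).
#' @export
#' @examples
#' steady_flow_solve(list(R = 1, k = 0.1), 10)   # 6.18034
steady_flow_solve <- function(branch, dP) {
  R <- branch$R; k <- if (is.null(branch$k)) 0 else branch$k
  if (R <= 0 && k <= 0) stop("degenerate branch: R and k both zero")
  if (k <= 0) return(dP / R)
  mag <- (-R + sqrt(R^2 + 4 * k * abs(dP))) / (2 * k)
  sign(dP) * mag
}

#' Adaptive macro-timestep controller
#'
#' Standard step controller: the step shrinks (by a factor of at least 0.5)
#' when the local error estimate exceeds `tol`, grows (by a factor of at most
#' 2) when it is below `tol/4`, and is clamped to `[dt_min, dt_max]`.
#'
#' @param dt Current macro step (s).
#' @param error_est Local error estimate (relative, dimensionless).
#' @param tol Target error.
#' @param dt_min,dt_max Step bounds (s).
#' @return New macro step (s).
#' @export
adapt_timestep <- function(dt, error_est, tol, dt_min = 1e-5, dt_max = 2e-3) {
  stopifnot(dt >= dt_min - 1e-15, dt <= dt_max + 1e-15)
  fac <- 1
  if (error_est > tol) {
    fac <- max(0.5, 0.9 * sqrt(tol / error_est))
  } else if (error_est < tol / 4) {
    fac <- if (error_est <= 0) 2 else min(2, 0.9 * sqrt(tol / error_est))
  }
  min(dt_max, max(dt_min, dt * fac))
}
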