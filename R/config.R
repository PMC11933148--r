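## Configuration: schema, defaults, loading and saving.
##
## All quantities are in the package's internal unit system: pressure mmHg,
## volume mL, time s; resistance mmHg.s/mL, compliance mL/mmHg, inertance
## mmHg.s^2/mL, quadratic loss mmHg.s^2/mL^2.

#' Boundary set of the coupled domain
#'
#' The seven coupling boundaries between the follower circulation and the
#' leader arch/shunt surrogate, in their fixed exchange order, with the sign
#' convention used throughout: `orientation` is `+1` where positive exchanged
#' flow enters the follower (the six distal boundaries) and `-1` where it
#' leaves it (the aortic root).
#'
#' @return A data frame with columns `name` and `orientation`.
#' @export
#' @examples
#' boundary_set()
boundary_set <- function() {
  data.frame(
    name = c("aortic_root", "innominate", "l_carotid", "l_subclavian",
             "dao", "lpa", "rpa"),
    orientation = c(-1L, 1L, 1L, 1L, 1L, 1L, 1L),
    stringsAsFactors = FALSE
  )
}

bed_names <- function() {
  c("innominate", "l_carotid", "l_subclavian", "dao", "lpa", "rpa")
}

branch_names <- function() {
  c("inlet", "arch_innominate", "innominate_outlet", "l_carotid",
    "l_subclavian", "dao", "shunt", "lpa", "rpa")
}

#' Default run configuration
#'
#' The shipped neonatal Norwood configuration: a 150 bpm heart period, an
#' upper-body/lower-body systemic split across four vascular beds, left and
#' right pulmonary beds fed through the shunt, and a low-impedance leader
#' network for the arch and its branches.  These defaults describe a
#' physiologically plausible stage-1 single-ventricle circulation and are the
#' starting point for [tune_parameters()].
#'
#' @return A nested list; see the package vignette for the schema.
#' @export
default_config <- function() {
  bed <- function(Rp, C, Rd) list(R_prox = Rp, C = C, R_dist = Rd)
  br <- function(R, L, k = 0) list(R = R, L = L, k = k)
  list(
    heart = list(T = 0.4, t_peak = 0.14, t_sys = 0.22,
                 E_max = 14, E_min = 0.22, V0 = 5),
    atrium = list(C = 2.0, V0 = 0),
    valves = list(R_av = 0.02, R_ao = 0.1, eps = 0),
    lpm = list(
      h_max_us = 100,
      hold = "zero_order",
      aortic_root = list(C = 0.25, R_prox = 0.05),
      beds = list(
        innominate   = bed(0.3, 0.05, 26),
        l_carotid    = bed(0.3, 0.05, 26),
        l_subclavian = bed(0.3, 0.05, 26),
        dao          = bed(0.15, 0.15, 8.5),
        lpa          = bed(0.05, 0.12, 1.5),
        rpa          = bed(0.05, 0.12, 1.5)
      ),
      venous = list(
        systemic  = list(C = 15, R_ret = 0.08, L_ret = 5e-4),
        pulmonary = list(C = 4, R_ret = 0.06, L_ret = 5e-4)
      ),
      ## start-of-cycle state on the settled limit cycle of this topology,
      ## so transients die out well before the final analysis cycle
      init = list(V_sv = 17.6578, V_a = 6.41279,
                  P_ao = 48.7075, P_inn = 47.4055, P_car = 47.8529,
                  P_sub = 47.8529, P_dao = 47.8463,
                  P_lpa = 11.4043, P_rpa = 11.4043,
                  P_svn = 4.32952, P_pvn = 3.93253,
                  Q_svr = 14.2947, Q_pvr = 12.6299)
    ),
    leader = list(
      branches = list(
        inlet             = br(0.05, 1e-3),
        arch_innominate   = br(0.05, 1e-3),
        innominate_outlet = br(0.05, 5e-4),
        l_carotid         = br(0.08, 1.5e-3),
        l_subclavian      = br(0.08, 1.5e-3),
        dao               = br(0.05, 1e-3),
        shunt             = br(2.6, 2e-3, 0.14),
        lpa               = br(0.1, 8e-4),
        rpa               = br(0.1, 8e-4)
      ),
      tol_rel = 1e-5, max_iter = 50,
      dt_min_us = 10, dt_max_us = 2000, dt_init_us = 200,
      step_tol = 2e-3
    ),
    coupling = list(n_cycles = 8, exchange_iterations = 0),
    seed = 1
  )
}

## --- schema validation -----------------------------------------------------

cfg_fail <- function(key, constraint) {
  stop(sprintf("configuration error: '%s' %s", key, constraint), call. = FALSE)
}

check_num <- function(cfg, key, lower = 0, strict = TRUE) {
  v <- cfg
  for (part in strsplit(key, ".", fixed = TRUE)[[1]]) {
    if (is.null(v[[part]])) cfg_fail(key, "is missing")
    v <- v[[part]]
  }
  if (!is.numeric(v) || length(v) != 1 || !is.finite(v))
    cfg_fail(key, "must be a finite number")
  if (strict && v <= lower) cfg_fail(key, sprintf("must be > %g", lower))
  if (!strict && v < lower) cfg_fail(key, sprintf("must be >= %g", lower))
  invisible(v)
}

check_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra))
    cfg_fail(paste0(where, ".", extra[1]), "is not a recognised key")
  invisible(x)
}

#' Validate a run configuration
#'
#' Checks structure (unknown keys are rejected), positivity and ordering
#' constraints, and that every coupling boundary is wired on both the follower
#' and leader sides.  Called by every entry point that accepts a config.
#'
#' @param cfg A configuration list, as from [default_config()] or
#'   [load_config()].
#' @return `cfg`, invisibly, with defaults filled in.
#' @export
validate_config <- function(cfg) {
  if (!is.list(cfg)) cfg_fail("(root)", "must be a list")
  # top-level sections and scalar settings are defaulted; the physical block
  # tables (beds, branches, initial state) must be complete when supplied, so
  # an omitted block parameter is reported by name instead of silently
  # refilled
  user_beds <- cfg$lpm$beds
  user_branches <- cfg$leader$branches
  user_init <- cfg$lpm$init
  cfg <- modifyList(default_config(), cfg)
  if (!is.null(user_beds)) cfg$lpm$beds <- user_beds
  if (!is.null(user_branches)) cfg$leader$branches <- user_branches
  if (!is.null(user_init)) cfg$lpm$init <- user_init
  check_keys(cfg, c("heart", "atrium", "valves", "lpm", "leader", "coupling",
                    "seed"), "config")
  check_keys(cfg$heart, c("T", "t_peak", "t_sys", "E_max", "E_min", "V0"), "heart")
  Tper <- check_num(cfg, "heart.T")
  tp <- check_num(cfg, "heart.t_peak")
  ts <- check_num(cfg, "heart.t_sys")
  if (!(tp < ts && ts <= Tper))
    cfg_fail("heart.t_sys", "must satisfy t_peak < t_sys <= T")
  emax <- check_num(cfg, "heart.E_max")
  emin <- check_num(cfg, "heart.E_min")
  if (emax < emin) cfg_fail("heart.E_max", "must be >= E_min")
  check_num(cfg, "heart.V0", 0, strict = FALSE)
  check_keys(cfg$atrium, c("C", "V0"), "atrium")
  check_num(cfg, "atrium.C")
  check_num(cfg, "atrium.V0", 0, strict = FALSE)
  check_keys(cfg$valves, c("R_av", "R_ao", "eps"), "valves")
  check_num(cfg, "valves.R_av")
  check_num(cfg, "valves.R_ao")
  check_num(cfg, "valves.eps", 0, strict = FALSE)

  check_keys(cfg$lpm, c("h_max_us", "hold", "aortic_root", "beds", "venous",
                        "init"), "lpm")
  check_num(cfg, "lpm.h_max_us")
  if (!cfg$lpm$hold %in% c("zero_order", "first_order"))
    cfg_fail("lpm.hold", "must be 'zero_order' or 'first_order'")
  check_num(cfg, "lpm.aortic_root.C")
  check_num(cfg, "lpm.aortic_root.R_prox", 0, strict = FALSE)
  check_keys(cfg$lpm$beds, bed_names(), "lpm.beds")
  for (b in bed_names()) {
    if (is.null(cfg$lpm$beds[[b]]))
      cfg_fail(paste0("lpm.beds.", b), "is missing")
    check_keys(cfg$lpm$beds[[b]], c("R_prox", "C", "R_dist"),
               paste0("lpm.beds.", b))
    check_num(cfg, paste0("lpm.beds.", b, ".R_prox"), 0, strict = FALSE)
    check_num(cfg, paste0("lpm.beds.", b, ".C"))
    check_num(cfg, paste0("lpm.beds.", b, ".R_dist"))
  }
  for (v in c("systemic", "pulmonary")) {
    check_num(cfg, paste0("lpm.venous.", v, ".C"))
    check_num(cfg, paste0("lpm.venous.", v, ".R_ret"))
    check_num(cfg, paste0("lpm.venous.", v, ".L_ret"))
  }
  init_keys <- c("V_sv", "V_a", "P_ao", "P_inn", "P_car", "P_sub", "P_dao",
                 "P_lpa", "P_rpa", "P_svn", "P_pvn", "Q_svr", "Q_pvr")
  check_keys(cfg$lpm$init, init_keys, "lpm.init")
  for (kk in init_keys)
    if (is.null(cfg$lpm$init[[kk]])) cfg_fail(paste0("lpm.init.", kk), "is missing")
  check_num(cfg, "lpm.init.V_sv")
  check_num(cfg, "lpm.init.V_a")

  check_keys(cfg$leader, c("branches", "tol_rel", "max_iter", "dt_min_us",
                           "dt_max_us", "dt_init_us", "step_tol"), "leader")
  check_keys(cfg$leader$branches, branch_names(), "leader.branches")
  for (b in branch_names()) {
    if (is.null(cfg$leader$branches[[b]]))
      cfg_fail(paste0("leader.branches.", b), "is missing")
    check_keys(cfg$leader$branches[[b]], c("R", "L", "k"),
               paste0("leader.branches.", b))
    check_num(cfg, paste0("leader.branches.", b, ".R"), 0, strict = FALSE)
    check_num(cfg, paste0("leader.branches.", b, ".L"))
    check_num(cfg, paste0("leader.branches.", b, ".k"), 0, strict = FALSE)
  }
  check_num(cfg, "leader.tol_rel")
  check_num(cfg, "leader.max_iter")
  dtmin <- check_num(cfg, "leader.dt_min_us")
  dtmax <- check_num(cfg, "leader.dt_max_us")
  check_num(cfg, "leader.dt_init_us")
  if (dtmax < dtmin) cfg_fail("leader.dt_max_us", "must be >= dt_min_us")
  # the initial step is clamped into the admissible range
  cfg$leader$dt_init_us <- min(max(cfg$leader$dt_init_us, dtmin), dtmax)
  check_num(cfg, "leader.step_tol")

  check_keys(cfg$coupling, c("n_cycles", "exchange_iterations"), "coupling")
  nc <- check_num(cfg, "coupling.n_cycles", 0)
  if (nc != round(nc) || nc < 1) cfg_fail("coupling.n_cycles", "must be an integer >= 1")
  check_num(cfg, "coupling.exchange_iterations", 0, strict = FALSE)
  invisible(cfg)
}

#' Load a run configuration from YAML
#'
#' Missing keys are filled from [default_config()]; unknown keys are rejected.
#'
#' @param path Path to a YAML file.
#' @return A validated configuration list.
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stop("configuration file not found: ", path)
  cfg <- yaml::read_yaml(path)
  validate_config(cfg)
}

#' Save a run configuration to YAML
#'
#' @param cfg A configuration list.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_config <- function(cfg, path) {
  cfg <- validate_config(cfg)
  yaml::write_yaml(cfg, path, precision = 17)
  invisible(path)
}

## --- flattening into the solver parameter layouts --------------------------

## Follower parameter vector; order must match the compiled layout.
lpm_param_vector <- function(cfg) {
  h <- cfg$heart; beds <- cfg$lpm$beds
  bv <- unlist(lapply(bed_names(), function(b)
    unlist(beds[[b]][c("R_prox", "C", "R_dist")], use.names = FALSE)))
  pv <- c(h$E_max, h$E_min, h$T, h$t_peak, h$t_sys, h$V0,
          cfg$atrium$C, cfg$atrium$V0,
          cfg$valves$R_av, cfg$valves$R_ao, cfg$valves$eps,
          cfg$lpm$aortic_root$C, cfg$lpm$aortic_root$R_prox,
          bv,
          cfg$lpm$venous$systemic$C, cfg$lpm$venous$systemic$R_ret,
          cfg$lpm$venous$systemic$L_ret,
          cfg$lpm$venous$pulmonary$C, cfg$lpm$venous$pulmonary$R_ret,
          cfg$lpm$venous$pulmonary$L_ret)
  as.numeric(pv)
}

lpm_state_names <- function() {
  c("V_sv", "V_a", "P_ao", "P_inn", "P_car", "P_sub", "P_dao",
    "P_lpa", "P_rpa", "P_svn", "P_pvn", "Q_svr", "Q_pvr")
}

lpm_initial_state <- function(cfg) {
  s <- unlist(cfg$lpm$init[lpm_state_names()], use.names = FALSE)
  setNames(as.numeric(s), lpm_state_names())
}

leader_param_list <- function(cfg) {
  br <- cfg$leader$branches[branch_names()]
  list(R = vapply(br, function(b) b$R, 0),
       L = vapply(br, function(b) b$L, 0),
       k = vapply(br, function(b) b$k, 0))
}
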