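# Closed-loop circulation model: elastance, valves, right-hand side,
# construction and bookkeeping.

test_that("elastance has the right amplitude, floor and periodicity", {
  p <- elastance_params(E_max = 2, E_min = 2, T = 0.4, t_peak = 0.14,
                        t_sys = 0.22)
  expect_equal(elastance(c(0, 0.1, 0.33, 5.27), p), rep(2, 4))

  p <- elastance_params(E_max = 14, E_min = 0.22, T = 0.4, t_peak = 0.14,
                        t_sys = 0.22)
  # activation floor in diastole
  expect_equal(elastance(c(0.23, 0.3, 0.399), p), rep(0.22, 3))
  # grid-search oracle: maximum over a dense grid of one period equals E_max
  grid <- seq(0, p$T, length.out = 1e5)
  expect_equal(max(elastance(grid, p)), p$E_max, tolerance = 1e-6)
  # T-periodicity
  ts <- seq(0, 0.4, by = 0.0173)
  expect_true(all(abs(elastance(ts, p) - elastance(ts + p$T, p)) < 1e-12))
})

test_that("elastance parameter validation rejects inconsistent values", {
  expect_error(elastance_params(1, 2, 0.4, 0.1), "E_max >= E_min")
  expect_error(elastance_params(2, 1, 0.4, 0.5), "t_peak < T")
  expect_error(elastance_params(2, 1, 0.4, 0.1, V0 = -1), "V0")
})

test_that("valve law: closed, Ohmic, and smooth regularisation bound", {
  v0 <- valve_params(R_open = 1, eps = 0)
  expect_identical(valve_flow(-5, v0), 0)
  expect_identical(valve_flow(10, v0), 10)
  ve <- valve_params(R_open = 1, eps = 0.1)
  q0 <- valve_flow(0, ve)
  expect_gte(q0, 0); expect_lte(q0, 0.1)
  # non-negative, monotone non-decreasing, bounded by ideal flow + eps/R
  dP <- seq(-20, 20, by = 0.05)
  q <- valve_flow(dP, ve)
  expect_true(all(q >= 0))
  expect_true(all(diff(q) >= 0))
  expect_true(all(q <= pmax(dP, 0) / ve$R_open + ve$eps / ve$R_open + 1e-12))
})

test_that("equilibrium state with closed valves has a zero derivative", {
  cfg <- static_equilibrium_config(P = 10)
  m <- build_norwood_lpm(cfg)
  d <- lpm_rhs(m$init, numeric(7), t = 0.3, m)
  expect_equal(unname(d), rep(0, 13))
})

test_that("a balanced Windkessel bed holds its pressure", {
  cfg <- default_config()
  m <- build_norwood_lpm(cfg)
  s <- m$init
  # feed the dao bed exactly its distal outflow: node pressure is stationary
  q <- numeric(7)
  q[5] <- (s[["P_dao"]] - s[["P_svn"]]) / cfg$lpm$beds$dao$R_dist
  d <- lpm_rhs(s, q, t = 0.3, m)
  expect_equal(unname(d[["P_dao"]]), 0, tolerance = 1e-14)
})

test_that("rhs matches an independently coded circuit oracle", {
  cfg <- default_config()
  m <- build_norwood_lpm(cfg)
  for (case in random_states(12)) {
    got <- lpm_rhs(case$state, case$q, case$t, m)
    want <- oracle_rhs(case$state, case$q, case$t, cfg)
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("volume bookkeeping: net volume rate equals oriented boundary flow", {
  cfg <- default_config()
  m <- build_norwood_lpm(cfg)
  orient <- boundary_set()$orientation
  beds <- cfg$lpm$beds
  Cs <- c(1, 1, cfg$lpm$aortic_root$C,
          vapply(beds, function(b) b$C, 0),
          cfg$lpm$venous$systemic$C, cfg$lpm$venous$pulmonary$C, 0, 0)
  for (case in random_states(12, seed = 7)) {
    d <- lpm_rhs(case$state, case$q, case$t, m)
    dvol <- sum(Cs * d)
    expect_equal(dvol, sum(orient * case$q), tolerance = 1e-10)
  }
})

test_that("rhs is deterministic (bitwise identical outputs)", {
  m <- build_norwood_lpm(default_config())
  case <- random_states(1, seed = 99)[[1]]
  expect_identical(lpm_rhs(case$state, case$q, case$t, m),
                   lpm_rhs(case$state, case$q, case$t, m))
})

test_that("model construction: dimensions, validation, volume oracle", {
  m <- build_norwood_lpm(default_config())
  expect_equal(nrow(m$boundaries), 7)
  expect_equal(m$n_state, 13)
  expect_named(m$init, m$state_names)

  cfg <- default_config()
  cfg$lpm$beds$lpa$C <- NULL
  expect_error(build_norwood_lpm(cfg), "lpm\\.beds\\.lpa\\.C")

  # hand-summed total volume oracle
  cfg <- default_config()
  m <- build_norwood_lpm(cfg)
  s <- m$init
  by_hand <- s[["V_sv"]] + s[["V_a"]] +
    cfg$lpm$aortic_root$C * s[["P_ao"]] +
    cfg$lpm$beds$innominate$C * s[["P_inn"]] +
    cfg$lpm$beds$l_carotid$C * s[["P_car"]] +
    cfg$lpm$beds$l_subclavian$C * s[["P_sub"]] +
    cfg$lpm$beds$dao$C * s[["P_dao"]] +
    cfg$lpm$beds$lpa$C * s[["P_lpa"]] +
    cfg$lpm$beds$rpa$C * s[["P_rpa"]] +
    cfg$lpm$venous$systemic$C * s[["P_svn"]] +
    cfg$lpm$venous$pulmonary$C * s[["P_pvn"]]
  expect_equal(total_volume(s, m), unname(by_hand))
})

test_that("dimension mismatches raise structural errors", {
  m <- build_norwood_lpm(default_config())
  expect_error(lpm_rhs(m$init[-1], numeric(7), 0, m), "structural error")
  expect_error(lpm_rhs(m$init, numeric(6), 0, m), "structural error")
})
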