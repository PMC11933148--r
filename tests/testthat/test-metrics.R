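# Waveform analytics: averages, ratios, percent differences, NRMSE, PV loops.

test_that("cycle_average: constants, zero-mean oscillations, linear oracle", {
  t <- seq(0, 1, by = 0.001)
  expect_equal(cycle_average(waveform(t, rep(5, length(t)))), 5)
  T <- 0.4
  tt <- seq(0, T, length.out = 4001)
  expect_equal(cycle_average(waveform(tt, sin(2 * pi * tt / T) + 3)), 3,
               tolerance = 1e-6)
  # piecewise-linear signal: trapezoid on knots vs densely resampled oracle
  set.seed(3)
  knots <- sort(runif(40, 0, 1)); knots <- c(0, knots, 1)
  vals <- rnorm(length(knots))
  w <- waveform(knots, vals)
  dense_t <- seq(0, 1, length.out = 2e5)
  dense_y <- approx(knots, vals, dense_t)$y
  oracle <- sum(diff(dense_t) * (head(dense_y, -1) + tail(dense_y, -1)) / 2)
  expect_equal(cycle_average(w, c(0, 1)), oracle, tolerance = 1e-7)
  expect_error(cycle_average(w, c(0.5, 0.5)), "empty")
  expect_error(cycle_average(w, c(0, 2)), "outside")
})

test_that("qp_qs reproduces the clinical-table arithmetic", {
  expect_equal(round(qp_qs(10.18, 5.79, 6.04), 2), 0.86)
  expect_equal(qp_qs(7.5, 3.0, 4.5), 1.0)
  expect_equal(qp_qs(0, 3.0, 4.5), 0.0)
  expect_error(qp_qs(5, -3, 1), "domain error")
})

test_that("percent differences match the reporting convention", {
  expect_equal(percent_difference(22.0, 21), 4.8)
  expect_equal(percent_difference(5.79, 5.6), 3.4)
  expect_equal(percent_difference(3.14, 3.14), 0.0)
  expect_error(percent_difference(1, 0), "domain error")
  # homogeneous of degree 0
  for (s in c(0.01, 7.5, 120)) {
    expect_equal(percent_difference(22 * s, 21 * s, digits = NA),
                 percent_difference(22, 21, digits = NA), tolerance = 1e-12)
  }
})

test_that("normalized RMSE: identity, constant offset, scale invariance", {
  t <- seq(0, 1, by = 0.002)
  ref <- waveform(t, sin(2 * pi * t) * 4 + 10)
  expect_equal(normalized_rmse(ref, ref), 0)
  off <- waveform(t, ref$y + 0.6)
  expect_equal(normalized_rmse(off, ref), 100 * 0.6 / 8, tolerance = 1e-9)
  scaled_s <- waveform(t, off$y * 7.5)
  scaled_r <- waveform(t, ref$y * 7.5)
  expect_equal(normalized_rmse(scaled_s, scaled_r), normalized_rmse(off, ref),
               tolerance = 1e-12)
  expect_gte(normalized_rmse(off, ref), 0)
  expect_error(normalized_rmse(ref, waveform(t, rep(1, length(t)))),
               "normalization error")
})

test_that("PV loop metrics: rectangle, ellipse, sinusoidal stroke volume", {
  # rectangle P in {10, 50}, V in {20, 40}: area 800
  th <- seq(0, 1, length.out = 4001)
  Vr <- c(seq(20, 40, length.out = 1000), rep(40, 1000),
          seq(40, 20, length.out = 1000), rep(20, 1001))
  Pr <- c(rep(10, 1000), seq(10, 50, length.out = 1000),
          rep(50, 1000), seq(50, 10, length.out = 1001))
  res <- pv_loop_metrics(waveform(th, Pr), waveform(th, Vr))
  expect_equal(res$loop_area, 800, tolerance = 1e-3)
  expect_equal(res$stroke_volume, 20)

  # ellipse, semi-axes a (volume), b (pressure): area pi*a*b
  a <- 12; b <- 35
  ph <- seq(0, 2 * pi, length.out = 1e4 + 1)
  tt <- seq(0, 1, length.out = 1e4 + 1)
  res <- pv_loop_metrics(waveform(tt, 60 + b * sin(ph)),
                         waveform(tt, 30 + a * cos(ph)))
  expect_equal(res$loop_area, pi * a * b, tolerance = 1e-3 * pi * a * b)
  expect_true(res$closed)

  # stroke volume of V(t) = 30 + 10 sin
  V <- waveform(tt, 30 + 10 * sin(ph))
  P <- waveform(tt, 40 + 20 * cos(ph))
  expect_equal(pv_loop_metrics(P, V)$stroke_volume, 20, tolerance = 1e-6)

  # open loop warns
  expect_warning(pv_loop_metrics(waveform(tt, seq(1, 40, length.out = length(tt))),
                                 waveform(tt, seq(10, 30, length.out = length(tt)))),
                 "does not close")
})

test_that("simulated PV loop yields a plausible stroke volume and work", {
  sim <- default_sim()
  w <- sim$final_cycle_window
  res <- pv_loop_metrics(sim_signal(sim, "P_sv", w), sim_signal(sim, "V_sv", w),
                         window = w)
  sv <- res$stroke_volume
  co <- cycle_average(sim_signal(sim, "Q_aortic_root"), w)
  # stroke volume x heart rate accounts for the cardiac output
  expect_equal(sv / sim$T, co, tolerance = 0.05)
  expect_gt(res$loop_area, 0)
})

test_that("Qp/Qs falls as the shunt loss coefficient rises (coupled model)", {
  ratios <- vapply(c(0.1, 0.25, 0.5), function(kk) {
    cfg <- default_config()
    cfg$leader$branches$shunt$k <- kk
    sim_averages(run_coupled(cfg))[["Qp_Qs"]]
  }, 0)
  expect_true(all(diff(ratios) < 0))
})
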