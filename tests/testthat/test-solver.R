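# RK4 integrator, macro-step subdivision, and the Windkessel analytic fixture.

test_that("subdivision tiles the macro step below the 100 us limit", {
  pol <- subdivision_policy(1e-4)
  s <- subdivide(1e-3, pol)
  expect_equal(s$n, 10); expect_equal(s$h, 1e-4)
  s <- subdivide(2.5e-4, pol)
  expect_equal(s$n, 3); expect_equal(s$h, 2.5e-4 / 3, tolerance = 1e-15)
  s <- subdivide(8e-5, pol)
  expect_equal(s$n, 1); expect_equal(s$h, 8e-5)
  # h never exceeds h_max; substeps sum exactly to dt
  for (dt in c(1e-5, 3.7e-4, 9.99e-4, 1e-3, 2e-3)) {
    s <- subdivide(dt, pol)
    expect_lte(s$h, pol$h_max * (1 + 1e-12))
    expect_equal(s$n * s$h, dt, tolerance = 1e-15)
  }
  expect_error(subdivide(0, pol), "positive")
})

test_that("rk4_step reproduces exact and frozen reference solutions", {
  # null dynamics
  expect_equal(rk4_step(function(t, y) 0 * y, c(1, 2), 0, 0.1), c(1, 2))
  # constant derivative is exact
  expect_equal(rk4_step(function(t, y) c(3, -2), c(0, 0), 0, 0.25),
               c(0.75, -0.5))
  # y' = -y, one step h = 0.1: RK4 polynomial 1 - h + h^2/2 - h^3/6 + h^4/24
  expect_equal(rk4_step(function(t, y) -y, 1, 0, 0.1), 0.9048375)
  # non-finite guard names the component
  expect_error(rk4_step(function(t, y) c(a = Inf), c(a = 1), 0, 0.1), "a")
})

test_that("global error shows fourth-order convergence on y' = -y", {
  integrate_to_1 <- function(h) {
    y <- 1
    for (i in seq_len(round(1 / h))) y <- rk4_step(function(t, y) -y, y, (i - 1) * h, h)
    y
  }
  e1 <- abs(integrate_to_1(0.1) - exp(-1))
  e2 <- abs(integrate_to_1(0.05) - exp(-1))
  ratio <- e1 / e2
  expect_gte(ratio, 12); expect_lte(ratio, 20)
})

test_that("one macro step equals two chained half steps on aligned grids", {
  fx <- make_windkessel_fixture()
  pol <- subdivision_policy(1e-4)
  one <- integrate_macro_step(function(t, P) fx$rhs(t, P), fx$P0, 0, 1e-3, pol)
  half <- integrate_macro_step(function(t, P) fx$rhs(t, P), fx$P0, 0, 5e-4, pol)
  two <- integrate_macro_step(function(t, P) fx$rhs(t, P), half, 5e-4, 5e-4, pol)
  expect_equal(one, two, tolerance = 1e-12)
})

test_that("windkessel fixture: DC limit, relaxation, analytic periodic solution", {
  fx <- make_windkessel_fixture(R = 0.5, C = 0.4, R_d = 1.2, T = 0.4,
                                amplitude = 30)
  # DC limit: constant inflow Q0 gives steady inlet pressure Q0 * (R + R_d)
  Q0 <- 10
  P <- 5
  for (i in 1:10000) P <- rk4_step(function(t, P) (Q0 - P / fx$params$R_d) / fx$params$C,
                                   P, 0, 1e-3)
  expect_equal(fx$params$R * Q0 + P, Q0 * (fx$params$R + fx$params$R_d),
               tolerance = 1e-6)
  # zero inflow: exponential decay with time constant R_d * C
  P <- 20
  tau <- fx$params$R_d * fx$params$C
  for (i in 1:100) P <- rk4_step(function(t, P) (0 - P / fx$params$R_d) / fx$params$C,
                                 P, 0, 1e-3)
  expect_equal(P, 20 * exp(-0.1 / tau), tolerance = 1e-9)
  # the closed form itself is periodic and satisfies the ODE at the seams
  expect_equal(fx$stored_pressure(0), fx$stored_pressure(fx$params$T),
               tolerance = 1e-12)
  # half-sine drive: subdivided RK4 vs closed form, < 0.1% at h = 100 us
  pol <- subdivision_policy(1e-4)
  P <- fx$P0
  ts <- seq(0, fx$params$T, by = 1e-3)
  err <- 0
  for (i in seq_along(ts)[-1]) {
    P <- integrate_macro_step(function(t, P) fx$rhs(t, P), P, ts[i - 1],
                              ts[i] - ts[i - 1], pol)
    err <- max(err, abs(P - fx$stored_pressure(ts[i])))
  }
  expect_lt(err / diff(range(fx$stored_pressure(ts))), 0.001)
})

test_that("compiled follower integrator agrees with the generic R solver", {
  cfg <- default_config()
  m <- build_norwood_lpm(cfg)
  q <- c(20, 3, 3, 3, 6, 5, 5)
  pol <- subdivision_policy(m$h_max)
  sR <- integrate_macro_step(function(t, y) lpm_rhs(y, q, t, m),
                             m$init, 0, 1e-3, pol)
  sC <- cardiocosim:::.lpm_integrate_cpp(as.numeric(m$init), 0, 1e-3, m$h_max,
                                         q, q, m$par)
  expect_equal(unname(sR), as.numeric(sC), tolerance = 1e-12)
})
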