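# Leader surrogate: steady flow solutions, implicit stepping, junction
# conservation, dissipativity, and the adaptive step controller.

test_that("steady_flow_solve handles linear, quadratic and degenerate branches", {
  expect_equal(steady_flow_solve(list(R = 1, k = 0), 0), 0)
  expect_equal(steady_flow_solve(list(R = 1, k = 0), 10), 10)
  expect_equal(steady_flow_solve(list(R = 1, k = 0.1), 10), 6.18034,
               tolerance = 1e-6)
  # sign symmetry and consistency with the forward relation
  for (dP in c(-25, -3, 0.7, 40)) {
    Q <- steady_flow_solve(list(R = 0.8, k = 0.05), dP)
    expect_equal(0.8 * Q + 0.05 * Q * abs(Q), dP, tolerance = 1e-10)
    expect_equal(sign(Q), sign(dP))
  }
  expect_error(steady_flow_solve(list(R = 0, k = 0), 5), "degenerate")
})

test_that("equal boundary pressures drive no flow", {
  ld <- build_leader(default_config())
  P <- rep(40, 7)
  st <- leader_init(ld, P)
  expect_equal(unname(st$Q), rep(0, 9), tolerance = 1e-9)
  st2 <- leader_step(st, P, 5e-4, ld)
  expect_equal(unname(st2$Q), rep(0, 9), tolerance = 1e-9)
  expect_lt(st2$resid, 1e-9)
})

test_that("held pressure gradient relaxes to the steady network solution", {
  ld <- build_leader(default_config())
  P <- c(55, 50, 50, 50, 50, 12, 12)
  steady <- leader_init(ld, P)   # steady solve under these pressures
  st <- leader_init(ld, rep(50, 7))   # start from zero flow
  st$Q[] <- 0
  for (i in 1:400) st <- leader_step(st, P, 1e-3, ld)
  expect_equal(unname(st$Q), unname(steady$Q), tolerance = 1e-4)
})

test_that("junction mass is conserved at every accepted step", {
  ld <- build_leader(default_config())
  P0 <- c(55, 50, 50, 50, 50, 12, 12)
  st <- leader_init(ld, P0)
  incidence <- function(Q) {
    from <- c(-1, 1, 2, 1, 1, 1, 2, 3, 3)
    to <- c(1, 2, -2, -3, -4, -5, 3, -6, -7)
    vapply(1:3, function(j)
      sum(Q[to == j]) - sum(Q[from == j]), 0)
  }
  for (i in 1:50) {
    P <- P0 + 5 * sin(2 * pi * i / 20) * c(1, 0.5, 0.5, 0.5, 0.5, 0.1, 0.1)
    st <- leader_step(st, P, 4e-4, ld)
    scale <- mean(abs(st$Q)) + 1e-9
    expect_lt(max(abs(incidence(st$Q))) / scale, ld$tol * 1.01)
  }
})

test_that("with equal pressures the branch kinetic energy is dissipated", {
  ld <- build_leader(default_config())
  P <- rep(30, 7)
  st <- leader_init(ld, P)
  st$Q[] <- c(20, 10, 5, 3, 3, 8, 6, 3, 3)   # artificial initial flows
  energy <- function(Q) sum(ld$L * Q^2) / 2
  e <- energy(st$Q)
  for (i in 1:200) {
    st <- leader_step(st, P, 1e-3, ld)
    e_new <- energy(st$Q)
    expect_lte(e_new, e + 1e-12)
    e <- e_new
  }
  expect_lt(e, 1e-6)
})

test_that("steady shunt flow decreases monotonically with its loss coefficient", {
  flows <- vapply(c(0.05, 0.1, 0.2, 0.4, 0.8), function(kk) {
    cfg <- default_config()
    cfg$leader$branches$shunt$k <- kk
    ld <- build_leader(cfg)
    st <- leader_init(ld, c(55, 50, 50, 50, 50, 12, 12))
    st$Q[["shunt"]]
  }, 0)
  expect_true(all(diff(flows) < 0))
})

test_that("adaptive controller shrinks, grows, and clamps", {
  tol <- 1e-3
  expect_equal(adapt_timestep(1e-3, 10 * tol, tol), 5e-4)   # shrink by half
  expect_equal(adapt_timestep(1e-5, 10 * tol, tol), 1e-5)   # clamped at dt_min
  expect_equal(adapt_timestep(2e-3, 0, tol), 2e-3)          # clamped at dt_max
  d <- adapt_timestep(4e-4, tol / 100, tol)
  expect_equal(d, 8e-4)                                     # grow capped at 2x
  # dead band: no change between tol/4 and tol
  expect_equal(adapt_timestep(4e-4, tol / 2, tol), 4e-4)
})

test_that("a full coupled run keeps dt within bounds with both step events", {
  sim <- default_sim()
  ld <- build_leader(sim$cfg)
  dts <- sim$signals$dt
  expect_gte(min(dts), ld$dt_min - 1e-15)
  expect_lte(max(dts), ld$dt_max + 1e-15)
  expect_gt(sum(diff(dts) < -1e-12), 0)   # shrink events
  expect_gt(sum(diff(dts) > 1e-12), 0)    # growth events
})
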