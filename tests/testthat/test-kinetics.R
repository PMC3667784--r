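test_that("the mass-action right-hand side matches closed forms", {
  net <- tiny_binding_network(kon = 0.3, koff = 0)
  v <- massActionRHS(net, c(A = 1, B = 1))
  expect_equal(unname(v["C"]), 0.3 * 1 * 1)
  expect_equal(unname(v["A"]), -0.3)
  ## empty state: zero derivative
  expect_true(all(massActionRHS(net, c(A = 0, B = 0, C = 0)) == 0))
  ## full network: surface MT1 is consumed from the start
  vfull <- massActionRHS(buildCoreNetwork(par0),
                         c(M14 = 100, T2 = 100, M2 = 100))
  expect_lt(vfull["M14"], 0)
})

test_that("RK4 reproduces exponential decay to 1e-6 relative accuracy", {
  net <- tiny_decay_network(k = 0.1)
  tr <- integrateRK4(net, c(ECM = 100), t_end = 10, dt = 0.01,
                     out_stride = 1000L)
  final <- concentrations(tr, "ECM")[nrow(tr@states), 1]
  expect_equal(unname(final), 100 * exp(-1), tolerance = 1e-6)
})

test_that("RK4 error on a linear system scales as O(dt^4)", {
  net <- tiny_decay_network(k = 0.5)
  err <- vapply(c(0.2, 0.1), function(dt) {
    tr <- integrateRK4(net, c(ECM = 1), t_end = 4, dt = dt,
                       out_stride = 1e6L)
    abs(concentrations(tr, "ECM")[nrow(tr@states), 1] - exp(-2))
  }, numeric(1))
  ## halving dt should reduce the error by ~16x
  expect_gt(err[1] / err[2], 12)
})

test_that("trajectories self-converge under step halving", {
  net <- buildCoreNetwork(par0)
  y0 <- c(M14 = 100, T2 = 100, M2 = 100)
  a <- integrateRK4(net, y0, t_end = 1000, dt = 0.02, out_stride = 1e6L)
  b <- integrateRK4(net, y0, t_end = 1000, dt = 0.01, out_stride = 1e6L)
  ya <- a@states[nrow(a@states), ]
  yb <- b@states[nrow(b@states), ]
  expect_lt(max(abs(ya - yb) / pmax(abs(yb), 1e-3)), 1e-6)
  expect_lt(auditStepSize(net, y0, t_end = 50, dt = 0.02), 1e-6)
})

test_that("closed-system monomer equivalents are conserved to 1e-8", {
  net <- buildCoreNetwork(par0)
  tr <- integrateRK4(net, c(M14 = 100, T2 = 100, M2 = 100), t_end = 10000,
                     dt = 0.05, out_stride = 200L)
  ct <- conservationTotals(tr)
  for (col in colnames(ct))
    expect_lt(diff(range(ct[, col])) / ct[1, col], 1e-8)
  ## output concentrations never negative
  expect_true(all(tr@states >= 0))
})

test_that("RK4 agrees with an independent adaptive integrator", {
  skip_if_not_installed("deSolve")
  ## binding equilibrium, hand-written ODEs
  kon <- 0.02; koff <- 0.05
  rhs_bind <- function(t, y, p)
    list(c(-kon * y[1] * y[2] + koff * y[3],
           -kon * y[1] * y[2] + koff * y[3],
           kon * y[1] * y[2] - koff * y[3]))
  ref <- deSolve::lsoda(c(10, 8, 0), seq(0, 50, 5), rhs_bind, NULL,
                        rtol = 1e-10, atol = 1e-12)
  tr <- integrateRK4(tiny_binding_network(kon, koff), c(A = 10, B = 8),
                     t_end = 50, dt = 0.005, out_stride = 1000L)
  got <- concentrations(tr)[-1, c("A", "B", "C")]
  expect_equal(unname(got), unname(ref[-1, 2:4]), tolerance = 1e-5)

  ## enzyme-substrate cycle with consumption, hand-written ODEs
  kon <- 0.01; koff <- 0.1; kcat <- 0.5
  rhs_enz <- function(t, y, p)
    list(c(-kon * y[1] * y[2] + (koff + kcat) * y[3],
           -kon * y[1] * y[2] + koff * y[3],
           kon * y[1] * y[2] - (koff + kcat) * y[3]))
  ref <- deSolve::lsoda(c(5, 100, 0), seq(0, 100, 10), rhs_enz, NULL,
                        rtol = 1e-10, atol = 1e-12)
  tr <- integrateRK4(tiny_enzyme_network(kon, koff, kcat),
                     c(E = 5, S = 100), t_end = 100, dt = 0.005,
                     out_stride = 2000L)
  got <- concentrations(tr)[-1, c("E", "S", "ES")]
  expect_equal(unname(got), unname(ref[-1, 2:4]), tolerance = 1e-5)
})

test_that("integration blow-ups are reported, not silently propagated", {
  ## an unstable step on a stiff decay produces a named error
  net <- tiny_decay_network(k = 50)
  expect_error(integrateRK4(net, c(ECM = 1), t_end = 500, dt = 1),
               "blow-up")
})

test_that("steady-state detection reports value, time and convergence", {
  net <- tiny_decay_network(k = 0.5)
  tr <- integrateRK4(net, c(ECM = 100), t_end = 100, dt = 0.01,
                     out_stride = 10L)
  ## decay to zero plateau: detected once the trailing window is flat
  ss <- detectSteadyState(tr, concentrations(tr, "ECM")[, 1],
                          rel_tol = 1e-4, window = 10)
  expect_true(ss$converged)
  expect_equal(ss$value, 0, tolerance = 1e-3)
  ## constant series converges at the first full window
  cs <- rep(5, length(tr@times))
  ss2 <- detectSteadyState(tr, cs, rel_tol = 1e-4, window = 10)
  expect_true(ss2$converged)
  expect_equal(ss2$value, 5)
  expect_equal(ss2$reached_at, tr@times[which(tr@times >= 10)[1]])
  ## drifting series: explicit non-convergence
  ss3 <- detectSteadyState(tr, tr@times, rel_tol = 1e-6, window = 10)
  expect_false(ss3$converged)
  expect_true(is.na(ss3$value))
  expect_error(detectSteadyState(tr, cs, window = 1000), "shorter")
})
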