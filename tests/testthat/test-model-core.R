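test_that("velocity law satisfies its monotonicity and range contracts", {
  p <- base_case_params(I_n = 10)
  r <- 10^seq(-4, 3, length.out = 60)
  v0 <- protrusion_velocity(r, 0, p)
  v5 <- protrusion_velocity(r, 5, p)
  expect_true(all(v0 >= 0 & v0 <= 1))
  expect_true(all(diff(v0) > 0))             # non-decreasing in r
  expect_true(all(v5 < v0))                  # inhibited by s when I_n > 0
  expect_gt(protrusion_velocity(1e8, 0, p), 1 - 1e-6)  # saturates to 1
  # independent symbolic evaluation on a small grid
  for (rr in c(0, 0.05, 1.3)) for (ss in c(0, 0.4, 2)) {
    expect_equal(protrusion_velocity(rr, ss, p),
                 (p$v0 + rr) / (p$v0 + rr + p$K_v) / (1 + p$I_n * ss),
                 tolerance = 1e-15)
  }
  expect_error(protrusion_velocity(-1, 0, p), "non-negative")
})

test_that("rhs satisfies the pinned structural contracts", {
  p <- base_case_params()
  st <- c(n = 0.8, s = 0.3, m = 0.3, x = 0.5, r = 0.4, p = 0.2)
  d <- model_rhs(st, p)
  expect_named(d, c("n", "s", "m", "x", "r", "p"))
  # m relaxes toward s: dm/dt = 0 exactly at m = s
  expect_equal(d[["m"]], 0, tolerance = 1e-15)
  # maturation term responds to f(m): raising E_s at fixed state raises ds/dt
  d2 <- model_rhs(st, update_params(p, E_s = 5))
  expect_gt(d2[["s"]], d[["s"]])
  # formation proportional to k_ecm * v
  dk <- model_rhs(st, update_params(p, k_ecm = 0.2))
  v <- protrusion_velocity(st[["r"]], st[["s"]], p)
  expect_equal(dk[["n"]] - d[["n"]], (0.2 - 0.1) * v, tolerance = 1e-12)
  # invariant violations are rejected
  expect_error(model_rhs(c(n = 0.1, s = 0, m = 0, x = 0.2, r = 0, p = 0), p),
               "x <= n")
  expect_error(model_rhs(c(n = 1, s = 0, m = 0, x = 0.2, r = 0, p = 0.3), p),
               "p <= x")
})

test_that("signaling quasi-steady solutions satisfy residual and subset bounds", {
  p <- base_case_params()
  for (n in c(0.4, 1.2, 2)) for (s in c(0, 0.3)) {
    qs <- signaling_quasi_steady(n, s, p)
    expect_gte(nrow(qs), 1)
    expect_true(all(qs$residual < 1e-10))
    expect_true(all(qs$p <= qs$x + 1e-12 & qs$x <= n + 1e-9))
    expect_equal(qs$v, protrusion_velocity(qs$r, s, p), tolerance = 1e-12)
  }
  # dark state
  q0 <- signaling_quasi_steady(0, 0, update_params(p, p0 = 0))
  expect_equal(unlist(q0[1, c("x", "r", "p")]), c(x = 0, r = 0, p = 0))
  # largest stable branch of r non-decreasing as n sweeps upward
  rs <- vapply(seq(0.05, 2, length.out = 25), function(n) {
    qs <- signaling_quasi_steady(n, 0.2, p)
    max(qs$r[qs$stable])
  }, numeric(1))
  expect_true(all(diff(rs) > -1e-9))
})

test_that("ODE integration is consistent with the fixed-point structure", {
  p <- base_case_params(k_ecm = 0.03)   # monostable low
  fp <- find_fixed_points(p)
  expect_identical(nrow(fp), 1L)
  tr <- integrate_ode(c(n = 0, s = 0, m = 0, x = 0, r = 0, p = 0), p,
                      t_end = 2000, dt_out = 5)
  expect_s3_class(tr, "adhesim_trajectory")
  expect_equal(tail(tr$v, 1), fp$v[1], tolerance = 1e-4)
  # subset ordering and non-negativity at every output time
  expect_true(all(tr$p <= tr$x + 1e-8 & tr$x <= tr$n + 1e-8))
  expect_true(all(tr[, c("n", "s", "m", "x", "r", "p")] >= -1e-10))
  expect_true(all(tr$v >= 0 & tr$v <= 1))
  # starting at the fixed point stays there
  st <- unlist(fp[1, c("n", "s", "m", "x", "r", "p")])
  tr2 <- integrate_ode(st, p, t_end = 200, dt_out = 1)
  expect_lt(max(abs(tail(tr2$v, 1) - fp$v[1])), 1e-6)
  # output grid does not affect dynamics
  tr3 <- integrate_ode(st * 1.05, p, t_end = 100, dt_out = 1)
  tr4 <- integrate_ode(st * 1.05, p, t_end = 100, dt_out = 0.5)
  expect_equal(unlist(tr3[nrow(tr3), -1]), unlist(tr4[nrow(tr4), -1]),
               tolerance = 1e-6)
})

test_that("with E_s = I_n = 0, C_s affects s but not the v trajectory", {
  st0 <- c(n = 0, s = 0, m = 0, x = 0, r = 0, p = 0)
  t1 <- integrate_ode(st0, base_case_params(C_s = 10), t_end = 400, dt_out = 2)
  t2 <- integrate_ode(st0, base_case_params(C_s = 2), t_end = 400, dt_out = 2)
  expect_equal(t1$v, t2$v, tolerance = 1e-6)
  expect_equal(t1$n, t2$n, tolerance = 1e-6)
  expect_gt(max(abs(t1$s - t2$s)), 1e-3)
})

test_that("k_ecm = 0 relaxes to the all-zero state", {
  p <- base_case_params(k_ecm = 0)
  st <- c(n = 0.5, s = 0.3, m = 0.3, x = 0.3, r = 0.3, p = 0.1)
  tr <- integrate_ode(st, p, t_end = 3000, dt_out = 10)
  expect_lt(max(unlist(tr[nrow(tr), c("n", "s", "m", "x", "r", "p")])), 1e-4)
})
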