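test_that("constant forcing from steady state stays flat", {
  m <- two_box_model(alpha_fs = exp(-2e-4), alpha_sf = exp(2e-4))
  traj <- simulate_diet(m, forcing_constant(0.42), t_end = 50, dt = 0.5)
  wide <- attr(traj, "wide")
  drift <- apply(wide, 2, function(y) max(abs(y - y[1])))
  expect_lt(max(drift), 1e-7)
})

test_that("step response of a two-box system matches the closed-form 2x2 solution", {
  mf <- 50; ms <- 2000; Fin <- 10; E <- 5
  m <- two_box_model(m_fast = mf, m_slow = ms, throughflow = Fin, exchange = E)
  traj <- simulate_diet(m, forcing_step(0, 1), t_end = 400, dt = 0.5)
  wide <- attr(traj, "wide"); tvec <- attr(traj, "times")

  # closed form: x(t) = x_inf + P diag(exp(lambda t)) P^-1 (x0 - x_inf)
  a <- -(Fin + E) / mf; b <- E / mf; cc <- E / ms; d <- -E / ms
  tr <- a + d; det <- a * d - b * cc
  lam <- c((tr + sqrt(tr^2 - 4 * det)) / 2, (tr - sqrt(tr^2 - 4 * det)) / 2)
  P <- cbind(c(b, lam[1] - a), c(b, lam[2] - a))
  Pinv <- solve(P)
  x0 <- c(0, 0); xinf <- c(1, 1)
  for (t in c(1, 10, 100, 400)) {
    xt <- xinf + P %*% diag(exp(lam * t)) %*% Pinv %*% (x0 - xinf)
    i <- which(tvec == t)
    expect_equal(unname(wide[i, c("fast", "slow")]), as.numeric(xt),
                 tolerance = 1e-6)
  }
})

test_that("single-box equilibration crosses 50% at residence_time * log(2)", {
  m <- one_box_model(mass = 100, flux = 10)   # tau = 10 d
  traj <- simulate_diet(m, forcing_step(0, 1), t_end = 60, dt = 0.01)
  tt <- time_to_progress(traj, "body", c(50, 95))
  expect_equal(tt[["t50"]], 10 * log(2), tolerance = 1e-3)
  expect_equal(tt[["t95"]], 10 * log(20), tolerance = 1e-3)
})

test_that("every box of the rat model approaches the new diet monotonically", {
  m <- rat_model("fitted_final")
  traj <- simulate_diet(m, forcing_step(0.42, -0.30), t_end = 400, dt = 0.5)
  wide <- attr(traj, "wide")
  for (b in colnames(wide)) {
    y <- wide[, b]
    s <- sign(y[length(y)] - y[1])
    expect_true(all(s * diff(y) > -1e-8), label = paste("monotone:", b))
  }
})

test_that("progress is undefined when the switch does not move the box", {
  m <- one_box_model()
  traj <- simulate_diet(m, forcing_step(0.42, 0.42), t_end = 10)
  expect_error(equilibration_progress(traj, "body"), "coincide")
})

test_that("t99 is grid-converged on the rat model", {
  m <- rat_model("fitted_final")
  f <- forcing_step(0.42, -0.30)
  t1 <- time_to_progress(simulate_diet(m, f, 520, dt = 0.1), "plasma", 99)
  t2 <- time_to_progress(simulate_diet(m, f, 520, dt = 0.05), "plasma", 99)
  expect_lt(abs(t1 - t2), 0.2)   # within 2 steps of the coarser grid
})

test_that("a single box behaves as the analytic one-pole filter", {
  tau <- 5; P <- 10
  m <- one_box_model(mass = 50, flux = 10)
  r <- sinusoid_response(m, "body", period = P)
  w <- 2 * pi * tau / P
  expect_equal(r$buffering_pct, 100 * (1 - 1 / sqrt(1 + w^2)),
               tolerance = 0.005)
  expect_equal(r$phase_shift_days, P / (2 * pi) * atan(w), tolerance = 0.02)
})

test_that("the delta response is linear in the forcing amplitude", {
  m <- two_box_model()
  r1 <- sinusoid_response(m, c("fast", "slow"), period = 50, amplitude = 1)
  r2 <- sinusoid_response(m, c("fast", "slow"), period = 50, amplitude = 2)
  expect_equal(r2$amplitude_box, 2 * r1$amplitude_box, tolerance = 1e-6)
  expect_equal(r2$buffering_pct, r1$buffering_pct, tolerance = 1e-6)
})

test_that("buffering and phase vanish in the long-period limit", {
  m <- two_box_model()   # slowest relaxation ~ 420 d
  r <- sinusoid_response(m, c("fast", "slow"), period = 4e4)
  expect_lt(max(r$buffering_pct), 1)
  expect_lt(max(r$phase_shift_days) / 4e4, 0.02)
})

test_that("bone is more buffered than plasma at every tested period", {
  m <- rat_model("fitted_final")
  for (P in c(10, 100)) {
    r <- sinusoid_response(m, c("plasma", "bone"), period = P)
    expect_gt(r$buffering_pct[r$compartment == "bone"],
              r$buffering_pct[r$compartment == "plasma"])
  }
})

test_that("simulation inputs are validated", {
  m <- one_box_model()
  expect_error(simulate_diet(m, forcing_constant(0), t_end = -1), "t_end")
  expect_error(simulate_diet(m, forcing_constant(0), t_end = 1, dt = 0), "dt")
  expect_error(forcing_sinusoid(0, 1, period = 0), "period")
  expect_error(forcing_sinusoid(0, -1, period = 10), "amplitude")
  expect_error(sinusoid_response(m, "body", period = 10, n_cycles = 1),
               "post-transient")
  expect_error(sinusoid_response(m, "nope", period = 10), "unknown finite box")
})
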