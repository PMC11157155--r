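test_that("with no fractionation every box sits at the diet composition", {
  m <- two_box_model()
  ss <- steady_vec(m, 0.73)
  expect_equal(unname(ss), rep(0.73, length(ss)), tolerance = 1e-12)

  withr::with_seed(11, {
    for (i in 1:5) {
      m <- random_box_model(n_boxes = sample(1:5, 1), delta_amp = 0)
      ss <- steady_vec(m, -0.2)
      expect_equal(unname(ss), rep(-0.2, length(ss)), tolerance = 1e-10)
    }
  })
})

test_that("a dead-end box is offset from its partner by the influx and efflux fractionation", {
  # split amplitude -0.42 / +0.42 on the exchange with the slow pool
  m <- two_box_model(alpha_fs = exp(-0.42e-3), alpha_sf = exp(0.42e-3))
  ss <- steady_vec(m, 0.42)
  expect_equal(ss[["slow"]] - ss[["fast"]], -0.84, tolerance = 1e-9)
  # the fast box still sits at the diet: the dead end returns what it gets
  expect_equal(ss[["fast"]], 0.42, tolerance = 1e-9)
})

test_that("linear solve agrees with brute-force ODE integration on random models", {
  withr::with_seed(101, {
    for (i in 1:10) {
      m <- random_box_model(n_boxes = sample(2:5, 1))
      ss <- steady_vec(m, 0.42)
      orc <- oracle_steady(m, 0.42)
      expect_lt(max(abs(ss[names(orc)] - orc)), 1e-6)
    }
  })
})

test_that("whole-organism isotope balance holds at steady state", {
  # flux-weighted composition of everything reaching the sinks = diet
  check_conservation <- function(m, diet) {
    ss <- steady_vec(m, diet)
    flx <- m$fluxes
    sinks <- m$compartments$name[m$compartments$role == "sink"]
    src <- m$compartments$name[m$compartments$role == "source"]
    out <- flx[flx$to %in% sinks, ]
    inn <- flx[flx$from %in% src, ]
    mean_out <- sum(out$rate * (ss[out$from] + out$cap_delta)) / sum(out$rate)
    mean_in <- sum(inn$rate * (diet + inn$cap_delta)) / sum(inn$rate)
    expect_equal(mean_out, mean_in, tolerance = 1e-8)
  }
  check_conservation(rat_model("fitted_final"), 0.42)
  withr::with_seed(7, {
    for (i in 1:5) check_conservation(random_box_model(4), -0.1)
  })
})

test_that("ratio-based bookkeeping cross-checks the linear delta formulation", {
  m <- rat_model("fitted_final")
  d1 <- steady_vec(m, 0.42)
  d2 <- steady_vec(m, 0.42, formulation = "ratio")
  # differs only by the linearisation error, O(Delta^2/1e3) per mil
  expect_lt(max(abs(d1 - d2)), 2e-3)
  expect_gt(max(abs(d1 - d2)), 0)
})

test_that("residence times are mass over total efflux", {
  rt <- residence_times(one_box_model(mass = 7, flux = 7))
  expect_equal(rt$residence_days, 1)
  m <- two_box_model(m_fast = 50, m_slow = 2000, throughflow = 10, exchange = 5)
  rt <- residence_times(m)
  expect_equal(rt$residence_days[rt$compartment == "fast"], 50 / 15)
  expect_equal(rt$residence_days[rt$compartment == "slow"], 400)
})

test_that("a no-return chain has relaxation times equal to each box's mass/efflux", {
  m <- chain_model(m_a = 120, m_b = 700, flux = 8)
  rel <- relaxation_times(m)
  expect_equal(rel$time_days, sort(c(120 / 8, 700 / 8)))
  # single box: unique relaxation time M/F
  rel1 <- relaxation_times(one_box_model(mass = 100, flux = 10))
  expect_equal(rel1$time_days, 10)
})

test_that("scaling all fluxes by k scales every timescale by 1/k and fixes the steady state", {
  m <- rat_model("fitted_final")
  k <- 3.7
  m2 <- m
  m2$fluxes$rate <- m2$fluxes$rate * k
  expect_equal(residence_times(m2)$residence_days,
               residence_times(m)$residence_days / k)
  expect_equal(relaxation_times(m2)$time_days,
               relaxation_times(m)$time_days / k, tolerance = 1e-10)
  expect_equal(steady_vec(m2, 0.42), steady_vec(m, 0.42), tolerance = 1e-10)
})

test_that("degenerate systems fail with explicit errors", {
  comps <- data.frame(name = c("diet", "pocket", "waste"),
                      mass = c(NA, 10, NA),
                      role = c("source", "internal", "sink"),
                      delta0 = c(0, 0, NA))
  flx <- data.frame(from = "diet", to = "pocket", rate = 1, alpha = 1)
  m <- box_model(comps, flx)   # structurally fine, dynamically a dead end
  expect_error(steady_state(m, 0.42), "dead-end finite box.*pocket")
  expect_error(residence_times(m), "dead-end finite box")
  expect_error(relaxation_times(m), "dead-end finite box")
})

test_that("an unbalanced model still solves but warns", {
  expect_warning(ss <- steady_state(rat_model("printed"), 0.42),
                 "not mass balanced")
  expect_true(all(is.finite(ss$delta)))
})
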