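test_that("axis construction validates its grid", {
  expect_error(sweep_axis_alpha("a", "x -> y", lo = 0.1, hi = 0.1, n = 3),
               "lo < hi")
  expect_error(sweep_axis_alpha("a", "x -> y", lo = 0, hi = 1, n = 1),
               "n >= 2")
  expect_error(sweep_axis_flux("f", "x -> y", lo = -1, hi = 10, n = 5),
               "log scale needs lo > 0")
  expect_error(sweep_axis_alpha("a", "x y", lo = 0, hi = 1, n = 3),
               "from -> to")
  ax <- sweep_axis_flux("f", "x -> y", lo = 1, hi = 100, n = 3)
  expect_equal(ax$values, c(1, 10, 100), tolerance = 1e-12)
})

test_that("a one-parameter fractionation sweep moves the target box monotonically", {
  ax <- sweep_axis_alpha("integ", "plasma -> integument",
                         lo = -0.5, hi = 0, n = 3)
  sw <- sweep_steady(rat_model("balanced"), list(ax), diet_delta = 0.42)
  expect_equal(nrow(sw$nodes), 3)
  integ <- sw$delta[, "integument"]
  expect_true(all(diff(integ) > 0))
  # the box tracks the fractionation, damped only by the feedback of the
  # integument loss on plasma itself
  expect_equal(diff(integ), diff(ax$values), tolerance = 0.2)
})

test_that("sweep nodes match one-at-a-time model application", {
  axes <- list(
    sweep_axis_alpha("split", c("intestine -> plasma", "plasma -> intestine"),
                     coef = c(1, -1), lo = -0.1, hi = 0.1, n = 3),
    sweep_axis_flux("bone", c("plasma -> bone", "bone -> plasma"),
                    coef = c(1, 1), lo = 10, hi = 100, n = 3)
  )
  m <- rat_model("balanced")
  sw <- sweep_steady(m, axes, diet_delta = 0.42)
  expect_equal(nrow(sw$nodes), 9)
  for (i in c(1, 5, 9)) {
    theta <- c(split = sw$nodes$split[i], bone = sw$nodes$bone[i])
    direct <- steady_vec(apply_sweep_axes(m, axes, theta), 0.42)
    expect_equal(sw$delta[i, ], direct[colnames(sw$delta)], tolerance = 1e-10)
  }
  # row-major: the last-declared axis varies fastest
  expect_equal(sw$nodes$split, rep(c(-0.1, 0, 0.1), each = 3))
})

test_that("an axis that breaks mass balance is rejected", {
  ax <- sweep_axis_flux("lopsided", "plasma -> bone", lo = 10, hi = 100, n = 3)
  expect_error(sweep_steady(rat_model("balanced"), list(ax), 0.42),
               "unbalanced model")
})

test_that("infinitely wide confidence intervals accept every node", {
  ax <- sweep_axis_alpha("renal", "kidney -> urine", lo = 0, hi = 1, n = 5)
  sw <- sweep_steady(rat_model("balanced"), list(ax), 0.42)
  obs <- rat_observations()
  obs$ci_halfwidth <- Inf
  fit <- ci_fit(sw, obs)
  expect_equal(fit$n_accepted, 5)
})

test_that("acceptance is monotone in the confidence width", {
  axes <- list(
    sweep_axis_alpha("split", c("intestine -> plasma", "plasma -> intestine"),
                     coef = c(1, -1), lo = -0.15, hi = 0.15, by = 0.025),
    sweep_axis_alpha("integ", "plasma -> integument", lo = -0.5, hi = 0,
                     by = 0.05)
  )
  sw <- sweep_steady(rat_model("balanced"), axes, 0.42)
  obs <- rat_observations()
  fit1 <- ci_fit(sw, obs)
  obs2 <- obs; obs2$ci_halfwidth <- 2 * obs2$ci_halfwidth
  fit2 <- ci_fit(sw, obs2)
  expect_true(all(!fit1$nodes$accepted | fit2$nodes$accepted))
  expect_gte(fit2$n_accepted, fit1$n_accepted)
})

test_that("refining the grid never loses an accepted coarse node", {
  mk <- function(by_split, by_integ) list(
    sweep_axis_alpha("split", c("intestine -> plasma", "plasma -> intestine"),
                     coef = c(1, -1), lo = -0.15, hi = 0.15, by = by_split),
    sweep_axis_alpha("integ", "plasma -> integument", lo = -0.5, hi = 0,
                     by = by_integ)
  )
  obs <- rat_observations()
  m <- rat_model("balanced")
  coarse <- ci_fit(sweep_steady(m, mk(0.05, 0.1), 0.42), obs)
  fine <- ci_fit(sweep_steady(m, mk(0.025, 0.05), 0.42), obs)
  expect_gt(fine$n_accepted, 0)
  acc_c <- coarse$nodes[coarse$nodes$accepted, c("split", "integ")]
  acc_f <- fine$nodes[fine$nodes$accepted, c("split", "integ")]
  kept <- vapply(seq_len(nrow(acc_c)), function(i) {
    any(abs(acc_f$split - acc_c$split[i]) < 1e-9 &
        abs(acc_f$integ - acc_c$integ[i]) < 1e-9)
  }, logical(1))
  expect_true(all(kept))
})

test_that("the representative node is an accepted grid node and glance summarises", {
  axes <- list(
    sweep_axis_alpha("split", c("intestine -> plasma", "plasma -> intestine"),
                     coef = c(1, -1), lo = -0.15, hi = 0.15, by = 0.025),
    sweep_axis_alpha("integ", "plasma -> integument", lo = -0.5, hi = 0,
                     by = 0.05)
  )
  sw <- sweep_steady(rat_model("balanced"), axes, 0.42)
  fit <- ci_fit(sw, rat_observations())
  expect_gt(fit$n_accepted, 0)
  i <- fit$representative$index
  expect_true(fit$nodes$accepted[i])
  expect_equal(unname(fit$representative$values),
               as.numeric(fit$nodes[i, c("split", "integ")]))
  g <- glance(fit)
  expect_equal(g$n_accepted, fit$n_accepted)
  expect_lte(g$representative_worst_excess, 0)
  td <- tidy(fit)
  expect_equal(td$axis, c("split", "integ"))
  expect_true(all(td$lo <= td$hi))
})

test_that("fit diagnostics survive an empty accepted set", {
  ax <- sweep_axis_alpha("renal", "kidney -> urine", lo = 0, hi = 1, n = 3)
  sw <- sweep_steady(rat_model("balanced"), list(ax), 0.42)
  obs <- rat_observations()
  obs$ci_halfwidth <- 1e-6
  fit <- ci_fit(sw, obs)
  expect_equal(fit$n_accepted, 0)
  expect_null(fit$representative)
  expect_true(all(fit$nodes$worst_excess > 0))
  expect_true(all(nchar(fit$nodes$worst_obs) > 0))
  expect_error(fitted_model(fit), "empty")
  expect_true(all(is.na(tidy(fit)$lo)))
})

test_that("observation handling: exclusions, unmatched names, empty tables", {
  ax <- sweep_axis_alpha("renal", "kidney -> urine", lo = 0, hi = 1, n = 3)
  sw <- sweep_steady(rat_model("balanced"), list(ax), 0.42)
  obs <- rat_observations()
  obs$compartment[obs$compartment == "muscle"] <- "tail"
  expect_warning(fit <- ci_fit(sw, obs), "unmatched.*tail")
  expect_false("tail" %in% fit$observations$compartment)
  expect_false("kidney" %in% fit$observations$compartment)  # excluded
  all_excluded <- rat_observations()
  all_excluded$excluded_from_fit <- TRUE
  expect_error(ci_fit(sw, all_excluded), "no constrained observations")
})

test_that("renal fractionation barely shifts constrained steady states", {
  m <- rat_model("fitted_final")
  sens <- renal_sensitivity(m, rat_observations(), c(0, 0.44, 1))
  expect_equal(sens$max_abs_change[1], 0)
  expect_lt(sens$max_abs_change[3], 0.03)   # smallest observed half-width
  expect_true(all(diff(sens$max_abs_change) > 0))
})

test_that("a known parameter node is recovered from low-noise synthetic data", {
  axes <- list(
    sweep_axis_alpha("split", c("intestine -> plasma", "plasma -> intestine"),
                     coef = c(1, -1), lo = -0.15, hi = 0.15, by = 0.025),
    sweep_axis_alpha("integ", "plasma -> integument", lo = -0.5, hi = 0,
                     by = 0.05)
  )
  m <- rat_model("balanced")
  truth <- c(split = -0.05, integ = -0.2)
  m_true <- apply_sweep_axes(m, axes, truth)
  spec <- synthetic_spec(m_true, sigma = 0.002, n = 3, seed = 99)
  obs <- generate_observations(spec)
  obs$ci_halfwidth <- 0.01    # noise sigma well below the acceptance band
  sw <- sweep_steady(m, axes, 0.42)
  fit <- ci_fit(sw, obs)
  hit <- fit$nodes$accepted &
    abs(fit$nodes$split - truth[["split"]]) < 1e-9 &
    abs(fit$nodes$integ - truth[["integ"]]) < 1e-9
  expect_true(any(hit))
})

test_that("diet-switch calibration separates slow from fast bone exchange", {
  ax <- sweep_axis_flux("bone", c("plasma -> bone", "bone -> plasma"),
                        coef = c(1, 1), lo = 1.1, hi = 231.1, n = 5)
  spec <- rat_synthetic_spec(seed = 5, sample_days = c(32, 54))
  ser <- generate_switch_series(spec, "bone", "supplier", "lucerne",
                                days = c(0, 32, 54))
  cal <- calibrate_switch(rat_model("fitted_final"), ax, ser,
                          delta_before = 0.42, delta_after = -0.30)
  res <- 3212 / cal$value
  expect_false(any(cal$accepted[res < 50]))    # fast-turnover bone rejected
  expect_true(any(cal$accepted[res > 200]))    # slow bone accepted
})
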