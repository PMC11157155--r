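#' Simulate the delta-66-Zn dynamics under a dietary forcing
#'
#' Integrates the linear delta-dynamics of the model (box masses constant,
#' source composition prescribed by the forcing, sinks excluded) with a
#' stiff-capable solver. The rat network spans timescales from 0.02 to
#' roughly 700 days, so the solver ([deSolve::ode()] with `lsoda`, which
#' switches to an implicit backward-differentiation scheme on stiff stretches)
#' matters; fixed explicit stepping at the output resolution would not be
#' stable at a useful step size.
#'
#' @param model A balanced [box_model()].
#' @param forcing A [forcing_constant()], [forcing_step()] or
#'   [forcing_sinusoid()].
#' @param t_end End of the simulation, days (> 0).
#' @param dt Output grid spacing, days (> 0; default 0.1).
#' @param init Initial per-box deltas: `NULL` (default) starts at the steady
#'   state of the initial diet composition, `"delta0"` uses the compartments'
#'   declared `delta0`, or a named numeric vector over the finite boxes.
#' @param rtol,atol Solver tolerances.
#' @return A `zn_trajectory`: a long tibble `time`, `compartment`, `delta`
#'   (the source's prescribed trajectory included), carrying the model and
#'   forcing as attributes.
#' @examples
#' m <- rat_model("fitted_final")
#' traj <- simulate_diet(m, forcing_step(0.42, -0.30), t_end = 60)
#' time_to_progress(traj, "plasma", 50)
#' @export
simulate_diet <- function(model, forcing, t_end, dt = 0.1, init = NULL,
                          rtol = 1e-8, atol = 1e-10) {
  stopifnot(inherits(model, "box_model"), inherits(forcing, "diet_forcing"))
  if (!is.numeric(t_end) || t_end <= 0) stop("t_end must be > 0")
  if (!is.numeric(dt) || dt <= 0) stop("dt must be > 0")
  check_solvable(model)
  warn_if_unbalanced(model)

  sys <- delta_system(model)
  y0 <- resolve_init(model, sys, forcing, init)
  times <- seq(0, t_end, by = dt)
  if (times[length(times)] < t_end) times <- c(times, t_end)

  rhs <- function(t, y, p) {
    list(sys$A %*% y + sys$b_const + sys$e_src * forcing_delta(forcing, t))
  }

  # integrate piecewise across a step discontinuity inside (0, t_end)
  sd <- if (forcing$kind == "step") forcing$params$switch_day else 0
  if (forcing$kind == "step" && sd > 0 && sd < t_end) {
    t1 <- unique(c(times[times <= sd], sd))
    t2 <- unique(c(sd, times[times >= sd]))
    o1 <- deSolve::ode(y0, t1, rhs, NULL, method = "lsoda",
                       rtol = rtol, atol = atol)
    y1 <- o1[nrow(o1), -1]
    o2 <- deSolve::ode(y1, t2, rhs, NULL, method = "lsoda",
                       rtol = rtol, atol = atol)
    keep1 <- o1[, 1] %in% times & !(o1[, 1] %in% o2[, 1])
    out <- rbind(o1[keep1, , drop = FALSE],
                 o2[o2[, 1] %in% times, , drop = FALSE])
  } else {
    out <- deSolve::ode(y0, times, rhs, NULL, method = "lsoda",
                        rtol = rtol, atol = atol)
  }

  wide <- as.matrix(out[, -1, drop = FALSE])
  colnames(wide) <- sys$boxes
  tvec <- as.numeric(out[, 1])
  src <- source_name(model)
  long <- tibble::tibble(
    time = rep(tvec, times = length(sys$boxes) + length(src)),
    compartment = rep(c(src, sys$boxes), each = length(tvec)),
    delta = c(if (length(src)) forcing_delta(forcing, tvec),
              as.numeric(wide))
  )
  structure(long,
            class = c("zn_trajectory", class(long)),
            model = model, forcing = forcing,
            times = tvec, wide = wide)
}

resolve_init <- function(model, sys, forcing, init) {
  fin <- sys$boxes
  if (is.null(init)) {
    return(solve_steady(sys, forcing_initial_delta(forcing)))
  }
  if (identical(init, "delta0")) {
    d0 <- model$compartments$delta0[match(fin, model$compartments$name)]
    if (anyNA(d0)) {
      stop("delta0 missing for finite box(es): ",
           paste(fin[is.na(d0)], collapse = ", "))
    }
    return(stats::setNames(d0, fin))
  }
  if (is.numeric(init) && !is.null(names(init)) && all(fin %in% names(init))) {
    return(init[fin])
  }
  stop("`init` must be NULL, \"delta0\", or a named vector over all finite boxes")
}

#' @export
print.zn_trajectory <- function(x, ...) {
  f <- attr(x, "forcing")
  tvec <- attr(x, "times")
  cat("<zn_trajectory> ", length(unique(x$compartment)), " compartments, t = ",
      min(tvec), "..", max(tvec), " d (", length(tvec), " points)\n", sep = "")
  print(f)
  NextMethod()
}

#' Equilibration progress after a diet switch
#'
#' After a step change of diet composition, each box relaxes from its old
#' steady state toward the new one. Progress is the signed fractional
#' approach `100 * (delta(t) - delta(0)) / (delta(inf) - delta(0))`, where
#' `delta(inf)` is the analytic steady state of the post-switch diet; boxes
#' with non-monotone trajectories can transiently exceed 100.
#'
#' @param trajectory A `zn_trajectory` produced with a step forcing.
#' @param box Name of a finite box.
#' @return A tibble `time`, `progress` (percent).
#' @export
equilibration_progress <- function(trajectory, box) {
  stopifnot(inherits(trajectory, "zn_trajectory"))
  forcing <- attr(trajectory, "forcing")
  if (forcing$kind != "step") {
    stop("equilibration progress is defined for step forcings only")
  }
  wide <- attr(trajectory, "wide")
  if (!box %in% colnames(wide)) stop("unknown finite box: ", box)
  model <- attr(trajectory, "model")
  sys <- delta_system(model)
  dinf <- solve_steady(sys, forcing$params$delta_after)[[box]]
  d0 <- wide[1, box]
  if (abs(dinf - d0) < 1e-12) {
    stop("initial and final steady states coincide for box '", box,
         "': progress undefined")
  }
  tibble::tibble(
    time = attr(trajectory, "times"),
    progress = 100 * (wide[, box] - d0) / (dinf - d0)
  )
}

#' First time a box reaches a given equilibration progress
#'
#' @inheritParams equilibration_progress
#' @param p Target progress percentage(s), e.g. `c(50, 95, 99)`.
#' @return A named numeric vector of days (first crossing, linearly
#'   interpolated between output grid points; `NA` with a warning if the
#'   target is not reached within the simulated window).
#' @export
time_to_progress <- function(trajectory, box, p) {
  prg <- equilibration_progress(trajectory, box)
  vapply(p, function(target) {
    idx <- which(prg$progress >= target)[1]
    if (is.na(idx)) {
      warning("progress ", target, "% not reached by t = ",
              max(prg$time), " d for box '", box, "'", call. = FALSE)
      return(NA_real_)
    }
    if (idx == 1) return(prg$time[1])
    t0 <- prg$time[idx - 1]; t1 <- prg$time[idx]
    p0 <- prg$progress[idx - 1]; p1 <- prg$progress[idx]
    t0 + (target - p0) / (p1 - p0) * (t1 - t0)
  }, numeric(1), USE.NAMES = FALSE) -> out
  stats::setNames(out, paste0("t", p))
}

#' Diet-switch equilibration summary for every box
#'
#' Convenience wrapper producing the time-to-x-percent table for a step diet
#' switch: one simulation, then first-crossing times per finite box.
#'
#' @param model A balanced [box_model()].
#' @param delta_before,delta_after Diet compositions around the switch.
#' @param p Progress targets in percent.
#' @param t_end Simulation length; defaults to 5.2 times the slowest
#'   relaxation time (enough to observe a 99% crossing of the slowest box).
#' @param dt Output step, days.
#' @return A tibble with `compartment` and one `t<p>` column per target.
#' @export
equilibration_table <- function(model, delta_before, delta_after,
                                p = c(50, 95, 99), t_end = NULL, dt = 0.1) {
  if (is.null(t_end)) {
    t_end <- ceiling(5.2 * max(relaxation_times(model)$time_days))
  }
  traj <- simulate_diet(model, forcing_step(delta_before, delta_after),
                        t_end = t_end, dt = dt)
  fin <- colnames(attr(traj, "wide"))
  purrr::map_dfr(fin, function(b) {
    tibble::as_tibble_row(c(list(compartment = b),
                            as.list(time_to_progress(traj, b, p))))
  })
}

#' Transfer of a sinusoidal dietary signal to body compartments
#'
#' Drives the model with a sinusoidal diet delta-66-Zn, discards transients
#' (by default the simulation spans five times the slowest whole-system
#' relaxation time), and measures for each requested box over the last full
#' cycle: the residual amplitude, the *buffering* (percent of the dietary
#' amplitude lost) and the *phase shift* (lag, in days, of the box's local
#' maximum behind the diet's local maximum). By linearity of the
#' delta-dynamics, buffering and phase are independent of the forcing
#' amplitude.
#'
#' @param model A balanced [box_model()].
#' @param boxes Finite box name(s) to analyse.
#' @param period Forcing period, days.
#' @param amplitude Diet half-amplitude, per mil (default 1; immaterial for
#'   buffering/phase).
#' @param delta_mean Mean diet composition (default 0.42).
#' @param n_cycles Total number of forcing cycles simulated; the last one is
#'   analysed. Default: enough cycles to cover five times the slowest
#'   relaxation time, plus one. Must be at least 2 so that a full
#'   post-transient cycle exists.
#' @param dt Output step over the analysis cycle (default `period / 2000`).
#' @param keep_trajectory Attach the analysed last-cycle trajectory as an
#'   attribute (used by [plot_sinusoid_transfer()]).
#' @return A tibble `compartment`, `period`, `amplitude_diet`,
#'   `amplitude_box`, `buffering_pct`, `phase_shift_days`.
#' @examples
#' \donttest{
#' sinusoid_response(rat_model("fitted_final"), c("plasma", "bone"), period = 10)
#' }
#' @export
sinusoid_response <- function(model, boxes, period, amplitude = 1,
                              delta_mean = 0.42, n_cycles = NULL,
                              dt = NULL, keep_trajectory = FALSE) {
  stopifnot(inherits(model, "box_model"))
  if (!is.numeric(period) || period <= 0) stop("period must be > 0")
  if (!is.numeric(amplitude) || amplitude <= 0) {
    stop("amplitude must be > 0 to measure buffering")
  }
  tau_max <- max(relaxation_times(model)$time_days)
  if (is.null(n_cycles)) n_cycles <- ceiling(5 * tau_max / period) + 1
  if (n_cycles < 2) {
    stop("fewer than one post-transient full cycle: n_cycles must be >= 2")
  }
  sys <- delta_system(model)
  bad <- setdiff(boxes, sys$boxes)
  if (length(bad)) stop("unknown finite box(es): ", paste(bad, collapse = ", "))

  forcing <- forcing_sinusoid(delta_mean, amplitude, period)
  rhs <- function(t, y, p) {
    list(sys$A %*% y + sys$b_const + sys$e_src * forcing_delta(forcing, t))
  }
  y0 <- solve_steady(sys, delta_mean)
  t_start <- (n_cycles - 1) * period
  t_end <- n_cycles * period

  # coarse pass through the transient, fine output over the analysis cycle
  if (t_start > 0) {
    t1 <- unique(c(seq(0, t_start, by = max(period / 50, t_start / 5000)),
                   t_start))
    o1 <- deSolve::ode(y0, t1, rhs, NULL, method = "lsoda",
                       rtol = 1e-8, atol = 1e-10)
    y0 <- o1[nrow(o1), -1]
  }
  if (is.null(dt)) dt <- period / 2000
  t2 <- seq(t_start, t_end, by = dt)
  o2 <- deSolve::ode(y0, t2, rhs, NULL, method = "lsoda",
                     rtol = 1e-8, atol = 1e-10)
  tvec <- o2[, 1]
  diet <- forcing_delta(forcing, tvec)
  t_diet_max <- tvec[which.max(diet)]

  res <- purrr::map_dfr(boxes, function(b) {
    y <- o2[, b]
    amp_box <- (max(y) - min(y)) / 2
    t_box_max <- tvec[which.max(y)]
    tibble::tibble(
      compartment = b,
      period = period,
      amplitude_diet = amplitude,
      amplitude_box = amp_box,
      buffering_pct = 100 * (1 - amp_box / amplitude),
      phase_shift_days = (t_box_max - t_diet_max) %% period
    )
  })
  if (keep_trajectory) {
    wide <- as.matrix(o2[, -1, drop = FALSE])
    attr(res, "cycle") <- tibble::tibble(
      time = rep(tvec, 1 + ncol(wide)),
      compartment = rep(c("diet", colnames(wide)), each = length(tvec)),
      delta = c(diet, as.numeric(wide))
    )
    attr(res, "forcing") <- forcing
  }
  res
}
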