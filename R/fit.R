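#' Confidence-interval fit over a swept parameter grid
#'
#' The fitting criterion of the sweep approach: a parameter node is accepted
#' if and only if its predicted steady state falls inside the observed
#' confidence interval of every constrained compartment
#' (`|predicted - observed| <= ci_halfwidth`). No likelihood is involved;
#' the accepted set is reported together with per-axis marginal accepted
#' ranges and a representative node (the coordinate-wise median of the
#' accepted nodes, snapped to the nearest accepted node in normalised axis
#' units). An empty accepted set is a valid result: per-node diagnostics
#' identify the worst-violated observation.
#'
#' @param sweep A `zn_sweep` from [sweep_steady()].
#' @param observations An observation table (see [read_observations()]);
#'   rows with `excluded_from_fit = TRUE` are skipped, rows naming unknown
#'   compartments are dropped with a warning. An observation on the source
#'   compartment is compared against the sweep's fixed `diet_delta`.
#' @return A `zn_fit` object with elements `nodes` (axis values plus
#'   `accepted`, `worst_obs`, `worst_excess`), `marginals`, `representative`
#'   (`values`, `index`, `steady`, `model`), `n_accepted` and
#'   `accepted_fraction`. [generics::tidy()] returns the marginal ranges and
#'   [generics::glance()] the one-row summary.
#' @examples
#' ax <- sweep_axis_alpha("renal", edges = "kidney -> urine", lo = 0, hi = 1, n = 5)
#' sw <- sweep_steady(rat_model("balanced"), list(ax), diet_delta = 0.42)
#' fit <- ci_fit(sw, rat_observations())
#' glance(fit)
#' @export
ci_fit <- function(sweep, observations) {
  stopifnot(inherits(sweep, "zn_sweep"))
  obs <- tibble::as_tibble(observations)
  need <- c("compartment", "delta66Zn", "ci_halfwidth")
  if (!all(need %in% names(obs))) {
    stop("observations need columns: ", paste(need, collapse = ", "))
  }
  if (!"excluded_from_fit" %in% names(obs)) obs$excluded_from_fit <- FALSE
  obs <- obs[!obs$excluded_from_fit, ]

  src <- source_name(sweep$model)
  known <- c(sweep$boxes, src)
  unmatched <- setdiff(obs$compartment, known)
  if (length(unmatched)) {
    warning("unmatched observation compartment(s) dropped: ",
            paste(unmatched, collapse = ", "), call. = FALSE)
    obs <- obs[obs$compartment %in% known, ]
  }
  if (!nrow(obs)) stop("no constrained observations")
  if (any(obs$ci_halfwidth <= 0)) stop("ci_halfwidth must be > 0")

  n_nodes <- nrow(sweep$nodes)
  excess <- matrix(NA_real_, n_nodes, nrow(obs),
                   dimnames = list(NULL, obs$compartment))
  for (i in seq_len(nrow(obs))) {
    comp <- obs$compartment[i]
    pred <- if (length(src) && comp == src) {
      rep(sweep$diet_delta, n_nodes)
    } else {
      sweep$delta[, comp]
    }
    excess[, i] <- abs(pred - obs$delta66Zn[i]) - obs$ci_halfwidth[i]
  }
  worst_i <- max.col(excess, ties.method = "first")
  worst_excess <- excess[cbind(seq_len(n_nodes), worst_i)]
  accepted <- worst_excess <= 0

  nodes <- dplyr::bind_cols(
    sweep$nodes,
    tibble::tibble(accepted = accepted,
                   worst_obs = obs$compartment[worst_i],
                   worst_excess = worst_excess)
  )

  axis_names <- vapply(sweep$axes, `[[`, "", "name")
  marginals <- purrr::map_dfr(axis_names, function(a) {
    v <- sweep$nodes[[a]][accepted]
    tibble::tibble(axis = a,
                   lo = if (length(v)) min(v) else NA_real_,
                   hi = if (length(v)) max(v) else NA_real_)
  })

  representative <- NULL
  if (any(accepted)) {
    acc_vals <- as.matrix(sweep$nodes[accepted, axis_names, drop = FALSE])
    med <- apply(acc_vals, 2, stats::median)
    span <- vapply(sweep$axes, function(a) diff(range(a$values)), numeric(1))
    norm <- base::sweep(acc_vals, 2, med, `-`)
    norm <- base::sweep(norm, 2, span, `/`)
    best <- which.min(rowSums(norm^2))     # first minimum: deterministic
    index <- which(accepted)[best]
    values <- stats::setNames(as.numeric(
      sweep$nodes[index, axis_names]), axis_names)
    m_rep <- apply_sweep_axes(sweep$model, sweep$axes, values)
    representative <- list(
      index = index, values = values, model = m_rep,
      steady = steady_state(m_rep, sweep$diet_delta)
    )
  }

  structure(list(nodes = nodes, observations = obs, axes = sweep$axes,
                 model = sweep$model, diet_delta = sweep$diet_delta,
                 marginals = marginals, representative = representative,
                 n_nodes = n_nodes, n_accepted = sum(accepted),
                 accepted_fraction = mean(accepted)),
            class = "zn_fit")
}

#' @export
print.zn_fit <- function(x, ...) {
  cat("<zn_fit> ", x$n_accepted, " / ", format(x$n_nodes, big.mark = ","),
      " nodes accepted (", signif(100 * x$accepted_fraction, 3), "%)\n",
      sep = "")
  if (is.null(x$representative)) {
    worst <- x$nodes[which.min(x$nodes$worst_excess), ]
    cat("empty accepted set; least-violated node misses '",
        worst$worst_obs, "' by ", signif(worst$worst_excess, 3),
        " permil\n", sep = "")
  } else {
    cat("representative node:\n")
    print(x$representative$values)
  }
  invisible(x)
}

#' Extract the representative fitted model
#'
#' @param fit A `zn_fit` with a non-empty accepted set.
#' @return A [box_model()] at the representative accepted node.
#' @export
fitted_model <- function(fit) {
  stopifnot(inherits(fit, "zn_fit"))
  if (is.null(fit$representative)) stop("accepted set is empty")
  fit$representative$model
}

#' Sensitivity of the steady state to renal isotope fractionation
#'
#' Urinary zinc loss is a small flux (7 of 1000 ug/day in the rat), so even
#' per-mil-scale fractionation on it barely shifts body compositions. This
#' quantifies that: for each candidate fractionation amplitude, the maximum
#' absolute change of any constrained compartment's steady state relative to
#' a zero-fractionation baseline.
#'
#' @param model A balanced [box_model()].
#' @param observations Observation table defining the constrained boxes
#'   (exclusions respected).
#' @param amplitudes Per-mil fractionation amplitudes to test (0..1).
#' @param edge The renal loss edge, default `"kidney -> urine"`.
#' @return A tibble `amplitude`, `max_abs_change`, `worst_box`.
#' @export
renal_sensitivity <- function(model, observations, amplitudes,
                              edge = "kidney -> urine") {
  stopifnot(inherits(model, "box_model"))
  obs <- tibble::as_tibble(observations)
  if (!"excluded_from_fit" %in% names(obs)) obs$excluded_from_fit <- FALSE
  fin <- finite_boxes(model)
  boxes <- intersect(obs$compartment[!obs$excluded_from_fit], fin)
  if (!length(boxes)) stop("no constrained finite boxes")
  ax <- sweep_axis_alpha("renal", edges = edge, lo = -1, hi = 1, n = 2)
  base <- steady_state(apply_axis(model, ax, 0), diet_delta = 0.42)
  base_v <- stats::setNames(base$delta, base$compartment)[boxes]
  purrr::map_dfr(amplitudes, function(a) {
    ss <- steady_state(apply_axis(model, ax, a), diet_delta = 0.42)
    v <- stats::setNames(ss$delta, ss$compartment)[boxes]
    ch <- abs(v - base_v)
    tibble::tibble(amplitude = a,
                   max_abs_change = max(ch),
                   worst_box = boxes[which.max(ch)])
  })
}

#' Calibrate a flux axis against a diet-switch time series
#'
#' Second-stage filter for parameters that steady-state compositions cannot
#' constrain (a dead-end exchange flux leaves the steady state untouched but
#' controls how fast the pool re-equilibrates after a diet change). Each
#' candidate axis value is simulated through the step switch and accepted if
#' every observed (day, compartment) point lies within its confidence
#' half-width of the prediction.
#'
#' @param model A balanced [box_model()].
#' @param axis A [sweep_axis_flux()] (e.g. the plasma/bone exchange).
#' @param series A tibble `day`, `compartment`, `delta66Zn`, `ci_halfwidth`
#'   of observations after the switch (see [generate_switch_series()]).
#' @param delta_before,delta_after Diet compositions around the switch.
#' @param switch_day Day of the switch (default 0).
#' @param dt Simulation output step, days.
#' @return A tibble `value`, `accepted`, `worst_excess` with one row per
#'   axis grid point.
#' @export
calibrate_switch <- function(model, axis, series, delta_before, delta_after,
                             switch_day = 0, dt = 0.1) {
  stopifnot(inherits(model, "box_model"), inherits(axis, "sweep_axis"))
  ser <- tibble::as_tibble(series)
  need <- c("day", "compartment", "delta66Zn", "ci_halfwidth")
  if (!all(need %in% names(ser))) {
    stop("series needs columns: ", paste(need, collapse = ", "))
  }
  t_end <- max(ser$day) + dt
  forcing <- forcing_step(delta_before, delta_after, switch_day)
  purrr::map_dfr(axis$values, function(v) {
    m <- apply_axis(model, axis, v)
    traj <- simulate_diet(m, forcing, t_end = t_end, dt = dt)
    wide <- attr(traj, "wide"); tvec <- attr(traj, "times")
    pred <- vapply(seq_len(nrow(ser)), function(i) {
      stats::approx(tvec, wide[, ser$compartment[i]], xout = ser$day[i])$y
    }, numeric(1))
    excess <- abs(pred - ser$delta66Zn) - ser$ci_halfwidth
    tibble::tibble(value = v,
                   accepted = all(excess <= 0),
                   worst_excess = max(excess))
  })
}
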