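#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a simulated trajectory
#'
#' One line per compartment of delta-66-Zn against time (the diet's
#' prescribed trajectory included).
#'
#' @param object A `zn_trajectory`.
#' @param boxes Optional subset of compartments.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zn_trajectory <- function(object, boxes = NULL, ...) {
  df <- tibble::as_tibble(object)
  if (!is.null(boxes)) df <- dplyr::filter(df, .data$compartment %in% boxes)
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$delta,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (days)",
                  y = expression(delta^{66} * "Zn (‰)"),
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the marginal acceptance profile of a CI fit
#'
#' For each sweep axis, the fraction of accepted nodes at each grid value —
#' a quick view of which parameter values the observations allow.
#'
#' @param object A `zn_fit`.
#' @param ... Unused.
#' @return A ggplot (facet per axis).
#' @export
autoplot.zn_fit <- function(object, ...) {
  axis_names <- vapply(object$axes, `[[`, "", "name")
  df <- purrr::map_dfr(axis_names, function(a) {
    object$nodes |>
      dplyr::group_by(value = .data[[a]]) |>
      dplyr::summarise(accepted_fraction = mean(.data$accepted),
                       .groups = "drop") |>
      dplyr::mutate(axis = a)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$value, .data$accepted_fraction)) +
    ggplot2::geom_col(width = NULL) +
    ggplot2::facet_wrap(~axis, scales = "free_x") +
    ggplot2::labs(x = "axis value", y = "fraction of nodes accepted") +
    ggplot2::theme_minimal()
}

#' Plot equilibration progress after a diet switch
#'
#' Progress (%) of each box toward its new steady state, on a log time axis.
#'
#' @param model A balanced [box_model()].
#' @param delta_before,delta_after Diet compositions around the switch.
#' @param boxes Boxes to show (default all finite).
#' @param t_end,dt Simulation window and output step.
#' @return A ggplot.
#' @export
plot_equilibration <- function(model, delta_before, delta_after,
                               boxes = NULL, t_end = NULL, dt = 0.5) {
  if (is.null(t_end)) {
    t_end <- ceiling(5.2 * max(relaxation_times(model)$time_days))
  }
  traj <- simulate_diet(model, forcing_step(delta_before, delta_after),
                        t_end = t_end, dt = dt)
  if (is.null(boxes)) boxes <- colnames(attr(traj, "wide"))
  df <- purrr::map_dfr(boxes, function(b) {
    dplyr::mutate(equilibration_progress(traj, b), compartment = b)
  })
  ggplot2::ggplot(df, ggplot2::aes(.data$time, .data$progress,
                                   colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "days since diet switch", y = "equilibration progress (%)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot the transfer of a sinusoidal dietary signal
#'
#' The post-transient cycle of selected boxes against the diet signal, shown
#' as deviation from the mean composition, annotated with buffering and
#' phase shift.
#'
#' @param model A balanced [box_model()].
#' @param period Forcing period, days.
#' @param boxes Boxes to show.
#' @param amplitude Diet half-amplitude, per mil.
#' @param delta_mean Mean diet composition.
#' @return A ggplot.
#' @export
plot_sinusoid_transfer <- function(model, period, boxes = c("plasma", "bone"),
                                   amplitude = 1, delta_mean = 0.42) {
  res <- sinusoid_response(model, boxes, period, amplitude = amplitude,
                           delta_mean = delta_mean, keep_trajectory = TRUE)
  cyc <- attr(res, "cycle")
  cyc <- dplyr::filter(cyc, .data$compartment %in% c("diet", boxes))
  cyc <- dplyr::mutate(cyc, time = .data$time - min(.data$time),
                       deviation = .data$delta - delta_mean)
  lab <- paste0(res$compartment, ": ", signif(res$buffering_pct, 3),
                "% buffered, +", signif(res$phase_shift_days, 3), " d",
                collapse = "\n")
  ggplot2::ggplot(cyc, ggplot2::aes(.data$time, .data$deviation,
                                    colour = .data$compartment)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time within cycle (days)",
                  y = expression(Delta * delta^{66} * "Zn from mean (‰)"),
                  colour = NULL, subtitle = lab) +
    ggplot2::theme_minimal()
}
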