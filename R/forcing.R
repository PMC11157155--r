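#' Dietary forcing functions
#'
#' A diet forcing prescribes the source (diet) delta-66-Zn through time:
#' constant, a step switch between two diets, or a sinusoid emulating
#' seasonal variation of dietary zinc sources.
#'
#' @param delta,delta_before,delta_after,delta_mean Compositions in per mil
#'   vs JMC-Lyon.
#' @param switch_day Day of the step switch (default 0).
#' @param amplitude Sinusoid half-amplitude in per mil (>= 0).
#' @param period Sinusoid period in days (> 0).
#' @return An object of class `diet_forcing`.
#' @examples
#' forcing_step(0.42, -0.30)
#' forcing_sinusoid(delta_mean = 0.42, amplitude = 1, period = 365)
#' @export
forcing_constant <- function(delta) {
  stopifnot(is.numeric(delta), length(delta) == 1)
  new_forcing("constant", list(delta = delta))
}

#' @rdname forcing_constant
#' @export
forcing_step <- function(delta_before, delta_after, switch_day = 0) {
  stopifnot(is.numeric(delta_before), is.numeric(delta_after),
            is.numeric(switch_day), switch_day >= 0)
  new_forcing("step", list(delta_before = delta_before,
                           delta_after = delta_after,
                           switch_day = switch_day))
}

#' @rdname forcing_constant
#' @export
forcing_sinusoid <- function(delta_mean, amplitude, period) {
  if (!is.numeric(period) || period <= 0) stop("period must be > 0")
  if (!is.numeric(amplitude) || amplitude < 0) stop("amplitude must be >= 0")
  new_forcing("sinusoid", list(delta_mean = delta_mean,
                               amplitude = amplitude, period = period))
}

new_forcing <- function(kind, params) {
  structure(list(kind = kind, params = params), class = "diet_forcing")
}

#' Evaluate a diet forcing
#'
#' @param forcing A `diet_forcing`.
#' @param t Time(s) in days.
#' @return Diet delta-66-Zn at `t` (vectorised).
#' @export
forcing_delta <- function(forcing, t) {
  stopifnot(inherits(forcing, "diet_forcing"))
  p <- forcing$params
  switch(forcing$kind,
    constant = rep(p$delta, length(t)),
    step = ifelse(t < p$switch_day, p$delta_before, p$delta_after),
    sinusoid = p$delta_mean + p$amplitude * sin(2 * pi * t / p$period)
  )
}

# diet value used for the default initial (pre-forcing) steady state
forcing_initial_delta <- function(forcing) {
  p <- forcing$params
  switch(forcing$kind,
    constant = p$delta,
    step = p$delta_before,
    sinusoid = p$delta_mean
  )
}

#' @export
print.diet_forcing <- function(x, ...) {
  p <- x$params
  desc <- switch(x$kind,
    constant = paste0("constant delta = ", p$delta, " permil"),
    step = paste0("step ", p$delta_before, " -> ", p$delta_after,
                  " permil at day ", p$switch_day),
    sinusoid = paste0("sinusoid mean ", p$delta_mean, " permil, amplitude ",
                      p$amplitude, " permil, period ", p$period, " d")
  )
  cat("<diet_forcing> ", desc, "\n", sep = "")
  invisible(x)
}
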