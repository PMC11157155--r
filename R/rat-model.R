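#' The reference rat zinc cycle
#'
#' Returns the whole-body zinc box model of a 370 g adult rat: 12
#' compartments (diet source; intestine, plasma, liver, red blood cells,
#' muscle, bone, kidney, integument; feces and urine day-loss accumulators;
#' waste sink) connected by 19 first-order fluxes with per-flux isotope
#' fractionation.
#'
#' @param variant One of:
#' \describe{
#'   \item{`"fitted_final"`}{The fitted configuration used for all dynamic
#'     predictions: bone exchange 10.69953 ug/day each way (300.2-day bone
#'     residence), plasma-to-integument loss 4 ug/day (696.8-day integument
#'     residence), renal fractionation alpha = 1.00044, and intestinal
#'     absorption/endogenous-loss and integument-transport fractionations at
#'     the representative node of the default observation-constrained sweep.}
#'   \item{`"balanced"`}{Literature-style fluxes with the muscle efflux
#'     corrected to 227 ug/day so that every box balances: 14-day bone
#'     residence, 70-day integument residence, neutral fractionation on the
#'     swept edges. The natural starting point for [sweep_steady()].}
#'   \item{`"printed"`}{The flux table as published, with muscle efflux
#'     900 ug/day. Not mass balanced (plasma +673, muscle -673 ug/day);
#'     shipped so the inconsistency can be audited with [mass_balance()].}
#' }
#' @return A [box_model()].
#' @examples
#' residence_times(rat_model("fitted_final"))
#' mass_balance(rat_model("printed"))
#' @export
rat_model <- function(variant = c("fitted_final", "balanced", "printed")) {
  variant <- match.arg(variant)
  path <- system.file("extdata", paste0("rat_zn_", variant, ".yml"),
                      package = "znbox", mustWork = TRUE)
  read_box_model(path)
}

#' Observed rat tissue delta-66-Zn values and their confidence bands
#'
#' The steady-state observation table for rats at isotopic equilibrium with
#' their supplier feed: per-compartment delta-66-Zn (per mil vs JMC-Lyon),
#' confidence half-width (2 SE; conservatively 0.2 per mil for boxes with a
#' single specimen) and replicate count. Kidney is present but flagged
#' `excluded_from_fit`: it behaves as an exchange interface and its fit is
#' excluded from model calibration. Urine was not measured and is absent.
#'
#' @return A tibble `compartment`, `delta66Zn`, `ci_halfwidth`, `n`,
#'   `excluded_from_fit`.
#' @examples
#' rat_observations()
#' @export
rat_observations <- function() {
  path <- system.file("extdata", "rat_observations.csv",
                      package = "znbox", mustWork = TRUE)
  read_observations(path)
}

#' Read or write an observation table
#'
#' Observation tables are CSV files with header
#' `compartment,delta66Zn,ci_halfwidth,n` (an optional logical
#' `excluded_from_fit` column marks constraints to skip during fitting).
#'
#' @param path File path.
#' @return `read_observations()` returns a tibble; `write_observations()`
#'   returns `path` invisibly.
#' @export
read_observations <- function(path) {
  obs <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("compartment", "delta66Zn", "ci_halfwidth")
  if (!all(need %in% names(obs))) {
    stop("observation table needs columns: ", paste(need, collapse = ", "))
  }
  if (!"n" %in% names(obs)) obs$n <- NA_integer_
  if (!"excluded_from_fit" %in% names(obs)) obs$excluded_from_fit <- FALSE
  if (any(!is.na(obs$ci_halfwidth) & obs$ci_halfwidth <= 0)) {
    stop("ci_halfwidth must be > 0")
  }
  obs
}

#' @rdname read_observations
#' @param observations A tibble in the observation-table schema.
#' @export
write_observations <- function(observations, path) {
  readr::write_csv(observations, path, progress = FALSE)
  invisible(path)
}
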