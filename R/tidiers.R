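#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy the per-axis marginal accepted ranges of a CI fit
#'
#' @param x A `zn_fit`.
#' @param ... Unused.
#' @return A tibble `axis`, `lo`, `hi` (NA when the accepted set is empty).
#' @export
tidy.zn_fit <- function(x, ...) x$marginals

#' One-row summary of a CI fit
#'
#' @param x A `zn_fit`.
#' @param ... Unused.
#' @return A tibble with node counts, accepted fraction and (if non-empty)
#'   the representative node's worst residual.
#' @export
glance.zn_fit <- function(x, ...) {
  worst <- if (is.null(x$representative)) {
    min(x$nodes$worst_excess)
  } else {
    x$nodes$worst_excess[x$representative$index]
  }
  tibble::tibble(
    n_nodes = x$n_nodes,
    n_accepted = x$n_accepted,
    accepted_fraction = x$accepted_fraction,
    representative_worst_excess = worst
  )
}

#' Tidy a box model's flux table
#'
#' @param x A `box_model`.
#' @param ... Unused.
#' @return The flux tibble (`from`, `to`, `rate`, `alpha`, `cap_delta`).
#' @export
tidy.box_model <- function(x, ...) x$fluxes

#' One-row structural summary of a box model
#'
#' @param x A `box_model`.
#' @param ... Unused.
#' @return A tibble with compartment/flux counts, total throughflow and the
#'   balanced flag.
#' @export
glance.box_model <- function(x, ...) {
  bal <- mass_balance(x)
  src <- source_name(x)
  intake <- if (length(src)) sum(x$fluxes$rate[x$fluxes$from == src]) else NA_real_
  tibble::tibble(
    n_compartments = nrow(x$compartments),
    n_finite = length(finite_boxes(x)),
    n_fluxes = nrow(x$fluxes),
    dietary_intake = intake,
    balanced = all(bal$balanced)
  )
}
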