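# Linear delta-dynamics of a box model.
#
# Each flux from i to j carries material with composition delta_i + Delta_ij
# (per-mil bookkeeping, linear in delta). For finite box i with mass M_i:
#
#   M_i d(delta_i)/dt = sum_in F (delta_src + Delta_in)
#                     - sum_out F (delta_i + Delta_out)
#
# which is delta' = A delta + b_const + e_src * delta_diet(t). The system
# matrix A depends on fluxes and masses only; all fractionation terms live in
# the constant vector. The exact ratio formulation (fluxes carry R * alpha)
# is also linear and is provided as a cross-check mode; the two differ by
# O(Delta^2 / 1e6) per mil.
delta_system <- function(model, formulation = c("delta", "ratio")) {
  formulation <- match.arg(formulation)
  fin <- finite_boxes(model)
  n <- length(fin)
  comps <- model$compartments
  M <- stats::setNames(comps$mass[match(fin, comps$name)], fin)
  src <- source_name(model)

  A <- matrix(0, n, n, dimnames = list(fin, fin))
  b_const <- stats::setNames(numeric(n), fin)
  e_src <- stats::setNames(numeric(n), fin)

  flx <- model$fluxes
  for (i in seq_len(nrow(flx))) {
    from <- flx$from[i]; to <- flx$to[i]
    r <- flx$rate[i]; D <- flx$cap_delta[i]; a <- flx$alpha[i]
    w <- if (formulation == "ratio") a else 1
    if (to %in% fin) {
      if (from %in% fin) {
        A[to, from] <- A[to, from] + r * w / M[to]
      } else if (length(src) && from == src) {
        e_src[to] <- e_src[to] + r * w / M[to]
      }
      if (formulation == "delta") b_const[to] <- b_const[to] + r * D / M[to]
    }
    if (from %in% fin) {
      A[from, from] <- A[from, from] - r * w / M[from]
      if (formulation == "delta") b_const[from] <- b_const[from] - r * D / M[from]
    }
  }
  list(A = A, b_const = b_const, e_src = e_src, boxes = fin, M = M,
       formulation = formulation)
}

# stop early on structurally singular systems (spec'd error cases)
check_solvable <- function(model) {
  fin <- finite_boxes(model)
  flx <- model$fluxes
  eff <- vapply(fin, function(b) sum(flx$rate[flx$from == b]), numeric(1))
  if (any(eff <= 0)) {
    stop("dead-end finite box (zero efflux): ",
         paste(fin[eff <= 0], collapse = ", "))
  }
  invisible(TRUE)
}

warn_if_unbalanced <- function(model, tol = 1e-6) {
  bal <- mass_balance(model, tol)
  if (!all(bal$balanced)) {
    warning("model is not mass balanced (",
            paste0(bal$compartment[!bal$balanced], ": ",
                   signif(bal$imbalance[!bal$balanced], 4), collapse = ", "),
            " ug/day); steady state assumes constant box masses",
            call. = FALSE)
  }
  invisible(bal)
}

#' Analytic steady-state isotope compositions
#'
#' Solves the linear delta-balance system for every finite box under a fixed
#' diet composition. With all fractionation coefficients equal to 1 every box
#' collapses exactly to the diet value; dead-end boxes that exchange with a
#' single partner sit at the partner's composition offset by the influx and
#' efflux fractionations.
#'
#' @param model A balanced [box_model()]. An imbalance beyond `tol` raises a
#'   warning (the linear system is still solvable).
#' @param diet_delta Prescribed source delta-66-Zn (per mil vs JMC-Lyon).
#' @param formulation `"delta"` (default, linear per-mil bookkeeping) or
#'   `"ratio"` (exact isotope-ratio bookkeeping, provided as a cross-check;
#'   the two agree to O(Delta^2/1e6)).
#' @param tol Mass-balance warning tolerance in micrograms per day.
#' @return A tibble `compartment`, `delta` with the source first (at
#'   `diet_delta`) followed by every finite box in declaration order.
#' @examples
#' steady_state(rat_model("fitted_final"), diet_delta = 0.42)
#' @export
steady_state <- function(model, diet_delta, formulation = c("delta", "ratio"),
                         tol = 1e-6) {
  stopifnot(inherits(model, "box_model"), is.numeric(diet_delta),
            length(diet_delta) == 1)
  formulation <- match.arg(formulation)
  check_solvable(model)
  warn_if_unbalanced(model, tol)
  sys <- delta_system(model, formulation)
  d <- solve_steady(sys, diet_delta)
  src <- source_name(model)
  tibble::tibble(
    compartment = c(src, sys$boxes),
    delta = c(if (length(src)) diet_delta, unname(d))
  )
}

# core solve, reused by the sweep machinery; returns named vector over boxes
solve_steady <- function(sys, diet_delta) {
  if (sys$formulation == "ratio") {
    r_diet <- diet_delta / 1000 + 1
    rhs <- -sys$e_src * r_diet
    R <- tryCatch(solve(sys$A, rhs), error = function(e) {
      stop("singular steady-state system: ", conditionMessage(e), call. = FALSE)
    })
    return(stats::setNames(1000 * (R - 1), sys$boxes))
  }
  rhs <- -(sys$b_const + sys$e_src * diet_delta)
  d <- tryCatch(solve(sys$A, rhs), error = function(e) {
    stop("singular steady-state system: ", conditionMessage(e), call. = FALSE)
  })
  stats::setNames(as.numeric(d), sys$boxes)
}

#' Mean residence time of zinc in each compartment
#'
#' Residence time is compartment mass divided by total efflux: the mean time
#' a zinc atom spends in the pool under first-order kinetics. Note that this
#' is the mean residence time, not mass/efflux scaled by log(2): the
#' half-life label often attached to these numbers in the physiology
#' literature refers to the same mass/efflux quantity.
#'
#' @param model A [box_model()].
#' @return A tibble `compartment`, `mass`, `efflux`, `residence_days` for
#'   every finite box. A finite box with zero efflux is an error
#'   ("dead-end finite box").
#' @examples
#' residence_times(rat_model("fitted_final"))
#' @export
residence_times <- function(model) {
  stopifnot(inherits(model, "box_model"))
  check_solvable(model)
  fin <- finite_boxes(model)
  comps <- model$compartments
  flx <- model$fluxes
  M <- comps$mass[match(fin, comps$name)]
  eff <- vapply(fin, function(b) sum(flx$rate[flx$from == b]), numeric(1))
  tibble::tibble(
    compartment = fin, mass = M, efflux = unname(eff),
    residence_days = M / unname(eff)
  )
}

#' Whole-system relaxation times
#'
#' The linear delta-dynamics relax toward steady state as a sum of
#' exponentials whose characteristic times are the negative reciprocal
#' eigenvalues of the system matrix (source held fixed, sinks excluded).
#' These times describe the dynamic behaviour of the network as a whole, not
#' of any one reservoir, although each mode is usually dominated by one box;
#' the dominant box (largest eigenvector component) is reported per mode.
#'
#' @param model A balanced [box_model()].
#' @return A tibble `mode`, `time_days`, `dominant_box`, sorted by increasing
#'   relaxation time. Complex eigenvalue pairs (possible in strongly cyclic
#'   networks) are reported through their real part, which sets the decay
#'   time. A non-negative eigenvalue is an error ("system not dissipative").
#' @examples
#' relaxation_times(rat_model("fitted_final"))
#' @export
relaxation_times <- function(model) {
  stopifnot(inherits(model, "box_model"))
  check_solvable(model)
  sys <- delta_system(model)
  eg <- eigen(sys$A)
  re <- Re(eg$values)
  dom <- sys$boxes[apply(abs(eg$vectors), 2, which.max)]
  if (any(re >= 0)) {
    i <- which(re >= 0)[1]
    stop("system not dissipative: eigenvalue ", signif(eg$values[i], 6),
         " with dominant box '", dom[i], "'")
  }
  tau <- -1 / re
  ord <- order(tau)
  tibble::tibble(
    mode = seq_along(tau),
    time_days = tau[ord],
    dominant_box = dom[ord]
  )
}
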