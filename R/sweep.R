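#' Sweep axes: parameter dimensions for the grid sweep
#'
#' An axis moves one model parameter (a fractionation amplitude or a flux
#' rate) over a grid while keeping the model physically valid. Flux axes act
#' on groups of edges so that mass balance is preserved by construction:
#' an exchange pair (both directions move together) or a loss route with
#' explicit compensation on other edges. Fractionation axes set the per-mil
#' fractionation `Delta` of their edges to `coef * theta`, which expresses
#' the split convention (amplitude attributed with opposite signs to influx
#' and efflux) as `coef = c(1, -1)`.
#'
#' @param name Axis name (becomes a column in the node grid).
#' @param edges Character vector of edges, each `"from -> to"`.
#' @param coef Numeric coefficient per edge. For a fractionation axis,
#'   `Delta_edge = coef * theta` (per mil). For a flux axis, the first edge
#'   takes the rate `theta` and every edge moves by
#'   `coef * (theta - base_rate_of_first_edge)` from its base rate.
#' @param lo,hi Axis range (`lo < hi`).
#' @param n Number of grid points (>= 2), or `NULL` if `by` is given.
#' @param by Grid step (fractionation axes); overrides `n`.
#' @param scale `"linear"` or `"log"` spacing (flux axes default to log).
#' @return A `sweep_axis` object.
#' @examples
#' sweep_axis_alpha("absorption_split",
#'   edges = c("intestine -> plasma", "plasma -> intestine"),
#'   coef = c(1, -1), lo = -0.3, hi = 0.3, by = 0.025)
#' @export
sweep_axis_alpha <- function(name, edges, coef = rep(1, length(edges)),
                             lo, hi, n = NULL, by = NULL, scale = "linear") {
  new_sweep_axis(name, "alpha", edges, coef, lo, hi, n, by, scale)
}

#' @rdname sweep_axis_alpha
#' @export
sweep_axis_flux <- function(name, edges, coef = rep(1, length(edges)),
                            lo, hi, n = 15, by = NULL, scale = "log") {
  new_sweep_axis(name, "flux", edges, coef, lo, hi, n, by, scale)
}

new_sweep_axis <- function(name, kind, edges, coef, lo, hi, n, by, scale) {
  stopifnot(is.character(name), length(name) == 1,
            is.character(edges), length(edges) >= 1,
            length(coef) == length(edges))
  if (!is.numeric(lo) || !is.numeric(hi) || lo >= hi) {
    stop("axis '", name, "': need lo < hi (zero-width axes are rejected)")
  }
  scale <- match.arg(scale, c("linear", "log"))
  if (!is.null(by)) {
    if (by <= 0) stop("axis '", name, "': by must be > 0")
    values <- seq(lo, hi, by = by)
  } else {
    if (is.null(n) || n < 2) stop("axis '", name, "': need n >= 2 grid points")
    values <- if (scale == "log") {
      if (lo <= 0) stop("axis '", name, "': log scale needs lo > 0")
      exp(seq(log(lo), log(hi), length.out = n))
    } else {
      seq(lo, hi, length.out = n)
    }
  }
  parts <- strsplit(edges, "\\s*->\\s*")
  if (any(lengths(parts) != 2)) {
    stop("axis '", name, "': edges must be written \"from -> to\"")
  }
  structure(list(name = name, kind = kind,
                 from = vapply(parts, `[`, "", 1),
                 to = vapply(parts, `[`, "", 2),
                 coef = as.numeric(coef), values = values),
            class = "sweep_axis")
}

#' @export
print.sweep_axis <- function(x, ...) {
  cat("<sweep_axis> ", x$name, " (", x$kind, "): ",
      length(x$values), " points in [", min(x$values), ", ", max(x$values),
      "] over ", paste(flux_key(x$from, x$to), collapse = ", "), "\n", sep = "")
  invisible(x)
}

# set one axis to a scalar value on a model
apply_axis <- function(model, axis, theta) {
  flx <- model$fluxes
  key <- flux_key(flx$from, flx$to)
  idx <- match(flux_key(axis$from, axis$to), key)
  if (anyNA(idx)) {
    stop("axis '", axis$name, "' references missing edge(s): ",
         paste(flux_key(axis$from, axis$to)[is.na(idx)], collapse = ", "))
  }
  if (axis$kind == "flux") {
    base <- flx$rate[idx]
    new <- base + axis$coef * (theta - base[1])
    if (any(new < 0)) {
      stop("axis '", axis$name, "' drives a flux negative at theta = ", theta)
    }
    flx$rate[idx] <- new
  } else {
    D <- axis$coef * theta
    flx$cap_delta[idx] <- D
    flx$alpha[idx] <- exp(D / 1000)
  }
  model$fluxes <- flx
  model
}

#' Apply sweep axes to a model at given parameter values
#'
#' @param model A [box_model()].
#' @param axes A list of [sweep_axis_alpha()] / [sweep_axis_flux()] objects.
#' @param theta Named numeric vector of axis values (names matching axis
#'   names), e.g. a row of a sweep's node grid.
#' @return The modified [box_model()].
#' @export
apply_sweep_axes <- function(model, axes, theta) {
  axes <- as_axis_list(axes)
  for (ax in axes) {
    if (!ax$name %in% names(theta)) stop("theta misses axis: ", ax$name)
    model <- apply_axis(model, ax, theta[[ax$name]])
  }
  model
}

as_axis_list <- function(axes) {
  if (inherits(axes, "sweep_axis")) axes <- list(axes)
  stopifnot(all(vapply(axes, inherits, TRUE, "sweep_axis")))
  nm <- vapply(axes, `[[`, "", "name")
  if (anyDuplicated(nm)) stop("duplicate axis names: ",
                              paste(nm[duplicated(nm)], collapse = ", "))
  axes
}

#' Default sweep axes for the rat zinc cycle
#'
#' The five poorly constrained parameters of the rat model, each swept over
#' its literature range: the split fractionation amplitude of intestinal
#' absorption vs endogenous loss (half-amplitude applied `+s` on
#' intestine-to-plasma and `-s` on plasma-to-intestine, 0.025 per mil
#' steps), the plasma-to-integument fractionation (-0.5..0 per mil, 0.05
#' steps), the plasma/bone exchange flux (1.1..231.1 ug/day, i.e. bone
#' residence 14..2900 days, 15 log-spaced points), the plasma-to-integument
#' loss flux (4..180 ug/day, 15 log-spaced points; endogenous loss and the
#' fecal return are co-adjusted to preserve balance, the low-loss end
#' corresponding to slow, 700-day integument turnover) and the renal
#' fractionation (0..1 per mil, 0.05 steps).
#'
#' @return A list of five `sweep_axis` objects, suitable for
#'   [sweep_steady()] on `rat_model("balanced")`.
#' @export
rat_axes <- function() {
  list(
    sweep_axis_alpha("absorption_split",
      edges = c("intestine -> plasma", "plasma -> intestine"),
      coef = c(1, -1), lo = -0.30, hi = 0.30, by = 0.025),
    sweep_axis_alpha("integument_alpha",
      edges = "plasma -> integument", lo = -0.50, hi = 0, by = 0.05),
    sweep_axis_flux("bone_exchange",
      edges = c("plasma -> bone", "bone -> plasma"),
      coef = c(1, 1), lo = 1.1, hi = 231.1, n = 15, scale = "log"),
    sweep_axis_flux("integument_loss",
      edges = c("plasma -> integument", "integument -> waste",
                "plasma -> intestine", "intestine -> feces",
                "feces -> waste"),
      coef = c(1, 1, -1, -1, -1), lo = 4, hi = 180, n = 15, scale = "log"),
    sweep_axis_alpha("renal_alpha",
      edges = "kidney -> urine", lo = 0, hi = 1, by = 0.05)
  )
}

#' Sweep the parameter space and solve every node's steady state
#'
#' Builds the Cartesian grid over the supplied axes (row-major in declaration
#' order: the last axis varies fastest) and computes the analytic steady
#' state at every node. The computation exploits the structure of the linear
#' delta-dynamics: the system matrix depends only on fluxes, and the
#' right-hand side is affine in the per-mil fractionations, so one matrix
#' factorisation per flux-axis combination is solved against all
#' fractionation combinations at once. This is exact, not an approximation,
#' and keeps million-node grids tractable.
#'
#' @param model A balanced [box_model()] (typically `rat_model("balanced")`).
#' @param axes List of sweep axes; see [rat_axes()] for the defaults used on
#'   the rat cycle.
#' @param diet_delta Diet composition applied at every node.
#' @param warn_nodes Emit a warning when the grid exceeds this many nodes
#'   (default 1e6).
#' @return A `zn_sweep` object: `nodes` (tibble of axis values), `delta`
#'   (matrix, nodes x finite boxes), plus the axes, base model and
#'   `diet_delta`.
#' @examples
#' ax <- sweep_axis_alpha("renal", edges = "kidney -> urine", lo = 0, hi = 1, n = 3)
#' sw <- sweep_steady(rat_model("balanced"), list(ax), diet_delta = 0.42)
#' head(as_tibble(sw))
#' @export
sweep_steady <- function(model, axes, diet_delta, warn_nodes = 1e6) {
  stopifnot(inherits(model, "box_model"))
  axes <- as_axis_list(axes)
  check_solvable(model)
  bal <- mass_balance(model)
  if (!all(bal$balanced)) {
    stop("sweep requires a balanced base model; imbalanced: ",
         paste(bal$compartment[!bal$balanced], collapse = ", "))
  }

  sizes <- vapply(axes, function(a) length(a$values), integer(1))
  n_nodes <- prod(sizes)
  if (n_nodes > warn_nodes) {
    warning("sweep grid has ", format(n_nodes, big.mark = ","),
            " nodes", call. = FALSE)
  }
  nodes <- grid_row_major(axes)

  is_flux <- vapply(axes, function(a) a$kind == "flux", logical(1))
  flux_axes <- axes[is_flux]
  alpha_axes <- axes[!is_flux]
  # disjointness keeps the affine RHS decomposition valid
  akeys <- unlist(lapply(alpha_axes, function(a) flux_key(a$from, a$to)))
  if (anyDuplicated(akeys)) {
    stop("fractionation axes must act on disjoint edges")
  }

  flux_grid <- grid_row_major(flux_axes)    # 1 row if no flux axes
  alpha_grid <- grid_row_major(alpha_axes)
  n_f <- nrow(flux_grid); n_a <- nrow(alpha_grid)

  # per-node combo indices, consistent with row-major node enumeration
  fidx <- combo_index(nodes, flux_grid)
  aidx <- combo_index(nodes, alpha_grid)

  fin <- finite_boxes(model)
  delta <- matrix(NA_real_, n_nodes, length(fin),
                  dimnames = list(NULL, fin))
  theta_a <- as.matrix(alpha_grid)          # n_a x (n alpha axes), 0 cols ok

  for (f in seq_len(n_f)) {
    m_f <- model
    for (j in seq_along(flux_axes)) {
      m_f <- apply_axis(m_f, flux_axes[[j]], flux_grid[[j]][f])
    }
    bal_f <- mass_balance(m_f)
    if (!all(bal_f$balanced)) {
      stop("flux axes produce an unbalanced model at node (",
           paste(names(flux_grid), "=", unlist(flux_grid[f, ]),
                 collapse = ", "), "); imbalanced: ",
           paste(bal_f$compartment[!bal_f$balanced], collapse = ", "))
    }
    # zero the alpha-axis fractionations, then add them back affinely
    m_0 <- m_f
    for (ax in alpha_axes) m_0 <- apply_axis(m_0, ax, 0)
    sys <- delta_system(m_0)
    b0 <- sys$b_const + sys$e_src * diet_delta
    D <- vapply(alpha_axes, function(ax) alpha_sensitivity(m_f, sys, ax),
                numeric(length(fin)))          # n_fin x n alpha axes
    B <- matrix(b0, length(fin), n_a)
    if (length(alpha_axes)) B <- B + D %*% t(theta_a)
    S <- solve(sys$A, -B)                      # n_fin x n_a
    rows <- which(fidx == f)
    delta[rows, ] <- t(S)[aidx[rows], , drop = FALSE]
  }

  structure(list(nodes = nodes, delta = delta, boxes = fin, axes = axes,
                 model = model, diet_delta = diet_delta),
            class = "zn_sweep")
}

# d b / d theta for a fractionation axis: each edge contributes
# +F*coef/M to its head row and -F*coef/M to its tail row
alpha_sensitivity <- function(model, sys, axis) {
  d <- stats::setNames(numeric(length(sys$boxes)), sys$boxes)
  flx <- model$fluxes
  key <- flux_key(flx$from, flx$to)
  idx <- match(flux_key(axis$from, axis$to), key)
  if (anyNA(idx)) {
    stop("axis '", axis$name, "' references missing edge(s): ",
         paste(flux_key(axis$from, axis$to)[is.na(idx)], collapse = ", "))
  }
  for (j in seq_along(idx)) {
    i <- idx[j]; r <- flx$rate[i]; cf <- axis$coef[j]
    if (flx$to[i] %in% sys$boxes) {
      d[flx$to[i]] <- d[flx$to[i]] + r * cf / sys$M[flx$to[i]]
    }
    if (flx$from[i] %in% sys$boxes) {
      d[flx$from[i]] <- d[flx$from[i]] - r * cf / sys$M[flx$from[i]]
    }
  }
  d
}

# Cartesian grid, row-major in axis declaration order (last axis fastest)
grid_row_major <- function(axes) {
  if (!length(axes)) return(tibble::tibble(.rows = 1))
  vals <- lapply(axes, `[[`, "values")
  names(vals) <- vapply(axes, `[[`, "", "name")
  g <- rev(expand.grid(rev(vals), KEEP.OUT.ATTRS = FALSE))
  tibble::as_tibble(g)
}

# row index of each node's sub-combination within a sub-grid
combo_index <- function(nodes, sub_grid) {
  cols <- setdiff(names(sub_grid), ".rows")
  if (!length(cols)) return(rep(1L, nrow(nodes)))
  key_sub <- do.call(paste, c(sub_grid[cols], sep = "\r"))
  key_nodes <- do.call(paste, c(nodes[cols], sep = "\r"))
  match(key_nodes, key_sub)
}

#' @export
print.zn_sweep <- function(x, ...) {
  cat("<zn_sweep> ", format(nrow(x$nodes), big.mark = ","), " nodes x ",
      length(x$boxes), " boxes; axes: ",
      paste(vapply(x$axes, `[[`, "", "name"), collapse = ", "),
      "; diet delta = ", x$diet_delta, " permil\n", sep = "")
  invisible(x)
}

#' @export
as_tibble.zn_sweep <- function(x, ...) {
  dplyr::bind_cols(x$nodes,
                   tibble::as_tibble(x$delta, .name_repair = "minimal"))
}

#' Read sweep axes from a YAML file
#'
#' Schema: a top-level `axes` list whose entries carry `name`,
#' `kind` (`"alpha"` or `"flux"`), `edges` (each `"from -> to"`), optional
#' `coef`, `lo`, `hi`, and either `n` (with optional `scale`) or `by`.
#'
#' @param path File path.
#' @return A list of `sweep_axis` objects.
#' @export
axes_from_yaml <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$axes)) stop("axes config needs a top-level `axes` list")
  lapply(doc$axes, function(x) {
    kind <- match.arg(x$kind, c("alpha", "flux"))
    fn <- if (kind == "alpha") sweep_axis_alpha else sweep_axis_flux
    edges <- unlist(x$edges)
    fn(name = x$name, edges = edges,
       coef = if (is.null(x$coef)) rep(1, length(edges)) else unlist(x$coef),
       lo = x$lo, hi = x$hi,
       n = x$n, by = x$by,
       scale = x$scale %||% if (kind == "flux") "log" else "linear")
  })
}
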