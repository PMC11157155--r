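#' Build a zinc isotope box model
#'
#' A box model is a network of well-mixed zinc pools ("compartments")
#' exchanging material by first-order fluxes, each flux carrying an isotope
#' fractionation coefficient. Finite compartments have a fixed zinc mass and
#' an evolving delta-66-Zn composition; the diet is an infinite source with a
#' prescribed composition and waste is an infinite sink that receives but
#' never emits.
#'
#' @param compartments A data frame with columns `name`, `mass` (micrograms of
#'   zinc; `NA` or `Inf` for the infinite source/sink), `role` (one of
#'   `"internal"`, `"source"`, `"sink"`, `"accumulator"`) and optionally
#'   `delta0` (initial delta-66-Zn in per mil vs JMC-Lyon; required for finite
#'   boxes, prescribed diet composition for the source).
#' @param fluxes A data frame with columns `from`, `to`, `rate` (micrograms of
#'   zinc per day) and `alpha` (fractionation coefficient, dimensionless and
#'   close to 1). The per-mil fractionation `cap_delta = 1000 * log(alpha)` is
#'   derived and stored alongside.
#'
#' @details Structural invariants are enforced at construction: flux endpoints
#'   must name declared compartments, rates must be non-negative, no
#'   self-loops or duplicate edges are allowed, alphas must lie in the
#'   (0.99, 1.01) sanity band, there is at most one source and at least one
#'   sink, every finite box must be reachable from the source, the source has
#'   no influx and sinks no efflux, and accumulator boxes (excreta pools such
#'   as feces and urine) must have at least one influx and exactly one efflux,
#'   directed to a sink. Mass balance is deliberately *not* enforced here;
#'   use [mass_balance()] to audit it, since published flux tables are
#'   sometimes internally inconsistent.
#'
#' @return An object of class `box_model`: a list with tibbles `compartments`
#'   and `fluxes`.
#' @seealso [mass_balance()], [steady_state()], [read_box_model()]
#' @examples
#' m <- box_model(
#'   compartments = data.frame(
#'     name = c("diet", "body", "waste"),
#'     mass = c(NA, 100, NA),
#'     role = c("source", "internal", "sink"),
#'     delta0 = c(0.42, 0.42, NA)
#'   ),
#'   fluxes = data.frame(
#'     from = c("diet", "body"), to = c("body", "waste"),
#'     rate = c(10, 10), alpha = c(1, 1)
#'   )
#' )
#' steady_state(m, diet_delta = 0.42)
#' @export
box_model <- function(compartments, fluxes) {
  comps <- tibble::as_tibble(compartments)
  flx <- tibble::as_tibble(fluxes)

  need_c <- c("name", "mass", "role")
  if (!all(need_c %in% names(comps))) {
    stop("`compartments` needs columns: ", paste(need_c, collapse = ", "))
  }
  if (!"delta0" %in% names(comps)) comps$delta0 <- NA_real_
  comps <- comps[, c("name", "mass", "role", "delta0")]
  comps$name <- as.character(comps$name)
  comps$mass <- as.numeric(comps$mass)
  comps$delta0 <- as.numeric(comps$delta0)

  need_f <- c("from", "to", "rate", "alpha")
  if (!all(need_f %in% names(flx))) {
    stop("`fluxes` needs columns: ", paste(need_f, collapse = ", "))
  }
  flx <- flx[, need_f]
  flx$from <- as.character(flx$from)
  flx$to <- as.character(flx$to)
  flx$rate <- as.numeric(flx$rate)
  flx$alpha <- as.numeric(flx$alpha)
  flx$cap_delta <- 1000 * log(flx$alpha)

  if (anyDuplicated(comps$name)) {
    stop("duplicate compartment names: ",
         paste(unique(comps$name[duplicated(comps$name)]), collapse = ", "))
  }
  ok_roles <- c("internal", "source", "sink", "accumulator")
  if (!all(comps$role %in% ok_roles)) {
    stop("compartment roles must be one of: ", paste(ok_roles, collapse = ", "))
  }
  finite <- comps$role %in% c("internal", "accumulator")
  if (any(finite & (!is.finite(comps$mass) | comps$mass <= 0))) {
    bad <- comps$name[finite & (!is.finite(comps$mass) | comps$mass <= 0)]
    stop("finite boxes need mass > 0: ", paste(bad, collapse = ", "))
  }
  if (sum(comps$role == "source") > 1) stop("at most one source is allowed")
  if (sum(comps$role == "sink") < 1) stop("at least one sink is required")

  edge <- paste(flx$from, flx$to, sep = " -> ")
  unknown <- setdiff(c(flx$from, flx$to), comps$name)
  if (length(unknown)) {
    bad <- edge[flx$from %in% unknown | flx$to %in% unknown]
    stop("flux references unknown compartment (", paste(unknown, collapse = ", "),
         "): ", paste(bad, collapse = "; "))
  }
  if (any(flx$rate < 0)) {
    stop("negative flux rate: ", paste(edge[flx$rate < 0], collapse = "; "))
  }
  if (any(flx$from == flx$to)) {
    stop("self-loop flux: ", paste(edge[flx$from == flx$to], collapse = "; "))
  }
  if (anyDuplicated(edge)) {
    stop("duplicate flux edge: ",
         paste(unique(edge[duplicated(edge)]), collapse = "; "))
  }
  if (any(flx$alpha <= 0.99 | flx$alpha >= 1.01)) {
    stop("alpha outside the (0.99, 1.01) sanity band: ",
         paste(edge[flx$alpha <= 0.99 | flx$alpha >= 1.01], collapse = "; "))
  }

  role_of <- stats::setNames(comps$role, comps$name)
  if (any(role_of[flx$to] == "source")) {
    stop("source receives influx: ",
         paste(edge[role_of[flx$to] == "source"], collapse = "; "))
  }
  if (any(role_of[flx$from] == "sink")) {
    stop("sink emits efflux: ",
         paste(edge[role_of[flx$from] == "sink"], collapse = "; "))
  }

  # connectivity: every finite box reachable from the source along flux edges
  src <- comps$name[comps$role == "source"]
  fin_names <- comps$name[finite]
  if (length(fin_names)) {
    if (!length(src) || !any(flx$from == src)) {
      stop("source not connected: no flux leaves the source")
    }
    reach <- src
    repeat {
      nxt <- unique(c(reach, flx$to[flx$from %in% reach]))
      if (length(nxt) == length(reach)) break
      reach <- nxt
    }
    miss <- setdiff(fin_names, reach)
    if (length(miss)) {
      stop("source not connected to finite box(es): ", paste(miss, collapse = ", "))
    }
  }

  # accumulator rule: >= 1 influx, exactly one efflux, going to a sink
  for (a in comps$name[comps$role == "accumulator"]) {
    n_in <- sum(flx$to == a)
    out_edges <- which(flx$from == a)
    if (n_in < 1 || length(out_edges) != 1 ||
        role_of[flx$to[out_edges]] != "sink") {
      stop("accumulator box '", a,
           "' must have >= 1 influx and exactly one efflux to a sink")
    }
  }

  structure(list(compartments = comps, fluxes = flx), class = "box_model")
}

#' @export
print.box_model <- function(x, ...) {
  fin <- finite_boxes(x)
  cat("<box_model> ", nrow(x$compartments), " compartments (",
      length(fin), " finite), ", nrow(x$fluxes), " fluxes\n", sep = "")
  bal <- mass_balance(x)
  if (all(bal$balanced)) {
    cat("mass balance: all finite boxes balanced\n")
  } else {
    cat("mass balance: IMBALANCED in ",
        paste(bal$compartment[!bal$balanced], collapse = ", "), "\n", sep = "")
  }
  invisible(x)
}

# names of finite (evolving) boxes, in declaration order
finite_boxes <- function(model) {
  model$compartments$name[model$compartments$role %in% c("internal", "accumulator")]
}

source_name <- function(model) {
  model$compartments$name[model$compartments$role == "source"]
}

flux_key <- function(from, to) paste(from, to, sep = " -> ")

#' Audit per-compartment zinc mass balance
#'
#' A physiological steady state requires each finite box to receive exactly as
#' much zinc per day as it loses. This reports the per-box imbalance so that
#' inconsistent flux tables can be diagnosed rather than silently used.
#'
#' @param model A [box_model()].
#' @param tol Imbalance tolerance in micrograms per day (default `1e-6`).
#' @return A tibble with one row per finite box: `compartment`, `influx`,
#'   `efflux`, `imbalance` (influx minus efflux) and `balanced`.
#' @examples
#' mass_balance(rat_model("printed"))   # flags the printed muscle efflux
#' @export
mass_balance <- function(model, tol = 1e-6) {
  stopifnot(inherits(model, "box_model"))
  fin <- finite_boxes(model)
  flx <- model$fluxes
  influx <- vapply(fin, function(b) sum(flx$rate[flx$to == b]), numeric(1))
  efflux <- vapply(fin, function(b) sum(flx$rate[flx$from == b]), numeric(1))
  tibble::tibble(
    compartment = fin,
    influx = influx,
    efflux = efflux,
    imbalance = influx - efflux,
    balanced = abs(influx - efflux) <= tol
  )
}

#' Read or write a box-model configuration file
#'
#' Models round-trip through a plain YAML schema:
#' `compartments: [{name, mass|infinite, role, delta0}]` and
#' `fluxes: [{from, to, rate, alpha}]`.
#'
#' @param path File path.
#' @return `read_box_model()` returns a validated [box_model()];
#'   `write_box_model()` returns `path` invisibly.
#' @export
read_box_model <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$compartments) || is.null(doc$fluxes)) {
    stop("model config needs `compartments` and `fluxes` sections: ", path)
  }
  comps <- purrr::map_dfr(doc$compartments, function(x) {
    mass <- x$mass
    if (is.null(mass) || identical(mass, "infinite")) mass <- NA_real_
    tibble::tibble(
      name = x$name, mass = as.numeric(mass), role = x$role,
      delta0 = if (is.null(x$delta0)) NA_real_ else as.numeric(x$delta0)
    )
  })
  flx <- purrr::map_dfr(doc$fluxes, function(x) {
    tibble::tibble(from = x$from, to = x$to,
                   rate = as.numeric(x$rate), alpha = as.numeric(x$alpha))
  })
  box_model(comps, flx)
}

#' @rdname read_box_model
#' @param model A [box_model()] to serialise.
#' @export
write_box_model <- function(model, path) {
  stopifnot(inherits(model, "box_model"))
  doc <- list(
    compartments = purrr::pmap(model$compartments, function(name, mass, role, delta0) {
      out <- list(name = name,
                  mass = if (is.na(mass)) "infinite" else mass,
                  role = role)
      if (!is.na(delta0)) out$delta0 <- delta0
      out
    }),
    fluxes = purrr::pmap(model$fluxes, function(from, to, rate, alpha, cap_delta) {
      list(from = from, to = to, rate = rate, alpha = alpha)
    })
  )
  yaml::write_yaml(doc, path, precision = 12)
  invisible(path)
}

# serialisable plain-list view used in provenance records
model_as_list <- function(model) {
  list(
    compartments = lapply(seq_len(nrow(model$compartments)), function(i) {
      as.list(model$compartments[i, ])
    }),
    fluxes = lapply(seq_len(nrow(model$fluxes)), function(i) {
      as.list(model$fluxes[i, c("from", "to", "rate", "alpha")])
    })
  )
}
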