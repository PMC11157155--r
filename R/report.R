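#' Write the steady-state report for a model
#'
#' Computes and writes as CSV the steady-state composition table, the
#' residence-time table and the whole-system relaxation times, plus a
#' provenance record (`provenance.json`: configuration echo, package
#' version, seed) from which the run can be regenerated bit-identically.
#' A mass imbalance is reported in `balance.csv` and as a warning rather
#' than an error, so published-but-inconsistent configurations can still be
#' audited.
#'
#' @param model A [box_model()].
#' @param dir Output directory (created if needed).
#' @param diet_delta Diet composition, per mil.
#' @param seed Seed recorded in the provenance (the computation itself is
#'   deterministic).
#' @return Invisibly, a named list of written file paths.
#' @export
report_steady <- function(model, dir, diet_delta = 0.42, seed = 1) {
  stopifnot(inherits(model, "box_model"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()

  bal <- mass_balance(model)
  if (!all(bal$balanced)) {
    warning("mass imbalance in: ",
            paste(bal$compartment[!bal$balanced], collapse = ", "),
            call. = FALSE)
    paths$balance <- file.path(dir, "balance.csv")
    readr::write_csv(bal, paths$balance, progress = FALSE)
  }

  paths$steady_state <- file.path(dir, "steady_state.csv")
  readr::write_csv(suppressWarnings(steady_state(model, diet_delta)),
                   paths$steady_state, progress = FALSE)
  paths$residence <- file.path(dir, "residence_times.csv")
  readr::write_csv(residence_times(model), paths$residence, progress = FALSE)
  paths$relaxation <- file.path(dir, "relaxation_times.csv")
  readr::write_csv(relaxation_times(model), paths$relaxation, progress = FALSE)

  paths$provenance <- file.path(dir, "provenance.json")
  write_provenance(paths$provenance, "steady",
                   list(diet_delta = diet_delta, seed = seed,
                        model = model_as_list(model)))
  invisible(paths)
}

#' Run the full sweep-fit / dynamics pipeline and write a summary
#'
#' The end-to-end analysis: sweep the parameter grid against the observation
#' table, take the representative accepted model, and characterise it —
#' steady state, residence and relaxation times, diet-switch
#' time-to-x-percent table, and the sinusoidal forcing battery (buffering
#' and phase shift per period). Writes component CSVs plus `summary.json`
#' and a provenance record. Stage failures are re-raised with the stage
#' name.
#'
#' @param observations Observation table (defaults to [rat_observations()]).
#' @param dir Output directory.
#' @param model Base model for the sweep (default `rat_model("balanced")`).
#' @param axes Sweep axes (default [rat_axes()]).
#' @param diet_delta Diet composition during the reference experiment.
#' @param switch_to Post-switch diet composition for the equilibration table.
#' @param periods Sinusoid periods, days.
#' @param forcing_boxes Boxes analysed under sinusoidal forcing.
#' @param seed Seed recorded in the provenance.
#' @param dt Simulation output step for the equilibration table.
#' @return Invisibly, a list with the `zn_fit` and the written paths.
#' @export
report_pipeline <- function(observations = rat_observations(), dir,
                            model = rat_model("balanced"),
                            axes = rat_axes(), diet_delta = 0.42,
                            switch_to = -0.30,
                            periods = c(10, 50, 100, 365),
                            forcing_boxes = c("plasma", "bone"),
                            seed = 1, dt = 0.1) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("stage '", name, "': ", conditionMessage(e), call. = FALSE)
    })
  }
  paths <- list()

  fit <- stage("sweep-fit", {
    sw <- suppressWarnings(sweep_steady(model, axes, diet_delta))
    ci_fit(sw, observations)
  })
  paths$fit_marginals <- file.path(dir, "fit_marginals.csv")
  readr::write_csv(generics::tidy(fit), paths$fit_marginals, progress = FALSE)

  m_fit <- stage("fitted-model", fitted_model(fit))
  sp <- stage("steady", report_steady(m_fit, dir, diet_delta, seed))
  paths <- c(paths, sp[setdiff(names(sp), "provenance")])

  eq <- stage("equilibration",
              equilibration_table(m_fit, diet_delta, switch_to, dt = dt))
  paths$equilibration <- file.path(dir, "equilibration.csv")
  readr::write_csv(eq, paths$equilibration, progress = FALSE)

  sr <- stage("sinusoid", purrr::map_dfr(periods, function(p) {
    sinusoid_response(m_fit, forcing_boxes, period = p,
                      delta_mean = diet_delta)
  }))
  paths$sinusoid <- file.path(dir, "sinusoid.csv")
  readr::write_csv(sr, paths$sinusoid, progress = FALSE)

  summary <- list(
    n_nodes = fit$n_nodes,
    n_accepted = fit$n_accepted,
    accepted_fraction = fit$accepted_fraction,
    representative = as.list(fit$representative$values),
    max_relaxation_days = max(relaxation_times(m_fit)$time_days),
    sinusoid = lapply(seq_len(nrow(sr)), function(i) as.list(sr[i, ]))
  )
  paths$summary <- file.path(dir, "summary.json")
  jsonlite::write_json(summary, paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)

  paths$provenance <- file.path(dir, "provenance.json")
  write_provenance(paths$provenance, "pipeline",
                   list(diet_delta = diet_delta, switch_to = switch_to,
                        periods = periods, forcing_boxes = forcing_boxes,
                        seed = seed, dt = dt,
                        model = model_as_list(model),
                        observations = as.list(tibble::as_tibble(observations))))
  invisible(list(fit = fit, paths = paths))
}

write_provenance <- function(path, subcommand, config) {
  rec <- list(package = "znbox",
              version = as.character(utils::packageVersion("znbox")),
              subcommand = subcommand,
              config = config)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
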