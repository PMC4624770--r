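#' Define a scenario for deterministic sensitivity analysis
#'
#' A scenario is a named set of overrides applied to a copy of the model
#' setup, plus an evaluation mode. Recognised override keys are any scalar
#' field of [sad_parameters] (e.g. `utility_sad`, `relapse_rr`,
#' `horizon_years_post_treatment`) and three cost keys that retarget
#' therapist unit costs by delivery mode: `selfhelp_therapist_unit_cost`,
#' `group_therapist_unit_cost`, `individual_therapist_unit_cost`.
#'
#' @param name scenario name.
#' @param overrides named list of overrides.
#' @param mode `"probabilistic"` (re-run the PSA under the scenario) or
#'   `"deterministic"` (evaluate at point estimates).
#' @return Object of class `sad_scenario`.
#' @export
sad_scenario <- function(name, overrides = list(),
                         mode = c("probabilistic", "deterministic")) {
  stopifnot(is.character(name), length(name) == 1L)
  if (length(overrides) && (is.null(names(overrides)) ||
                            any(names(overrides) == "")))
    stop("scenario overrides must be named")
  structure(list(name = name, overrides = overrides, mode = match.arg(mode)),
            class = "sad_scenario")
}

cost_override_keys <- c("selfhelp_therapist_unit_cost",
                        "group_therapist_unit_cost",
                        "individual_therapist_unit_cost")

#' Apply a scenario to a model setup
#'
#' Returns a new [sad_model] with the scenario's overrides applied; the base
#' model is left untouched. Parameter overrides are routed through
#' [sad_parameters()] (so fixing a sampled quantity collapses its
#' distribution to a point mass); cost overrides rewrite the therapist unit
#' cost of the matching delivery rows in the psychological cost table.
#'
#' @param model a [sad_model] object.
#' @param scenario a [sad_scenario] object.
#' @return A new `sad_model`.
#' @export
apply_scenario <- function(model, scenario) {
  stopifnot(inherits(model, "sad_model"), inherits(scenario, "sad_scenario"))
  ov <- scenario$overrides
  par_ov <- ov[setdiff(names(ov), cost_override_keys)]
  params <- if (length(par_ov)) do.call(sad_parameters, par_ov)
            else model$parameters
  psych <- model$psych_costs
  map <- c(selfhelp_therapist_unit_cost = "selfhelp",
           group_therapist_unit_cost = "group",
           individual_therapist_unit_cost = "individual")
  for (k in intersect(names(ov), cost_override_keys))
    psych$therapist_unit_cost[psych$delivery == map[[k]]] <- ov[[k]]
  sad_model(parameters = params,
            interventions = model$interventions,
            drug_costs = model$drug_costs,
            psych_costs = psych,
            recovery_table = model$recovery_table)
}

#' Packaged sensitivity scenarios
#'
#' The deterministic sensitivity analyses shipped with the model:
#' * `base`: no overrides;
#' * `therapist_bands`: self-help supported by a Band 5 therapist (£87/h)
#'   and group therapies delivered by one Band 7 and one Band 6 therapist
#'   (average £101.50 per therapist-hour);
#' * `alternative_utilities`: utilities 0.79 (ill) and 0.91 (recovered);
#' * `horizon_1y`, `horizon_3y`, `horizon_10y`: 1, 3 and 10 years
#'   post-treatment;
#' * `relapse_rr_1.0`, `relapse_rr_1.15`, `relapse_rr_1.5`,
#'   `relapse_rr_2.0`: fixed relapse risk ratios of drugs versus
#'   psychological therapy.
#'
#' @param mode evaluation mode for all returned scenarios.
#' @return Named list of [sad_scenario] objects.
#' @export
sad_scenarios <- function(mode = c("probabilistic", "deterministic")) {
  mode <- match.arg(mode)
  mk <- function(name, overrides = list()) sad_scenario(name, overrides, mode)
  scen <- list(
    mk("base"),
    mk("therapist_bands",
       list(selfhelp_therapist_unit_cost = 87,
            group_therapist_unit_cost = (110 + 93) / 2)),
    mk("alternative_utilities",
       list(utility_sad = 0.79, utility_recovered = 0.91)),
    mk("horizon_1y", list(horizon_years_post_treatment = 1L)),
    mk("horizon_3y", list(horizon_years_post_treatment = 3L)),
    mk("horizon_10y", list(horizon_years_post_treatment = 10L)),
    mk("relapse_rr_1.0", list(relapse_rr = 1.0)),
    mk("relapse_rr_1.15", list(relapse_rr = 1.15)),
    mk("relapse_rr_1.5", list(relapse_rr = 1.5)),
    mk("relapse_rr_2.0", list(relapse_rr = 2.0))
  )
  stats::setNames(scen, vapply(scen, `[[`, character(1), "name"))
}

#' Run a suite of scenarios and collect cost-effectiveness rankings
#'
#' Each scenario is applied to a copy of the base model and evaluated —
#' probabilistically with the shared seed (so scenarios differ only through
#' their overrides), or deterministically at point estimates — and
#' summarised into a ranking table.
#'
#' @param model base [sad_model].
#' @param scenarios list of [sad_scenario] objects (default:
#'   [sad_scenarios()]).
#' @param posterior optional `sad_posterior` shared across scenarios; by
#'   default each probabilistic scenario samples the synthetic posterior
#'   under `seed`.
#' @param n_iter PSA iterations for probabilistic scenarios.
#' @param seed integer seed reused for every scenario.
#' @param threshold willingness to pay per QALY for the NMB ranking.
#' @return Named list of [cea_summary()] data frames.
#' @export
run_scenario_suite <- function(model = sad_model(),
                               scenarios = sad_scenarios(),
                               posterior = NULL, n_iter = 1000L, seed = 1L,
                               threshold = 20000) {
  labels <- stats::setNames(model$interventions$label, model$interventions$id)
  out <- lapply(scenarios, function(sc) {
    m <- apply_scenario(model, sc)
    res <- if (sc$mode == "deterministic") {
      det <- run_deterministic(m)
      list(cost = matrix(det$cost, 1, dimnames = list(NULL, det$id)),
           qaly = matrix(det$qaly, 1, dimnames = list(NULL, det$id)),
           well = matrix(det$well, 1, dimnames = list(NULL, det$id)),
           ids = det$id)
    } else {
      run_psa(m, posterior = posterior, n_iter = n_iter, seed = seed)
    }
    cea_summary(res, threshold = threshold, labels = labels)
  })
  stats::setNames(out, vapply(scenarios, `[[`, character(1), "name"))
}
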