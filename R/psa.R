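#' Sample one set of joint parameter draws for the probabilistic analysis
#'
#' Draws every stochastic quantity other than the recovery probabilities:
#' utilities, annual state costs, first-year drug relapse and the relapse
#' risk ratio (from which the psychological relapse is derived within the
#' same draw), the 12-year recovery/relapse probabilities (annualised per
#' draw by constant hazard), GP visit counts (one initial and one
#' maintenance count shared by all pharmacological arms and pill placebo),
#' attended-session counts per individually delivered therapy and therapist
#' contact minutes per self-help arm. Draws are cohort-level: one value of
#' each quantity applies to the whole cohort in an iteration, and the same
#' draw set is shared by every intervention (common random numbers).
#'
#' Sampling always covers the full packaged intervention list in packaged
#' order, regardless of which interventions are later evaluated, so results
#' for any one arm are invariant to the subset of comparators in a run.
#' Uses the current RNG stream; call `set.seed()` (or let [run_psa()] do it)
#' for reproducibility.
#'
#' @param model a [sad_model] object.
#' @param n number of joint draws.
#' @return Object of class `sad_draws`: a list of numeric vectors of length
#'   `n` (`u_recovered`, `u_sad`, `cost_recovered`, `cost_sad`,
#'   `relapse_drug`, `relapse_rr`, `relapse_psych`, `recovery_annual`,
#'   `relapse_annual`, `gp_initial`, `gp_maintenance`) plus named lists
#'   `sessions` and `contact_minutes` of per-intervention draw vectors.
#' @export
sample_parameter_draws <- function(model = sad_model(), n = 1L) {
  stopifnot(inherits(model, "sad_model"), n >= 1)
  p <- model$parameters
  d <- p$dists
  out <- list(
    u_recovered = sample_dist(d$utility_recovered, n),
    u_sad = sample_dist(d$utility_sad, n),
    cost_recovered = sample_dist(d$annual_cost_recovered, n),
    cost_sad = sample_dist(d$annual_cost_sad, n),
    relapse_drug = sample_dist(d$relapse_drug_y1, n),
    relapse_rr = sample_dist(d$relapse_rr, n),
    recovery_annual = multi_year_to_annual_prob(sample_dist(d$recovery_12yr, n), 12),
    relapse_annual = multi_year_to_annual_prob(sample_dist(d$relapse_12yr, n), 12),
    gp_initial = sample_dist(d$gp_visits_initial, n),
    gp_maintenance = sample_dist(d$gp_visits_maintenance, n)
  )
  out$relapse_psych <- psych_relapse_year1(out$relapse_drug, out$relapse_rr)

  pc <- model$psych_costs
  sessions <- list()
  minutes <- list()
  for (i in seq_len(nrow(pc))) {
    id <- pc$id[i]
    if (pc$delivery[i] == "individual")
      sessions[[id]] <- sample_dist(session_count_dist(pc[i, ]), n)
    else if (pc$delivery[i] == "selfhelp")
      minutes[[id]] <- sample_dist(
        contact_minutes_dist(pc[i, ], p$selfhelp_minutes_sd_factor), n)
  }
  out$sessions <- sessions
  out$contact_minutes <- minutes
  structure(out, class = "sad_draws")
}

#' Point-estimate parameter draws
#'
#' The degenerate draw set in which every quantity takes its point estimate
#' (modal GP visits, full course of sessions, mean contact minutes), used by
#' deterministic analyses. Structure matches [sample_parameter_draws()].
#'
#' @param model a [sad_model] object.
#' @return An object of class `sad_draws` with length-1 components.
#' @export
point_parameter_draws <- function(model = sad_model()) {
  p <- model$parameters
  d <- p$dists
  out <- list(
    u_recovered = p$utility_recovered,
    u_sad = p$utility_sad,
    cost_recovered = p$annual_cost_recovered,
    cost_sad = p$annual_cost_sad,
    relapse_drug = p$relapse_drug_y1,
    relapse_rr = p$relapse_rr,
    relapse_psych = p$relapse_psych_y1,
    recovery_annual = p$recovery_annual,
    relapse_annual = p$relapse_annual,
    gp_initial = d$gp_visits_initial$point,
    gp_maintenance = d$gp_visits_maintenance$point
  )
  pc <- model$psych_costs
  out$sessions <- stats::setNames(
    as.list(pc$sessions[pc$delivery == "individual"]),
    pc$id[pc$delivery == "individual"])
  out$contact_minutes <- stats::setNames(
    as.list(pc$contact_minutes[pc$delivery == "selfhelp"]),
    pc$id[pc$delivery == "selfhelp"])
  structure(out, class = "sad_draws")
}

# intervention cost components for one arm under a draw set (vectors)
intervention_cost_draws <- function(id, model, draws) {
  p <- model$parameters
  info <- model$interventions[model$interventions$id == id, ]
  if (nrow(info) != 1L) stop("unknown intervention id: ", id)
  if (info$class == "wait-list")
    return(list(initial = 0, maintenance = 0))
  if (id %in% model$drug_costs$id) {
    cc <- drug_cost_components(model$drug_costs[model$drug_costs$id == id, ],
                               draws$gp_initial, draws$gp_maintenance,
                               gp_unit_cost = p$gp_visit_unit_cost)
    return(cc)
  }
  profile <- model$psych_costs[model$psych_costs$id == id, ]
  cost <- switch(profile$delivery,
    individual = psych_intervention_cost(profile,
                                         sessions_attended = draws$sessions[[id]],
                                         gp_unit_cost = p$gp_visit_unit_cost),
    group = psych_intervention_cost(profile, gp_unit_cost = p$gp_visit_unit_cost),
    selfhelp = psych_intervention_cost(profile,
                                       contact_minutes = draws$contact_minutes[[id]],
                                       gp_unit_cost = p$gp_visit_unit_cost))
  list(initial = cost, maintenance = 0)
}

relapse_y1_draws <- function(relapse_class, draws, params) {
  switch(relapse_class,
         drug = draws$relapse_drug,
         psychological = draws$relapse_psych,
         waitlist = params$relapse_waitlist_y1,
         stop("unknown relapse class: ", relapse_class))
}

#' Run the probabilistic sensitivity analysis
#'
#' Evaluates every intervention over `n_iter` joint parameter draws. Each
#' iteration pairs one row of the recovery posterior with one draw of all
#' other parameters; every intervention is evaluated under the same draw
#' (common random numbers), which minimises the Monte Carlo variance of
#' incremental comparisons. Fully reproducible given `seed`.
#'
#' @param model a [sad_model] object.
#' @param posterior a `sad_posterior` with at least `n_iter` rows and a
#'   column per intervention in `model`; defaults to the packaged synthetic
#'   posterior sampled with the same seed.
#' @param n_iter number of iterations (default: the model's `n_iterations`).
#' @param seed integer seed set before all sampling.
#' @return Object of class `sad_psa`: list with `cost`, `qaly`, `well`
#'   matrices (`n_iter` rows, one column per intervention), `ids`, `n_iter`
#'   and `seed`.
#' @export
run_psa <- function(model = sad_model(), posterior = NULL, n_iter = NULL,
                    seed = NULL) {
  stopifnot(inherits(model, "sad_model"))
  if (!is.null(seed)) set.seed(seed)
  params <- model$parameters
  if (is.null(n_iter)) n_iter <- params$n_iterations
  if (n_iter < 1) stop("n_iter must be >= 1")
  if (is.null(posterior))
    posterior <- sample_recovery_posterior(
      default_effect_specs(baseline_log_odds(params$baseline_log_odds_mean,
                                             params$baseline_log_odds_variance),
                           model$recovery_table),
      baseline_log_odds(params$baseline_log_odds_mean,
                        params$baseline_log_odds_variance),
      n_draws = n_iter)
  stopifnot(inherits(posterior, "sad_posterior"))
  if (nrow(posterior$draws) < n_iter)
    stop("posterior has fewer rows (", nrow(posterior$draws),
         ") than n_iter (", n_iter, ")")
  ids <- model$interventions$id
  missing <- setdiff(ids, posterior$ids)
  if (length(missing))
    stop("posterior lacks column(s): ", paste(missing, collapse = ", "))

  draws <- sample_parameter_draws(model, n_iter)
  cost <- qaly <- well <- matrix(NA_real_, n_iter, length(ids),
                                 dimnames = list(NULL, ids))
  for (j in seq_along(ids)) {
    id <- ids[j]
    cc <- intervention_cost_draws(id, model, draws)
    rel <- relapse_y1_draws(
      model$interventions$relapse_class[model$interventions$id == id],
      draws, params)
    res <- evaluate_cohort(posterior$draws[seq_len(n_iter), id],
                           rel, cc$initial, cc$maintenance, draws, params)
    cost[, j] <- res$cost
    qaly[, j] <- res$qaly
    well[, j] <- res$well
  }
  structure(list(cost = cost, qaly = qaly, well = well, ids = ids,
                 n_iter = n_iter, seed = seed),
            class = "sad_psa")
}

#' @export
print.sad_psa <- function(x, ...) {
  cat("<sad_psa> ", x$n_iter, " iterations x ", length(x$ids),
      " interventions", if (!is.null(x$seed)) paste0(" (seed ", x$seed, ")"),
      "\n", sep = "")
  invisible(x)
}

#' Deterministic evaluation at point estimates
#'
#' Evaluates every intervention once, with all parameters at their point
#' estimates and recovery at the published per-intervention means (or a
#' supplied vector), for fast deterministic runs and scenario rankings.
#'
#' @param model a [sad_model] object.
#' @param recovery named vector of recovery probabilities per intervention;
#'   defaults to the `mean` column of the model's recovery table.
#' @return `data.frame` with columns `id`, `cost`, `qaly`, `well`.
#' @export
run_deterministic <- function(model = sad_model(), recovery = NULL) {
  stopifnot(inherits(model, "sad_model"))
  params <- model$parameters
  if (is.null(recovery))
    recovery <- stats::setNames(model$recovery_table$mean,
                                model$recovery_table$id)
  ids <- model$interventions$id
  missing <- setdiff(ids, names(recovery))
  if (length(missing))
    stop("recovery vector lacks: ", paste(missing, collapse = ", "))
  draws <- point_parameter_draws(model)
  rows <- lapply(ids, function(id) {
    cc <- intervention_cost_draws(id, model, draws)
    rel <- relapse_y1_draws(
      model$interventions$relapse_class[model$interventions$id == id],
      draws, params)
    evaluate_cohort(recovery[[id]], rel, cc$initial, cc$maintenance,
                    draws, params)
  })
  out <- do.call(rbind, rows)
  data.frame(id = ids, cost = out$cost, qaly = out$qaly, well = out$well,
             row.names = NULL)
}
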