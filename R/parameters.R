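#' Model parameters for the social anxiety disorder cost-utility model
#'
#' Builds the full parameter set from the packaged default parameter file
#' (a YAML file mirroring the model's input-parameter table field for field),
#' applying any overrides supplied as named arguments. Point estimates follow
#' the reported means; probabilistic sensitivity analysis samples from the
#' reported distributions (which for the ill-state utility has a slightly
#' different mean than the reported point estimate, as in the source table).
#'
#' Derived quantities are recomputed from their primitives on construction:
#' the years-2-5 annual recovery/relapse probabilities from the 12-year beta
#' counts via the constant-hazard conversion, the first-year drug relapse as
#' the midpoint of two beta means, and the first-year psychological relapse
#' as the drug value divided by the relapse risk ratio.
#'
#' Recognised overrides are the scalar fields of the returned object
#' (for example `utility_sad`, `discount_rate`,
#' `horizon_years_post_treatment`, `wtp_threshold`, `relapse_rr`,
#' `relapse_waitlist_y1`, `gp_visit_unit_cost`, `n_iterations`).
#' Overriding `utility_recovered`, `utility_sad`, `annual_cost_recovered`,
#' `annual_cost_sad` or `relapse_rr` replaces both the point estimate and the
#' sampling distribution with the fixed value, which is how the deterministic
#' scenario analyses are expressed.
#'
#' @param ... named overrides (see Details).
#' @param file path to a parameter YAML file; defaults to the packaged file.
#' @return An object of class `sad_parameters`: a list of point estimates,
#'   model timeline settings, and a `dists` list of [sad_dist] sampling
#'   specifications.
#' @export
sad_parameters <- function(..., file = NULL) {
  if (is.null(file))
    file <- system.file("extdata", "parameters.yaml", package = "sadcea")
  raw <- yaml::read_yaml(file)
  overrides <- list(...)

  p <- list(
    treatment_weeks = raw$treatment_weeks,
    post_treatment_weeks_y1 = raw$post_treatment_weeks_y1,
    horizon_years_post_treatment = raw$horizon_years_post_treatment,
    discount_rate = raw$discount_rate,
    wtp_threshold = raw$wtp_threshold,
    n_iterations = raw$n_iterations,
    utility_recovered = raw$utility_recovered$mean,
    utility_sad = raw$utility_sad$mean,
    annual_cost_recovered = raw$annual_cost_recovered$mean,
    annual_cost_sad = raw$annual_cost_sad$mean,
    relapse_rr = raw$relapse_rr_drug_vs_psych$mean,
    relapse_waitlist_y1 = raw$relapse_waitlist_y1,
    gp_visit_unit_cost = raw$gp_visit_unit_cost,
    therapist_unit_cost_band7 = raw$therapist_unit_cost_band7,
    therapist_unit_cost_band6 = raw$therapist_unit_cost_band6,
    therapist_unit_cost_band5 = raw$therapist_unit_cost_band5,
    selfhelp_minutes_sd_factor = raw$selfhelp_minutes_sd_factor,
    baseline_log_odds_mean = raw$baseline_log_odds$mean,
    baseline_log_odds_variance = raw$baseline_log_odds$variance
  )

  dists <- list(
    utility_recovered = dist_beta_counts(raw$utility_recovered$beta$alpha,
                                         raw$utility_recovered$beta$beta,
                                         point = raw$utility_recovered$mean),
    utility_sad = dist_beta_counts(raw$utility_sad$beta$alpha,
                                   raw$utility_sad$beta$beta,
                                   point = raw$utility_sad$mean),
    annual_cost_recovered = dist_gamma_mean_se(raw$annual_cost_recovered$mean,
                                               raw$annual_cost_recovered$se),
    annual_cost_sad = dist_gamma_mean_se(raw$annual_cost_sad$mean,
                                         raw$annual_cost_sad$se),
    relapse_drug_y1 = dist_beta_midpoint(raw$relapse_drug_y1$first$alpha,
                                         raw$relapse_drug_y1$first$beta,
                                         raw$relapse_drug_y1$second$alpha,
                                         raw$relapse_drug_y1$second$beta),
    relapse_rr = dist_lognormal_ci(raw$relapse_rr_drug_vs_psych$mean,
                                   raw$relapse_rr_drug_vs_psych$ci_low,
                                   raw$relapse_rr_drug_vs_psych$ci_high),
    recovery_12yr = dist_beta_counts(raw$recovery_y2_5_12yr$alpha,
                                     raw$recovery_y2_5_12yr$beta),
    relapse_12yr = dist_beta_counts(raw$relapse_y2_5_12yr$alpha,
                                    raw$relapse_y2_5_12yr$beta),
    gp_visits_initial = dist_categorical(raw$gp_visits_initial$values,
                                         raw$gp_visits_initial$probs,
                                         point = raw$gp_visits_initial$point),
    gp_visits_maintenance = dist_categorical(raw$gp_visits_maintenance$values,
                                             raw$gp_visits_maintenance$probs,
                                             point = raw$gp_visits_maintenance$point)
  )
  p$dists <- dists

  # derived point estimates
  p$relapse_drug_y1 <- dists$relapse_drug_y1$point
  p$recovery_annual <- multi_year_to_annual_prob(dists$recovery_12yr$point, 12)
  p$relapse_annual <- multi_year_to_annual_prob(dists$relapse_12yr$point, 12)

  if (length(overrides)) {
    if (is.null(names(overrides)) || any(names(overrides) == ""))
      stop("parameter overrides must be named")
    known <- setdiff(names(p), "dists")
    bad <- setdiff(names(overrides), known)
    if (length(bad))
      stop("unknown parameter override(s): ", paste(bad, collapse = ", "))
    for (k in names(overrides)) p[[k]] <- overrides[[k]]
    # fixing a sampled quantity turns its distribution into a point mass
    fix_map <- c(utility_recovered = "utility_recovered",
                 utility_sad = "utility_sad",
                 annual_cost_recovered = "annual_cost_recovered",
                 annual_cost_sad = "annual_cost_sad",
                 relapse_rr = "relapse_rr",
                 relapse_drug_y1 = "relapse_drug_y1")
    for (k in intersect(names(overrides), names(fix_map)))
      p$dists[[fix_map[[k]]]] <- dist_point(p[[k]])
    if ("recovery_annual" %in% names(overrides))
      p$dists$recovery_12yr <- dist_point(annual_to_multi_year_prob(p$recovery_annual, 12))
    if ("relapse_annual" %in% names(overrides))
      p$dists$relapse_12yr <- dist_point(annual_to_multi_year_prob(p$relapse_annual, 12))
  }

  p$relapse_psych_y1 <- psych_relapse_year1(p$relapse_drug_y1, p$relapse_rr)
  p$markov_cycles <- p$horizon_years_post_treatment - 1L

  validate_parameters(p)
  structure(p, class = "sad_parameters")
}

validate_parameters <- function(p) {
  stopifnot(
    p$treatment_weeks > 0,
    p$post_treatment_weeks_y1 >= 0,
    p$horizon_years_post_treatment >= 1,
    p$discount_rate >= 0, p$discount_rate < 1,
    p$wtp_threshold >= 0,
    p$annual_cost_recovered >= 0, p$annual_cost_sad >= 0,
    p$gp_visit_unit_cost >= 0
  )
  if (!(p$utility_recovered >= 0 && p$utility_recovered <= 1 &&
        p$utility_sad >= 0 && p$utility_sad <= 1))
    stop("utilities must lie in [0, 1]")
  if (p$utility_recovered <= p$utility_sad)
    stop("utility_recovered must exceed utility_sad")
  probs <- c(p$relapse_drug_y1, p$relapse_waitlist_y1,
             p$recovery_annual, p$relapse_annual)
  if (any(probs < 0) || any(probs > 1))
    stop("all probabilities must lie in [0, 1]")
  invisible(p)
}

#' @export
print.sad_parameters <- function(x, ...) {
  cat("<sad_parameters>\n")
  cat("  horizon: ", x$treatment_weeks, " weeks treatment + ",
      x$horizon_years_post_treatment, " years; discount ",
      x$discount_rate * 100, "%/year\n", sep = "")
  cat("  utilities: recovered ", x$utility_recovered, ", ill ",
      x$utility_sad, "\n", sep = "")
  cat("  annual state costs: £", x$annual_cost_recovered, " / £",
      x$annual_cost_sad, "\n", sep = "")
  cat("  relapse year 1: drug ", round(x$relapse_drug_y1, 4), ", psych ",
      round(x$relapse_psych_y1, 4), ", wait list ",
      round(x$relapse_waitlist_y1, 4), "\n", sep = "")
  cat("  annual recovery/relapse years 2+: ", round(x$recovery_annual, 4),
      " / ", round(x$relapse_annual, 4), "\n", sep = "")
  invisible(x)
}
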