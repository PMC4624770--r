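#' Export and re-import PSA matrices as delimited text
#'
#' Writes the cost, QALY and fraction-well matrices as CSV files
#' (`psa_cost.csv`, `psa_qaly.csv`, `psa_well.csv`; one row per iteration,
#' one column per intervention) into a directory, and reads them back into
#' a `sad_psa` object, so downstream cost-effectiveness summaries can be
#' computed on exported runs byte-identically.
#'
#' @param psa a `sad_psa` object.
#' @param dir directory for the matrix files (created if needed).
#' @return `write_psa_matrices()` returns `dir` invisibly;
#'   `read_psa_matrices()` returns a `sad_psa`.
#' @export
write_psa_matrices <- function(psa, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (part in c("cost", "qaly", "well"))
    utils::write.csv(psa[[part]], file.path(dir, paste0("psa_", part, ".csv")),
                     row.names = FALSE)
  invisible(dir)
}

#' @rdname write_psa_matrices
#' @export
read_psa_matrices <- function(dir) {
  read_part <- function(part)
    as.matrix(utils::read.csv(file.path(dir, paste0("psa_", part, ".csv")),
                              check.names = FALSE))
  cost <- read_part("cost")
  out <- list(cost = cost, qaly = read_part("qaly"), well = read_part("well"),
              ids = colnames(cost), n_iter = nrow(cost), seed = NULL)
  stopifnot(identical(dim(out$cost), dim(out$qaly)),
            identical(dim(out$cost), dim(out$well)))
  structure(out, class = "sad_psa")
}

#' Self-check of the packaged model inputs
#'
#' Recomputes every derived model parameter and deterministic cost component
#' from its primitives and compares it with the published value: the
#' annualised years-2-5 recovery and relapse probabilities, the first-year
#' relapse probabilities, the recovered-state utility from its beta counts,
#' the wait-list median recovery from the baseline log-odds, per-person
#' therapist hours, and full-adherence intervention costs (the latter to a
#' 5p tolerance absorbing the rounding embedded in the published totals).
#'
#' @return `data.frame` with columns `check`, `expected`, `actual`,
#'   `tolerance`, `pass`.
#' @export
sad_validate <- function() {
  model <- sad_model()
  p <- model$parameters
  pc <- model$psych_costs
  full_cost <- function(id) {
    if (id %in% model$drug_costs$id)
      drug_intervention_cost(model$drug_costs[model$drug_costs$id == id, ],
                             4, 3, gp_unit_cost = p$gp_visit_unit_cost)
    else psych_intervention_cost(pc[pc$id == id, ],
                                 gp_unit_cost = p$gp_visit_unit_cost)
  }
  rows <- list(
    list("annual recovery years 2-5", 0.0377, round(p$recovery_annual, 4), 0),
    list("annual relapse years 2-5", 0.0409, round(p$relapse_annual, 4), 0),
    list("drug relapse year 1", 0.4169, round(p$relapse_drug_y1, 4), 0),
    list("psychological relapse year 1 (%)", 14,
         round(100 * p$relapse_psych_y1), 0),
    list("recovered-state utility", 0.866,
         round(beta_mean_from_counts(4572, 707), 3), 0),
    list("wait-list median recovery", 0.07,
         round(stats::plogis(p$baseline_log_odds_mean), 2), 0),
    list("therapist hours, GCBT Heimberg", 10,
         therapist_hours_per_person(12, 2.5, 2, 6), 0),
    list("therapist hours, mindfulness", 4.58,
         round(therapist_hours_per_person(8, 2.5, 2, 12, extra_hours = 7.5), 2), 0),
    list("therapist hours, ICBT C&W", 21,
         therapist_hours_per_person(14, 1.5), 0),
    list("citalopram full-adherence cost", 339.43, full_cost("citalopram"), 0.05),
    list("pregabalin full-adherence cost", 939.07, full_cost("pregabalin"), 0.05),
    list("pill placebo cost (7 GP visits)", 327.25, full_cost("pill_placebo"), 0),
    list("GCBT Heimberg cost", 1148, full_cost("gcbt_heimberg"), 2),
    list("SHNS book cost", 205, full_cost("shns_book"), 1)
  )
  out <- do.call(rbind, lapply(rows, function(r)
    data.frame(check = r[[1]], expected = r[[2]], actual = r[[3]],
               tolerance = r[[4]])))
  out$pass <- abs(out$actual - out$expected) <= out$tolerance
  out
}

#' Run the full analysis and write its outputs
#'
#' End-to-end pipeline: sample (or load) the recovery posterior, run the
#' probabilistic sensitivity analysis, and write the cost-effectiveness
#' summary table, the efficiency-frontier listing, the acceptability
#' frontier curve, the cost-effectiveness plane versus wait list, the PSA
#' matrices and a JSON run manifest (seed, iteration count, threshold,
#' package version) into `out_dir`. All outputs are reproducible
#' byte-for-byte under a fixed seed.
#'
#' @param out_dir output directory (created if needed).
#' @param model a [sad_model] object.
#' @param posterior optional externally supplied `sad_posterior`.
#' @param n_iter PSA iterations (default: the model's `n_iterations`).
#' @param seed integer master seed.
#' @param threshold willingness to pay per QALY for the summary NMB.
#' @param thresholds grid for the acceptability frontier.
#' @param write_matrices also export the raw PSA matrices.
#' @return The [cea_summary()] data frame, invisibly.
#' @export
sad_run <- function(out_dir, model = sad_model(), posterior = NULL,
                    n_iter = NULL, seed = 1L, threshold = 20000,
                    thresholds = seq(0, 50000, by = 250),
                    write_matrices = FALSE) {
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  psa <- run_psa(model, posterior = posterior, n_iter = n_iter, seed = seed)
  labels <- stats::setNames(model$interventions$label, model$interventions$id)
  summary <- cea_summary(psa, threshold = threshold, labels = labels)
  curve <- ceaf(psa, thresholds)
  plane <- ce_plane(summary)

  utils::write.csv(summary, file.path(out_dir, "cea_summary.csv"),
                   row.names = FALSE)
  utils::write.csv(summary[summary$status == "frontier",
                           c("id", "qaly", "cost", "icer")],
                   file.path(out_dir, "frontier.csv"), row.names = FALSE)
  utils::write.csv(curve, file.path(out_dir, "ceaf.csv"), row.names = FALSE)
  utils::write.csv(plane, file.path(out_dir, "ce_plane.csv"), row.names = FALSE)
  if (write_matrices) write_psa_matrices(psa, out_dir)

  manifest <- list(seed = seed, n_iter = psa$n_iter, threshold = threshold,
                   interventions = length(psa$ids),
                   package_version = as.character(utils::packageVersion("sadcea")))
  jsonlite::write_json(manifest, file.path(out_dir, "run_manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(summary)
}
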