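#' Packaged intervention definitions and cost profiles
#'
#' The model compares 28 treatment options for adults with social anxiety
#' disorder: 11 active drugs, pill placebo, 15 psychological interventions
#' (individually delivered, group-based and self-help) and wait list. The
#' packaged tables mirror the published cost tables column for column and are
#' plain CSV files under `inst/extdata/`, so they can be inspected or edited.
#'
#' * `sad_interventions()`: identity, class and relapse class of each option,
#'   ordered by effectiveness (probability of recovery, highest first).
#' * `sad_drug_costs()`: per-drug 12-week and 26-week acquisition costs.
#' * `sad_psych_costs()`: resource-use profiles of psychological
#'   interventions (sessions, session length, therapists and participants per
#'   group, therapist contact minutes for self-help, consumables) together
#'   with the categorical distributions of attended sessions used in the
#'   probabilistic analysis.
#' * `sad_recovery_table()`: published end-of-treatment recovery summaries
#'   (mean, median, 95% credible interval) per intervention.
#'
#' @param file optional path to a replacement CSV with the same columns.
#' @return A `data.frame`, one row per intervention.
#' @name sad_tables
NULL

read_pkg_csv <- function(name, file = NULL) {
  if (is.null(file)) file <- system.file("extdata", name, package = "sadcea")
  utils::read.csv(file, stringsAsFactors = FALSE)
}

#' @rdname sad_tables
#' @export
sad_interventions <- function(file = NULL) {
  x <- read_pkg_csv("interventions.csv", file)
  stopifnot(!anyDuplicated(x$id))
  x
}

#' @rdname sad_tables
#' @export
sad_drug_costs <- function(file = NULL) read_pkg_csv("drug_costs.csv", file)

#' @rdname sad_tables
#' @export
sad_psych_costs <- function(file = NULL) read_pkg_csv("psych_costs.csv", file)

#' @rdname sad_tables
#' @export
sad_recovery_table <- function(file = NULL) read_pkg_csv("recovery_table.csv", file)

#' Bundle parameters and cost tables into one model setup
#'
#' Convenience container passed to [run_psa()], [run_deterministic()] and the
#' scenario machinery. Scenario overrides operate on a copy of this object;
#' the packaged defaults are never mutated.
#'
#' @param parameters a [sad_parameters] object.
#' @param interventions intervention definition table ([sad_interventions]).
#' @param drug_costs drug cost table ([sad_drug_costs]).
#' @param psych_costs psychological-intervention cost table ([sad_psych_costs]).
#' @param recovery_table published recovery summaries ([sad_recovery_table]).
#' @return An object of class `sad_model`.
#' @export
sad_model <- function(parameters = sad_parameters(),
                      interventions = sad_interventions(),
                      drug_costs = sad_drug_costs(),
                      psych_costs = sad_psych_costs(),
                      recovery_table = sad_recovery_table()) {
  stopifnot(inherits(parameters, "sad_parameters"))
  missing_cost <- setdiff(
    interventions$id[interventions$class != "wait-list"],
    c(drug_costs$id, psych_costs$id))
  if (length(missing_cost))
    stop("no cost profile for intervention(s): ",
         paste(missing_cost, collapse = ", "))
  structure(list(parameters = parameters,
                 interventions = interventions,
                 drug_costs = drug_costs,
                 psych_costs = psych_costs,
                 recovery_table = recovery_table),
            class = "sad_model")
}

#' @export
print.sad_model <- function(x, ...) {
  cat("<sad_model> ", nrow(x$interventions), " interventions (",
      sum(x$interventions$class == "pharmacological"), " drugs, ",
      sum(grepl("psychological|self-help", x$interventions$class)),
      " psychological/self-help, pill placebo, wait list)\n", sep = "")
  invisible(x)
}

#' Categorical distribution of attended sessions for one intervention
#'
#' Individually delivered psychological therapies carry a three-band
#' categorical distribution of the number of sessions attended: a probability
#' mass on the full course, and one or two lower bands whose quoted mass is
#' divided equally across the integer session counts in the band.
#'
#' @param profile one row of [sad_psych_costs()] (delivery `"individual"`).
#' @return A categorical [sad_dist] whose point value is the full course.
#' @export
session_count_dist <- function(profile) {
  stopifnot(nrow(profile) == 1L, profile$delivery == "individual")
  values <- profile$sessions
  probs <- profile$p_full
  for (band in c("band2", "band3")) {
    lo <- profile[[paste0(band, "_lo")]]
    hi <- profile[[paste0(band, "_hi")]]
    pb <- profile[[paste0("p_", band)]]
    if (!is.na(pb) && pb > 0) {
      v <- seq.int(lo, hi)
      values <- c(values, v)
      probs <- c(probs, rep(pb / length(v), length(v)))
    }
  }
  dist_categorical(values, probs, point = profile$sessions)
}

#' Normal distribution of therapist contact minutes for self-help
#'
#' @param profile one row of [sad_psych_costs()] (delivery `"selfhelp"`).
#' @param sd_factor standard deviation as a fraction of the mean.
#' @return A zero-truncated normal [sad_dist] centred on the mean contact time.
#' @export
contact_minutes_dist <- function(profile, sd_factor = 0.3) {
  stopifnot(nrow(profile) == 1L, profile$delivery == "selfhelp")
  dist_normal(profile$contact_minutes, sd_factor * profile$contact_minutes,
              truncate_zero = TRUE, point = profile$contact_minutes)
}
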