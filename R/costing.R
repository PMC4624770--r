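#' Therapist hours per person for a course of psychological therapy
#'
#' Group sessions are staffed by one or more therapists and shared by the
#' group, so per-person therapist time is total therapist-session time scaled
#' by therapists over participants. Individually delivered therapy is the
#' special case `therapists = participants = 1`.
#'
#' @param sessions number of sessions in the course (> 0).
#' @param hours_per_session session length in hours (> 0).
#' @param therapists therapists present per session (>= 1).
#' @param participants participants sharing the session (>= 1).
#' @param extra_hours additional therapist-session hours outside the regular
#'   sessions (e.g. an all-day retreat, or an extended first session).
#' @return Therapist hours per service user.
#' @export
therapist_hours_per_person <- function(sessions, hours_per_session,
                                       therapists = 1, participants = 1,
                                       extra_hours = 0) {
  if (any(sessions <= 0) || any(hours_per_session <= 0) ||
      any(therapists <= 0) || any(participants <= 0))
    stop("sessions, hours, therapists and participants must all be positive")
  (sessions * hours_per_session + extra_hours) * therapists / participants
}

#' Intervention cost of a pharmacological treatment arm
#'
#' Cost of initial (12-week) treatment plus, for people who recover and are
#' therefore offered 26 weeks of maintenance treatment, the maintenance
#' component. GP-visit counts carry cost contingencies: with only 1 or 2
#' initial visits no maintenance follows regardless of recovery; with a
#' single initial visit only half of the 12-week drug acquisition cost is
#' incurred; and with zero maintenance visits no 26-week acquisition cost is
#' incurred. Pill placebo has zero acquisition costs. All arguments are
#' vectorised over visit counts.
#'
#' @param profile one row of [sad_drug_costs()].
#' @param initial_visits GP visits during initial treatment (>= 0).
#' @param maintenance_visits GP visits during maintenance (>= 0).
#' @param recovered logical: does this branch of the cohort receive
#'   maintenance treatment?
#' @param gp_unit_cost cost per GP visit in GBP.
#' @return Cost in GBP (vector of the common length of the visit inputs).
#' @export
drug_intervention_cost <- function(profile, initial_visits, maintenance_visits,
                                   recovered = TRUE, gp_unit_cost = 46.75) {
  cc <- drug_cost_components(profile, initial_visits, maintenance_visits,
                             gp_unit_cost)
  cc$initial + ifelse(recovered, cc$maintenance, 0)
}

#' @rdname drug_intervention_cost
#' @return `drug_cost_components()` returns a list with `initial` and
#'   `maintenance` cost vectors; the maintenance component already embeds the
#'   visit-count contingencies and is incurred only by recoverers.
#' @export
drug_cost_components <- function(profile, initial_visits, maintenance_visits,
                                 gp_unit_cost = 46.75) {
  stopifnot(nrow(profile) == 1L)
  if (any(initial_visits < 0) || any(maintenance_visits < 0))
    stop("visit counts must be nonnegative")
  acq12 <- if (profile$is_placebo) 0 else profile$acq_cost_12wk
  acq26 <- if (profile$is_placebo) 0 else profile$acq_cost_26wk
  initial <- initial_visits * gp_unit_cost +
    acq12 * ifelse(initial_visits == 1, 0.5, 1)
  maintenance <- ifelse(initial_visits >= 3,
                        maintenance_visits * gp_unit_cost +
                          ifelse(maintenance_visits == 0, 0, acq26),
                        0)
  list(initial = initial, maintenance = maintenance)
}

#' Intervention cost of a psychological treatment arm
#'
#' * Individual therapies: therapist time for the sessions actually attended
#'   (the extended first session, where present, is attended whenever at
#'   least one session is) at the therapist unit cost, plus a GP referral
#'   visit.
#' * Group therapies: the full-course per-person therapist time regardless of
#'   attendance, because absent participants are not replaced and the group
#'   still runs, plus the referral visit.
#' * Self-help: therapist contact minutes (truncated at zero) at the unit
#'   cost, plus consumables (book, or internet hosting/hardware share), plus
#'   the referral visit.
#'
#' @param profile one row of [sad_psych_costs()].
#' @param sessions_attended sessions attended (individual therapies only;
#'   defaults to the full course). Vectorised.
#' @param contact_minutes therapist contact minutes (self-help only;
#'   defaults to the profile mean). Vectorised.
#' @param gp_unit_cost cost per GP visit in GBP.
#' @param therapist_unit_cost therapist cost per hour; defaults to the
#'   profile's unit cost (Band 7).
#' @param referral whether to include the GP referral visit.
#' @return Cost in GBP.
#' @export
psych_intervention_cost <- function(profile, sessions_attended = NULL,
                                    contact_minutes = NULL,
                                    gp_unit_cost = 46.75,
                                    therapist_unit_cost = NULL,
                                    referral = TRUE) {
  stopifnot(nrow(profile) == 1L)
  unit <- if (is.null(therapist_unit_cost)) profile$therapist_unit_cost
          else therapist_unit_cost
  referral_cost <- if (referral) gp_unit_cost else 0
  switch(profile$delivery,
    individual = {
      s <- if (is.null(sessions_attended)) profile$sessions else sessions_attended
      if (any(s < 0) || any(s > profile$sessions))
        stop("sessions attended must lie in [0, full course]")
      hours <- (s * profile$session_minutes +
                  (s >= 1) * profile$extra_session_minutes) / 60
      hours * unit + referral_cost
    },
    group = {
      hours <- therapist_hours_per_person(
        profile$sessions, profile$session_minutes / 60,
        profile$therapists, profile$participants,
        extra_hours = profile$extra_session_minutes / 60)
      hours * unit + referral_cost
    },
    selfhelp = {
      m <- if (is.null(contact_minutes)) profile$contact_minutes else contact_minutes
      pmax(m, 0) / 60 * unit + profile$consumable_cost + referral_cost
    },
    stop("unknown delivery mode: ", profile$delivery)
  )
}

#' Annual health and personal social service cost of a health state
#'
#' @param state `"recovered"` (no social anxiety disorder) or `"sad"`
#'   (social anxiety disorder).
#' @param params a [sad_parameters] object.
#' @return Annual cost in GBP.
#' @export
annual_state_cost <- function(state, params = sad_parameters()) {
  switch(match.arg(state, c("recovered", "sad")),
         recovered = params$annual_cost_recovered,
         sad = params$annual_cost_sad)
}

#' Full-adherence intervention cost table
#'
#' Deterministic intervention cost of every arm at full adherence (modal GP
#' visits for drugs, full course for psychological therapies, mean contact
#' time for self-help), recomputed from cost components.
#'
#' @param model a [sad_model] object.
#' @return `data.frame` with columns `id` and `cost`.
#' @export
intervention_cost_table <- function(model = sad_model()) {
  p <- model$parameters
  costs <- vapply(model$interventions$id, function(id) {
    cls <- model$interventions$class[model$interventions$id == id]
    if (cls == "wait-list") return(0)
    if (id %in% model$drug_costs$id) {
      drug_intervention_cost(model$drug_costs[model$drug_costs$id == id, ],
                             p$dists$gp_visits_initial$point,
                             p$dists$gp_visits_maintenance$point,
                             recovered = TRUE,
                             gp_unit_cost = p$gp_visit_unit_cost)
    } else {
      psych_intervention_cost(model$psych_costs[model$psych_costs$id == id, ],
                              gp_unit_cost = p$gp_visit_unit_cost)
    }
  }, numeric(1))
  data.frame(id = model$interventions$id, cost = unname(costs))
}
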