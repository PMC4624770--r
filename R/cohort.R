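#' Discounted QALYs over a segment with a linear utility path
#'
#' Utility is assumed to change linearly when transitioning between health
#' states, so the quality-adjusted time over a segment is the trapezoid of
#' the start and end utilities times the duration, multiplied by the
#' segment's discount factor `(1 + r)^(-time_offset)`.
#'
#' @param u_start,u_end utilities in `[0, 1]` at the segment's ends.
#' @param duration segment length in years (>= 0).
#' @param discount_rate annual discount rate.
#' @param time_offset model time in years at which the segment is credited.
#' @return QALYs accrued over the segment.
#' @export
qaly_segment <- function(u_start, u_end, duration, discount_rate = 0,
                         time_offset = 0) {
  if (any(duration < 0)) stop("duration must be nonnegative")
  if (any(u_start < 0 | u_start > 1) || any(u_end < 0 | u_end > 1))
    stop("utilities must lie in [0, 1]")
  (u_start + u_end) / 2 * duration * (1 + discount_rate)^(-time_offset)
}

#' First model year: treatment decision tree and first-year relapse
#'
#' The decision tree covers the initial treatment (default 12 weeks) and the
#' first post-treatment year. After treatment a fraction `p_recover` of the
#' cohort recovers; recoverers may relapse during the first post-treatment
#' year. Utility ramps linearly from the ill-state to the recovered-state
#' value across the treatment weeks for recoverers; first-year relapsers are
#' credited the average of the two state utilities (and state costs) over the
#' post-treatment window, equivalent to a uniformly distributed relapse time.
#' State costs start only after treatment ends, to avoid double counting
#' treatment costs; intervention costs fall entirely in this year.
#' Maintenance intervention cost (drug arms) applies to recoverers only.
#' All amounts are undiscounted (year 1). Vectorised over parameter draws.
#'
#' @param p_recover probability of recovery at end of treatment.
#' @param relapse_y1 first-year relapse probability of recoverers.
#' @param cost_initial initial intervention cost (GBP).
#' @param cost_maintenance maintenance intervention cost incurred by
#'   recoverers (GBP, drug arms; 0 otherwise).
#' @param u_recovered,u_sad state utilities.
#' @param cost_recovered_annual,cost_sad_annual annual state costs (GBP).
#' @param treatment_weeks,post_weeks treatment and post-treatment durations
#'   in weeks (52-week years).
#' @return List with `recovered` (end-of-year fraction recovered), `cost`
#'   and `qaly`, each the common length of the inputs.
#' @export
run_decision_tree_year <- function(p_recover, relapse_y1,
                                   cost_initial, cost_maintenance = 0,
                                   u_recovered, u_sad,
                                   cost_recovered_annual, cost_sad_annual,
                                   treatment_weeks = 12, post_weeks = 52) {
  if (any(p_recover < 0 | p_recover > 1) || any(relapse_y1 < 0 | relapse_y1 > 1))
    stop("probabilities must lie in [0, 1]")
  tw <- treatment_weeks / 52
  pw <- post_weeks / 52
  stay <- p_recover * (1 - relapse_y1)
  rel <- p_recover * relapse_y1
  fail <- 1 - p_recover

  qaly <- qaly_segment(u_sad, u_recovered, tw) * p_recover +
    qaly_segment(u_sad, u_sad, tw) * fail +
    (stay * u_recovered +
       rel * (u_recovered + u_sad) / 2 +
       fail * u_sad) * pw

  cost <- cost_initial + p_recover * cost_maintenance +
    (stay * cost_recovered_annual +
       rel * (cost_recovered_annual + cost_sad_annual) / 2 +
       fail * cost_sad_annual) * pw

  list(recovered = stay, cost = cost, qaly = qaly)
}

#' Markov years: two-state cohort model with half-cycle correction
#'
#' Runs yearly cycles of the recovered / social-anxiety-disorder two-state
#' model. Each cycle, the ill recover with probability `p_recover_annual`
#' and the recovered relapse with probability `p_relapse_annual`. QALYs and
#' state costs are credited at the average of start- and end-of-cycle
#' occupancy (half-cycle correction) and discounted by
#' `(1 + r)^-(year_offset + k - 1)` for cycle `k`; with the default offset,
#' cycle k covers calendar year k + 1 of the model. The fraction well at the
#' horizon is read after the final transition, before any averaging.
#' Vectorised over parameter draws.
#'
#' @param start_recovered fraction recovered at entry.
#' @param p_recover_annual,p_relapse_annual annual transition probabilities.
#' @param cycles number of yearly cycles (>= 0).
#' @param u_recovered,u_sad state utilities.
#' @param cost_recovered_annual,cost_sad_annual annual state costs (GBP).
#' @param discount_rate annual discount rate.
#' @param half_cycle if `FALSE`, cycles are credited at end-of-cycle
#'   occupancy (plain occupancy-weighted sum).
#' @param year_offset model year at which the first cycle is discounted.
#' @return List with `recovered` (fraction well at horizon), `cost`, `qaly`.
#' @export
run_markov_years <- function(start_recovered, p_recover_annual,
                             p_relapse_annual, cycles,
                             u_recovered, u_sad,
                             cost_recovered_annual, cost_sad_annual,
                             discount_rate = 0.035, half_cycle = TRUE,
                             year_offset = 1) {
  if (any(start_recovered < 0 | start_recovered > 1))
    stop("start occupancy must lie in [0, 1]")
  if (any(p_recover_annual < 0 | p_recover_annual > 1) ||
      any(p_relapse_annual < 0 | p_relapse_annual > 1))
    stop("transition probabilities must lie in [0, 1]")
  if (cycles < 0) stop("cycles must be nonnegative")
  occ <- start_recovered
  qaly <- 0
  cost <- 0
  if (cycles >= 1) for (k in seq_len(cycles)) {
    occ_end <- occ * (1 - p_relapse_annual) + (1 - occ) * p_recover_annual
    credit <- if (half_cycle) (occ + occ_end) / 2 else occ_end
    df <- (1 + discount_rate)^(-(year_offset + k - 1))
    qaly <- qaly + (credit * u_recovered + (1 - credit) * u_sad) * df
    cost <- cost + (credit * cost_recovered_annual +
                      (1 - credit) * cost_sad_annual) * df
    occ <- occ_end
  }
  list(recovered = occ, cost = cost, qaly = qaly)
}

#' Evaluate one intervention cohort over the full model horizon
#'
#' Composes the decision-tree year and the Markov years into discounted
#' totals. Deterministic given its inputs; vectorised over parameter draws,
#' so a whole probabilistic-sensitivity-analysis column can be evaluated in
#' one call.
#'
#' @param p_recover end-of-treatment recovery probability.
#' @param relapse_y1 first-year relapse probability for this arm's relapse
#'   class.
#' @param cost_initial,cost_maintenance intervention cost components (GBP);
#'   maintenance is incurred by recoverers only.
#' @param draw named list (or environment) of parameter values:
#'   `u_recovered`, `u_sad`, `cost_recovered`, `cost_sad`,
#'   `recovery_annual`, `relapse_annual`; each scalar or a vector of draws.
#' @param params a [sad_parameters] object (timeline and discounting).
#' @return `data.frame` of class `sad_cohort_result` with columns `cost`
#'   (discounted GBP), `qaly` (discounted QALYs) and `well` (fraction with
#'   no social anxiety disorder at the horizon).
#' @export
evaluate_cohort <- function(p_recover, relapse_y1, cost_initial,
                            cost_maintenance = 0, draw, params) {
  stopifnot(inherits(params, "sad_parameters"))
  y1 <- run_decision_tree_year(
    p_recover, relapse_y1, cost_initial, cost_maintenance,
    u_recovered = draw$u_recovered, u_sad = draw$u_sad,
    cost_recovered_annual = draw$cost_recovered,
    cost_sad_annual = draw$cost_sad,
    treatment_weeks = params$treatment_weeks,
    post_weeks = params$post_treatment_weeks_y1)
  mk <- run_markov_years(
    y1$recovered, draw$recovery_annual, draw$relapse_annual,
    cycles = params$markov_cycles,
    u_recovered = draw$u_recovered, u_sad = draw$u_sad,
    cost_recovered_annual = draw$cost_recovered,
    cost_sad_annual = draw$cost_sad,
    discount_rate = params$discount_rate)
  out <- data.frame(cost = y1$cost + mk$cost,
                    qaly = y1$qaly + mk$qaly,
                    well = mk$recovered)
  class(out) <- c("sad_cohort_result", class(out))
  out
}
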