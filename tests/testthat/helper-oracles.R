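# Independent oracles used across the suite. These are deliberately written
# as naive, slow implementations so they share no code path with the package.

# Exhaustive dominance oracle: an option is on the efficiency frontier iff it
# maximises lambda * qaly - cost for some positive willingness-to-pay. The
# candidate lambdas are all pairwise slopes, perturbed to either side, plus
# near-zero and very large values. Returns the set of (qaly, cost) pairs on
# the frontier (duplicate points collapse).
oracle_frontier_points <- function(cost, qaly) {
  n <- length(cost)
  slopes <- c()
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (qaly[i] != qaly[j]) {
      s <- (cost[i] - cost[j]) / (qaly[i] - qaly[j])
      if (is.finite(s) && s > 0) slopes <- c(slopes, s)
    }
  }
  lams <- sort(unique(c(1e-9, slopes * (1 - 1e-7), slopes * (1 + 1e-7),
                        (max(c(slopes, 1)) + 1) * 10)))
  on_front <- rep(FALSE, n)
  for (l in lams) {
    nmb <- l * qaly - cost
    on_front[nmb >= max(nmb) - 1e-9] <- TRUE
  }
  unique(paste(signif(qaly[on_front], 12), signif(cost[on_front], 12)))
}

frontier_points <- function(front) {
  keep <- front$status == "frontier"
  unique(paste(signif(front$qaly[keep], 12), signif(front$cost[keep], 12)))
}

# Scalar transition-matrix cohort oracle (spreadsheet style): one number at a
# time, explicit 2x2 transition matrix, no vectorisation.
oracle_cohort <- function(p_rec, rel1, cost_init, cost_maint,
                          u_r, u_s, c_r, c_s,
                          p_rec_ann, p_rel_ann, cycles, r,
                          treatment_weeks = 12, post_weeks = 52) {
  tw <- treatment_weeks / 52
  pw <- post_weeks / 52
  qaly <- p_rec * (u_s + u_r) / 2 * tw + (1 - p_rec) * u_s * tw
  stay <- p_rec * (1 - rel1)
  relp <- p_rec * rel1
  fail <- 1 - p_rec
  qaly <- qaly + (stay * u_r + relp * (u_r + u_s) / 2 + fail * u_s) * pw
  cost <- cost_init + p_rec * cost_maint +
    (stay * c_r + relp * (c_r + c_s) / 2 + fail * c_s) * pw
  state <- c(stay, 1 - stay)
  P <- matrix(c(1 - p_rel_ann, p_rel_ann,
                p_rec_ann, 1 - p_rec_ann), 2, 2, byrow = TRUE)
  for (k in seq_len(cycles)) {
    state_new <- as.vector(state %*% P)
    mid <- (state + state_new) / 2
    qaly <- qaly + (mid[1] * u_r + mid[2] * u_s) / (1 + r)^k
    cost <- cost + (mid[1] * c_r + mid[2] * c_s) / (1 + r)^k
    state <- state_new
  }
  list(cost = cost, qaly = qaly, well = state[1])
}

# logistic-normal mean by adaptive quadrature (oracle for posterior column
# means under the shared-baseline generative model)
logistic_normal_mean <- function(mean, variance) {
  stats::integrate(function(x) stats::plogis(x) * stats::dnorm(x, mean, sqrt(variance)),
                   -Inf, Inf)$value
}

# a small draw list with equal utilities / unit costs for engine edge cases
flat_draw <- function(u = 0.7, c_state = 0) {
  list(u_recovered = u, u_sad = u, cost_recovered = c_state, cost_sad = c_state,
       recovery_annual = 0, relapse_annual = 0)
}
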