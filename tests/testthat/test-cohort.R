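test_that("QALY segments integrate the linear utility path with discounting", {
  expect_equal(qaly_segment(0.7, 0.7, 1), 0.7)
  expect_equal(qaly_segment(0.659, 0.866, 12 / 52), (0.659 + 0.866) / 2 * 12 / 52)
  expect_equal(round(qaly_segment(0.659, 0.866, 12 / 52), 5), 0.17596)
  expect_equal(qaly_segment(0.7, 0.7, 1, 0.035, 1), 0.7 / 1.035)
  expect_error(qaly_segment(0.7, 0.7, -1), "nonnegative")
  expect_error(qaly_segment(1.2, 0.7, 1), "utilities")
})

test_that("the decision-tree year handles degenerate cohorts in closed form", {
  # nobody recovers: a full year at the ill-state utility plus treatment ramp
  r0 <- run_decision_tree_year(0, 0.4, cost_initial = 500, cost_maintenance = 100,
                               u_recovered = 0.866, u_sad = 0.659,
                               cost_recovered_annual = 645,
                               cost_sad_annual = 1037)
  expect_equal(r0$recovered, 0)
  expect_equal(r0$qaly, 0.659 * (12 / 52 + 1))
  expect_equal(r0$cost, 500 + 1037)  # maintenance never triggered

  # everyone recovers, nobody relapses
  r1 <- run_decision_tree_year(1, 0, cost_initial = 0,
                               u_recovered = 0.866, u_sad = 0.659,
                               cost_recovered_annual = 645,
                               cost_sad_annual = 1037)
  expect_equal(r1$recovered, 1)
  expect_equal(r1$qaly, (0.659 + 0.866) / 2 * 12 / 52 + 0.866)
  expect_equal(r1$cost, 645)

  # product rule for end-of-year occupancy at the published drug relapse
  r2 <- run_decision_tree_year(0.5, 0.4169, 0, 0, 0.866, 0.659, 645, 1037)
  expect_equal(r2$recovered, 0.29155)

  expect_error(run_decision_tree_year(1.2, 0, 0, 0, 0.9, 0.6, 1, 1),
               "probabilities")
})

test_that("maintenance cost accrues to recoverers only", {
  base <- run_decision_tree_year(0.4, 0, 100, 0, 0.9, 0.6, 0, 0)
  with_m <- run_decision_tree_year(0.4, 0, 100, 250, 0.9, 0.6, 0, 0)
  expect_equal(with_m$cost - base$cost, 0.4 * 250)
})

test_that("the Markov engine matches geometric compounding and fixed points", {
  # no flows: absorbing chain, QALYs are cycles x utility when undiscounted
  m0 <- run_markov_years(1, 0, 0, 4, 0.866, 0.659, 0, 0, discount_rate = 0)
  expect_equal(m0$recovered, 1)
  expect_equal(m0$qaly, 4 * 0.866)

  # pure recovery from the ill state compounds geometrically
  m1 <- run_markov_years(0, 0.0377, 0, 4, 0.866, 0.659, 0, 0)
  expect_equal(m1$recovered, 1 - (1 - 0.0377)^4, tolerance = 1e-12)

  # the stationary mix is invariant
  p_rec <- 0.0377; p_rel <- 0.0409
  eq <- p_rec / (p_rec + p_rel)
  meq <- run_markov_years(eq, p_rec, p_rel, 7, 0.9, 0.6, 0, 0)
  expect_equal(meq$recovered, eq, tolerance = 1e-12)

  # zero cycles: pass-through
  mz <- run_markov_years(0.3, 0.5, 0.5, 0, 0.9, 0.6, 100, 200)
  expect_equal(mz$recovered, 0.3)
  expect_equal(mz$qaly, 0)
  expect_equal(mz$cost, 0)
})

test_that("without half-cycle correction and discounting, cycles sum end occupancy", {
  occ <- 0.25; p_rec <- 0.1; p_rel <- 0.2; u_r <- 0.9; u_s <- 0.5
  m <- run_markov_years(occ, p_rec, p_rel, 3, u_r, u_s, 10, 20,
                        discount_rate = 0, half_cycle = FALSE)
  # closed-form occupancy-weighted sum
  o <- occ; q <- 0; cost <- 0
  for (k in 1:3) {
    o <- o * (1 - p_rel) + (1 - o) * p_rec
    q <- q + o * u_r + (1 - o) * u_s
    cost <- cost + o * 10 + (1 - o) * 20
  }
  expect_equal(m$qaly, q, tolerance = 1e-12)
  expect_equal(m$cost, cost, tolerance = 1e-12)
  expect_equal(m$recovered, o, tolerance = 1e-12)
})

test_that("evaluate_cohort equals the independent transition-matrix oracle", {
  params <- sad_parameters()
  set.seed(99)
  for (rep in 1:20) {
    p_rec <- runif(1); rel1 <- runif(1)
    ci <- runif(1, 0, 3000); cm <- runif(1, 0, 500)
    u_r <- runif(1, 0.5, 1); u_s <- runif(1, 0, u_r)
    c_r <- runif(1, 0, 1000); c_s <- runif(1, 0, 2000)
    pa <- runif(1, 0, 0.3); pb <- runif(1, 0, 0.3)
    draw <- list(u_recovered = u_r, u_sad = u_s, cost_recovered = c_r,
                 cost_sad = c_s, recovery_annual = pa, relapse_annual = pb)
    got <- evaluate_cohort(p_rec, rel1, ci, cm, draw, params)
    want <- oracle_cohort(p_rec, rel1, ci, cm, u_r, u_s, c_r, c_s,
                          pa, pb, cycles = 4, r = 0.035)
    expect_equal(got$cost, want$cost, tolerance = 1e-10)
    expect_equal(got$qaly, want$qaly, tolerance = 1e-10)
    expect_equal(got$well, want$well, tolerance = 1e-10)
  }
})

test_that("a flow-free cohort with equal utilities accrues utility times model span", {
  params <- sad_parameters(discount_rate = 0)
  res <- evaluate_cohort(0.3, 0, 0, 0, flat_draw(u = 0.7), params)
  expect_equal(res$qaly, 0.7 * (12 / 52 + 5), tolerance = 1e-12)
})

test_that("QALYs are monotone in recovery and relapse, and bounded by discounting", {
  params <- sad_parameters()
  draw <- list(u_recovered = 0.866, u_sad = 0.659, cost_recovered = 645,
               cost_sad = 1037, recovery_annual = 0.0377,
               relapse_annual = 0.0409)
  p <- seq(0, 1, by = 0.1)
  q_by_p <- evaluate_cohort(p, 0.2, 0, 0, draw, params)$qaly
  expect_true(all(diff(q_by_p) > 0))

  rel <- seq(0, 1, by = 0.1)
  q_by_rel <- evaluate_cohort(0.5, rel, 0, 0, draw, params)$qaly
  expect_true(all(diff(q_by_rel) < 0))

  undiscounted <- evaluate_cohort(0.5, 0.2, 0, 0, draw,
                                  sad_parameters(discount_rate = 0))$qaly
  discounted <- evaluate_cohort(0.5, 0.2, 0, 0, draw, params)$qaly
  expect_lt(discounted, undiscounted)
  expect_lt(undiscounted, 0.866 * (12 / 52 + 5))
})

test_that("occupancy stays conserved and results stay within bounds across random draws", {
  params <- sad_parameters()
  set.seed(4)
  n <- 200
  draw <- list(u_recovered = runif(n, 0.5, 1), u_sad = runif(n, 0, 0.5),
               cost_recovered = runif(n, 0, 1000), cost_sad = runif(n, 0, 2000),
               recovery_annual = runif(n, 0, 1), relapse_annual = runif(n, 0, 1))
  res <- evaluate_cohort(runif(n), runif(n), runif(n, 0, 3000), 0, draw, params)
  expect_true(all(res$well >= 0 & res$well <= 1))
  expect_true(all(res$cost >= 0))
  expect_true(all(res$qaly >= 0 &
                    res$qaly <= draw$u_recovered * (12 / 52 + 5) + 1e-12))
})
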