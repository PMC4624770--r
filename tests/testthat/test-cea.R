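test_that("net monetary benefit is the linear valuation of QALYs minus cost", {
  expect_equal(net_monetary_benefit(1234, 3.2, 0), -1234)
  expect_equal(net_monetary_benefit(6178, 3.75, 20000), 68822)
  dC <- 300; dQ <- 0.12; t <- 25000
  expect_equal(net_monetary_benefit(1000 + dC, 2 + dQ, t) -
                 net_monetary_benefit(1000, 2, t),
               t * dQ - dC)
  expect_error(net_monetary_benefit(1, 1, -5), "nonnegative")
})

test_that("the frontier sweep classifies the toy three-option instance", {
  f <- incremental_frontier(c(100, 500, 600), c(1, 2, 3), c("A", "B", "C"))
  expect_equal(f$status, c("frontier", "extendedly dominated", "frontier"))
  expect_equal(f$icer, c(NA, NA, 250))

  single <- incremental_frontier(500, 2, "only")
  expect_equal(single$status, "frontier")
  expect_true(is.na(single$icer))
})

test_that("dominance ties break deterministically and collapse duplicates", {
  # same QALYs, higher cost: dominated
  f <- incremental_frontier(c(100, 150), c(1, 1), c("a", "b"))
  expect_equal(f$status, c("frontier", "dominated"))
  # exact ties collapse onto the first id
  f2 <- incremental_frontier(c(100, 100), c(1, 1), c("b", "a"))
  expect_equal(f2$status[f2$id == "a"], "frontier")
  expect_equal(f2$status[f2$id == "b"], "dominated")
})

test_that("the frontier sweep agrees with the exhaustive dominance oracle", {
  set.seed(12)
  for (rep in 1:60) {
    n <- sample(2:10, 1)
    cost <- round(runif(n, 0, 5000), 2)
    qaly <- round(runif(n, 0, 5), 3)
    f <- incremental_frontier(cost, qaly)
    expect_setequal(frontier_points(f), oracle_frontier_points(cost, qaly))
    # frontier ICERs strictly increase along increasing effectiveness
    fr <- f[f$status == "frontier", ]
    icers <- fr$icer[order(fr$qaly)][-1]
    if (length(icers) > 1) expect_true(all(diff(icers) > 0))
  }
})

test_that("every removed option is beaten by a frontier point or a mix of two", {
  set.seed(77)
  for (rep in 1:20) {
    n <- sample(3:10, 1)
    cost <- runif(n, 0, 5000); qaly <- runif(n, 0, 5)
    f <- incremental_frontier(cost, qaly)
    keep <- which(f$status == "frontier")
    for (i in which(f$status != "frontier")) {
      beaten <- FALSE
      for (j in keep) for (k in keep) for (lam in seq(0, 1, by = 0.01)) {
        qm <- lam * qaly[j] + (1 - lam) * qaly[k]
        cm <- lam * cost[j] + (1 - lam) * cost[k]
        if (qm >= qaly[i] - 1e-9 && cm <= cost[i] + 1e-9) { beaten <- TRUE; break }
      }
      expect_true(beaten)
    }
  }
})

test_that("the published means reproduce the published dominance structure", {
  t5 <- published_means()
  f <- incremental_frontier(t5$cost, t5$qaly, t5$id)
  expect_setequal(f$id[f$status == "frontier"],
                  c("shns_book", "phenelzine", "icbt_cw"))
  expect_equal(f$status[f$id == "icbt_general"], "extendedly dominated")
  # adjacent frontier ICERs from the rounded printed means
  expect_equal(f$icer[f$id == "phenelzine"], 1400, tolerance = 1e-6)
  expect_equal(f$icer[f$id == "icbt_cw"], 9005.6, tolerance = 1e-4)

  rank <- rank_interventions(t5$cost, t5$qaly, 20000, t5$id)
  expect_equal(t5$id[rank == 1], "icbt_cw")
  expect_equal(t5$id[rank == 28], "supportive")
})

test_that("rankings are invariant to uniform cost shifts and break ties by id", {
  t5 <- published_means()
  r1 <- rank_interventions(t5$cost, t5$qaly, 20000, t5$id)
  r2 <- rank_interventions(t5$cost + 500, t5$qaly, 20000, t5$id)
  expect_identical(r1, r2)
  r3 <- rank_interventions(c(10, 10), c(1, 1), 20000, c("b", "a"))
  expect_equal(r3, c(2L, 1L))
})

test_that("the acceptability frontier is exact for one option and matches the normal oracle for two", {
  one <- structure(list(cost = matrix(rnorm(50, 1000, 10), 50, 1,
                                      dimnames = list(NULL, "only")),
                        qaly = matrix(rnorm(50, 3, 0.1), 50, 1,
                                      dimnames = list(NULL, "only")),
                        well = matrix(0.5, 50, 1), ids = "only",
                        n_iter = 50), class = "sad_psa")
  cf <- ceaf(one, thresholds = c(0, 10000, 30000))
  expect_true(all(cf$prob == 1))
  expect_true(all(cf$best == "only"))

  # two options: P(B most cost-effective) has a closed normal form
  set.seed(6)
  n <- 40000
  dc <- rnorm(n, 400, 300); dq <- rnorm(n, 0.05, 0.04)
  psa2 <- structure(list(
    cost = cbind(A = rep(1000, n), B = 1000 + dc),
    qaly = cbind(A = rep(3, n), B = 3 + dq),
    well = matrix(0.5, n, 2, dimnames = list(NULL, c("A", "B"))),
    ids = c("A", "B"), n_iter = n), class = "sad_psa")
  for (t in c(5000, 20000, 40000)) {
    cf2 <- ceaf(psa2, thresholds = t)
    p_b <- pnorm((t * 0.05 - 400) / sqrt(t^2 * 0.04^2 + 300^2))
    expected <- if (cf2$best == "B") p_b else 1 - p_b
    expect_lt(abs(cf2$prob - expected), 0.01)
  }
  expect_error(ceaf(psa2, thresholds = numeric(0)), "nonempty")
})

test_that("the frontier probability never exceeds any option's own win probability", {
  psa <- run_psa(sad_model(), n_iter = 400, seed = 19)
  for (t in c(5000, 20000)) {
    nmb <- t * psa$qaly - psa$cost
    row_max <- apply(nmb, 1, max)
    is_max <- nmb == row_max
    win <- colMeans(is_max / rowSums(is_max))
    cf <- ceaf(psa, thresholds = t)
    expect_lte(cf$prob, max(win) + 1e-12)
    expect_equal(cf$prob, win[[cf$best]], tolerance = 1e-12)
  }
})

test_that("the cost-effectiveness plane puts the reference at the origin", {
  psa <- run_psa(sad_model(), n_iter = 100, seed = 23)
  s <- cea_summary(psa)
  pl <- ce_plane(s, reference = "wait_list", cohort_size = 1000)
  expect_equal(pl$delta_cost[pl$id == "wait_list"], 0)
  expect_equal(pl$delta_qaly[pl$id == "wait_list"], 0)
  expect_equal(pl$delta_qaly[pl$id == "icbt_cw"],
               (s$qaly[s$id == "icbt_cw"] - s$qaly[s$id == "wait_list"]) * 1000)
  expect_error(ce_plane(s, reference = "nope"), "not found")
})
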