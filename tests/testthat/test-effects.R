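test_that("the SMD to recovery log-odds bridge is the exact linear map", {
  expect_equal(smd_to_recovery_lor(0), 0)
  expect_equal(round(smd_to_recovery_lor(-1), 4), 1.8138)
  lor <- c(-2.1, 0, 0.4, 3.2)
  expect_equal(smd_to_recovery_lor(recovery_lor_to_smd(lor)), lor,
               tolerance = 1e-12)
  expect_error(smd_to_recovery_lor(Inf), "finite")
})

test_that("calibration recovers the published effect scale", {
  b <- baseline_log_odds()
  cw <- calibrate_effect_spec(0.65, 0.16, 0.95, b, id = "icbt_cw")
  expect_equal(cw$lor_mean, 3.25, tolerance = 0.005)
  expect_equal(cw$lor_sd, 0.38, tolerance = 0.005)
  expect_false(cw$floored)

  # the wait-list row itself calibrates to (almost) the null effect
  wl <- calibrate_effect_spec(0.07, 0.01, 0.39, b)
  expect_lt(abs(wl$lor_mean), 0.05)
  expect_equal(wl$lor_sd, 0)
  expect_true(wl$floored)

  # degenerate: summaries generated exactly by the baseline calibrate to (0, 0)
  med <- stats::plogis(b$mean)
  half <- stats::qnorm(0.975) * sqrt(b$variance)
  null <- calibrate_effect_spec(med, stats::plogis(b$mean - half),
                                stats::plogis(b$mean + half), b)
  expect_equal(null$lor_mean, 0, tolerance = 1e-12)
  expect_equal(null$lor_sd, 0, tolerance = 1e-6)

  expect_error(calibrate_effect_spec(0.5, 0.6, 0.9, b), "invalid recovery summary")
})

test_that("packaged effect specs pin wait list at the null effect", {
  specs <- default_effect_specs()
  expect_length(specs, 28L)
  expect_equal(specs$wait_list$lor_mean, 0)
  expect_equal(specs$wait_list$lor_sd, 0)
})

test_that("the synthetic posterior reproduces published marginals and is reproducible", {
  post <- sample_recovery_posterior(n_draws = 1e5, seed = 31)
  expect_true(all(post$draws > 0 & post$draws < 1))

  wl <- post$draws[, "wait_list"]
  expect_lt(abs(mean(wl) - 0.10), 0.01)
  expect_lt(abs(stats::median(wl) - 0.07), 0.01)
  expect_lt(abs(mean(post$draws[, "icbt_cw"]) - 0.62), 0.02)

  post2 <- sample_recovery_posterior(n_draws = 1e5, seed = 31)
  expect_identical(post$draws, post2$draws)
})

test_that("column means agree with the logistic-normal quadrature oracle", {
  b <- baseline_log_odds()
  specs <- default_effect_specs(b)
  post <- sample_recovery_posterior(specs, b, n_draws = 1e5, seed = 5)
  for (id in c("icbt_cw", "phenelzine", "shns_book", "supportive", "wait_list")) {
    s <- specs[[id]]
    expected <- logistic_normal_mean(b$mean + s$lor_mean,
                                     b$variance + s$lor_sd^2)
    mc_se <- stats::sd(post$draws[, id]) / sqrt(nrow(post$draws))
    expect_lt(abs(mean(post$draws[, id]) - expected), 3 * mc_se + 1e-4)
  }
})

test_that("calibration round-trips through sampling and summarising", {
  tab <- sad_recovery_table()
  post <- sample_recovery_posterior(n_draws = 1e5, seed = 13)
  s <- summarize_posterior(post)
  s <- s[match(tab$id, s$id), ]
  active <- tab$id != "wait_list"
  expect_lt(max(abs(s$median[active] - tab$median[active])), 0.01)
  expect_lt(max(abs(s$ci_low[active] - tab$ci_low[active])), 0.03)
  # the mindfulness interval is asymmetric on the logit scale beyond what a
  # median-anchored logistic-normal can express: its model-implied upper
  # bound sits 0.032 below the published one analytically, so it is checked
  # at that asymmetry rather than the common band
  sym <- active & tab$id != "mindfulness"
  expect_lt(max(abs(s$ci_high[sym] - tab$ci_high[sym])), 0.03)
  expect_lt(abs(s$ci_high[tab$id == "mindfulness"] - 0.63), 0.04)
})

test_that("interventions are positively rank-correlated through the shared baseline", {
  post <- sample_recovery_posterior(n_draws = 5000, seed = 9)
  pairs <- list(c("icbt_cw", "wait_list"), c("phenelzine", "sertraline"),
                c("shns_book", "supportive"))
  for (pr in pairs)
    expect_gt(stats::cor(post$draws[, pr[1]], post$draws[, pr[2]],
                         method = "spearman"), 0)
})

test_that("null effects collapse every column onto the baseline draw", {
  null_spec <- function(id)
    structure(list(id = id, lor_mean = 0, lor_sd = 0, floored = FALSE),
              class = "sad_effect_spec")
  post <- sample_recovery_posterior(list(null_spec("a"), null_spec("b")),
                                    n_draws = 100, seed = 3)
  expect_identical(post$draws[, "a"], post$draws[, "b"])
})

test_that("posterior summaries behave on degenerate input and order quantiles", {
  deg <- structure(list(draws = matrix(0.3, 50, 2,
                                       dimnames = list(NULL, c("x", "y"))),
                        ids = c("x", "y"), seed = NULL),
                   class = "sad_posterior")
  s <- summarize_posterior(deg)
  expect_equal(s$mean, c(0.3, 0.3))
  expect_equal(s$median, s$ci_low)
  expect_equal(s$median, s$ci_high)

  post <- sample_recovery_posterior(n_draws = 2000, seed = 2)
  s2 <- summarize_posterior(post)
  expect_true(all(s2$ci_low <= s2$median & s2$median <= s2$ci_high))
})
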