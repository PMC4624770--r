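#' Convert a standardised mean difference to a recovery log-odds ratio
#'
#' Uses the logistic-distribution bridge `LOR = -(pi / sqrt(3)) * SMD`: a
#' negative SMD (greater symptom reduction than the comparator) maps to a
#' positive log-odds ratio of recovery. [recovery_lor_to_smd()] is the exact
#' inverse.
#'
#' @param smd standardised mean difference (finite).
#' @param lor log-odds ratio of recovery (finite).
#' @return The transformed effect on the other scale.
#' @export
smd_to_recovery_lor <- function(smd) {
  if (any(!is.finite(smd))) stop("smd must be finite")
  -pi / sqrt(3) * smd
}

#' @rdname smd_to_recovery_lor
#' @export
recovery_lor_to_smd <- function(lor) {
  if (any(!is.finite(lor))) stop("lor must be finite")
  -sqrt(3) / pi * lor
}

#' Wait-list baseline recovery log-odds
#'
#' The log-odds of end-of-treatment recovery on wait list is modelled as a
#' normal distribution; relative treatment effects are added to draws from
#' this baseline before inverse-logit transformation.
#'
#' @param mean baseline log-odds mean.
#' @param variance baseline log-odds variance (> 0).
#' @return An object of class `sad_baseline`.
#' @export
baseline_log_odds <- function(mean = -2.629, variance = 1.235) {
  if (!(variance > 0)) stop("baseline variance must be positive")
  structure(list(mean = mean, variance = variance), class = "sad_baseline")
}

logit <- function(p) log(p / (1 - p))

#' Calibrate a treatment-effect distribution to published recovery summaries
#'
#' The synthetic posterior assumes, per draw, `logit(p) = b + d` with
#' `b ~ Normal(baseline)` shared across interventions and
#' `d ~ Normal(lor_mean, lor_sd^2)` independent per intervention. Given a
#' published median and 95% credible interval of the recovery probability,
#' the monotone logit maps the median directly:
#' `lor_mean = logit(median) - baseline mean`, and the effect variance is
#' recovered by subtracting the baseline variance from the squared logit-scale
#' interval width divided by `2 * qnorm(0.975)`. When the published interval
#' is narrower than the baseline alone implies, the effect variance is floored
#' at zero and the spec is flagged (`floored = TRUE`).
#'
#' @param median_p,cri_low,cri_high published median and 95% credible
#'   interval of the recovery probability, with
#'   `0 < cri_low < median_p < cri_high < 1`.
#' @param baseline a [baseline_log_odds] object.
#' @param id optional intervention identifier carried through.
#' @return An object of class `sad_effect_spec` with fields `id`,
#'   `lor_mean`, `lor_sd`, `floored`.
#' @export
calibrate_effect_spec <- function(median_p, cri_low, cri_high,
                                  baseline = baseline_log_odds(), id = NULL) {
  stopifnot(inherits(baseline, "sad_baseline"))
  if (!(cri_low > 0 && cri_low < median_p && median_p < cri_high && cri_high < 1))
    stop("invalid recovery summary: need 0 < cri_low < median < cri_high < 1")
  lor_mean <- logit(median_p) - baseline$mean
  width <- (logit(cri_high) - logit(cri_low)) / (2 * stats::qnorm(0.975))
  v <- width^2 - baseline$variance
  structure(list(id = id, lor_mean = lor_mean,
                 lor_sd = sqrt(max(0, v)), floored = v < 0),
            class = "sad_effect_spec")
}

#' Packaged treatment-effect specifications
#'
#' Calibrates one effect spec per intervention from the packaged recovery
#' summary table. Wait list is the reference and is pinned at a null effect
#' (`lor_mean = 0`, `lor_sd = 0`) rather than calibrated, so its recovery
#' distribution is exactly the inverse-logit of the baseline normal.
#'
#' @param baseline a [baseline_log_odds] object.
#' @param table recovery summary table, as [sad_recovery_table()].
#' @return Named list of `sad_effect_spec` objects in table order.
#' @export
default_effect_specs <- function(baseline = baseline_log_odds(),
                                 table = sad_recovery_table()) {
  specs <- lapply(seq_len(nrow(table)), function(i) {
    if (table$id[i] == "wait_list")
      structure(list(id = "wait_list", lor_mean = 0, lor_sd = 0,
                     floored = FALSE), class = "sad_effect_spec")
    else
      calibrate_effect_spec(table$median[i], table$ci_low[i], table$ci_high[i],
                            baseline, id = table$id[i])
  })
  names(specs) <- table$id
  specs
}

#' Sample the synthetic recovery posterior
#'
#' Generates joint draws of end-of-treatment recovery probabilities across
#' all interventions. Per draw, one shared baseline value `b` is sampled and
#' an independent effect `d_k` per intervention; the recovery probability is
#' `plogis(b + d_k)`. Sharing `b` induces the positive cross-intervention
#' rank correlation that the published method implies, while every marginal
#' reproduces its published summaries.
#'
#' @param specs named list of `sad_effect_spec` objects (all interventions).
#' @param baseline a [baseline_log_odds] object.
#' @param n_draws number of joint draws (default 10,000).
#' @param seed optional integer seed for reproducibility.
#' @return An object of class `sad_posterior`: list with `draws`
#'   (`n_draws x n_interventions` matrix of probabilities strictly inside
#'   (0, 1)), `ids`, and the `seed` used.
#' @export
sample_recovery_posterior <- function(specs = default_effect_specs(),
                                      baseline = baseline_log_odds(),
                                      n_draws = 10000L, seed = NULL) {
  stopifnot(inherits(baseline, "sad_baseline"), n_draws >= 1)
  if (length(specs) == 0L) stop("no treatment-effect specs supplied")
  if (!all(vapply(specs, inherits, logical(1), "sad_effect_spec")))
    stop("specs must be a list of sad_effect_spec objects")
  ids <- vapply(specs, function(s) s$id, character(1))
  if (anyNA(ids) || anyDuplicated(ids))
    stop("every effect spec needs a unique intervention id")
  if (!is.null(seed)) set.seed(seed)
  b <- stats::rnorm(n_draws, baseline$mean, sqrt(baseline$variance))
  draws <- vapply(specs, function(s) {
    d <- if (s$lor_sd > 0) stats::rnorm(n_draws, s$lor_mean, s$lor_sd)
         else s$lor_mean
    stats::plogis(b + d)
  }, numeric(n_draws))
  draws <- matrix(draws, nrow = n_draws,
                  dimnames = list(NULL, unname(ids)))
  structure(list(draws = draws, ids = unname(ids), seed = seed),
            class = "sad_posterior")
}

#' @export
print.sad_posterior <- function(x, ...) {
  cat("<sad_posterior> ", nrow(x$draws), " draws x ", ncol(x$draws),
      " interventions\n", sep = "")
  invisible(x)
}

#' Summarise a recovery posterior
#'
#' Column-wise mean, median and 95% credible interval, in the layout of the
#' published recovery table, for validation against it.
#'
#' @param posterior a `sad_posterior` object.
#' @return `data.frame` with columns `id`, `mean`, `median`, `ci_low`,
#'   `ci_high`.
#' @export
summarize_posterior <- function(posterior) {
  stopifnot(inherits(posterior, "sad_posterior"), nrow(posterior$draws) > 0)
  d <- posterior$draws
  data.frame(id = posterior$ids,
             mean = colMeans(d),
             median = apply(d, 2, stats::median),
             ci_low = apply(d, 2, stats::quantile, probs = 0.025),
             ci_high = apply(d, 2, stats::quantile, probs = 0.975),
             row.names = NULL)
}

#' Read or write a recovery draw matrix as delimited text
#'
#' The exchange format is tab-separated text with a header row of
#' intervention ids and one row per draw, so an externally estimated
#' posterior can replace the synthetic one.
#'
#' @param posterior a `sad_posterior` object.
#' @param file path to the delimited text file.
#' @return `read_posterior()` returns a `sad_posterior`;
#'   `write_posterior()` returns `file` invisibly.
#' @export
write_posterior <- function(posterior, file) {
  stopifnot(inherits(posterior, "sad_posterior"))
  utils::write.table(posterior$draws, file, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(file)
}

#' @rdname write_posterior
#' @export
read_posterior <- function(file) {
  d <- as.matrix(utils::read.delim(file, check.names = FALSE))
  if (any(!is.finite(d)) || any(d <= 0) || any(d >= 1))
    stop("posterior draws must be probabilities strictly inside (0, 1)")
  structure(list(draws = d, ids = colnames(d), seed = NULL),
            class = "sad_posterior")
}
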