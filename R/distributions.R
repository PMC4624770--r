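#' Parameter distributions for probabilistic sensitivity analysis
#'
#' Each uncertain model input is described by a `sad_dist` object: a
#' distribution family, its family-specific parameters, and a deterministic
#' `point` value used in analyses at means. The families cover the ways the
#' model's input parameters are reported in the source evidence: beta
#' distributions given as event counts, gammas given as mean and standard
#' error (method of moments), log-normals given as a central value with a 95%
#' confidence interval, normals given as mean and standard deviation
#' (optionally truncated at zero for quantities such as contact minutes),
#' categorical distributions over visit or session counts, the midpoint of two
#' independent beta distributions, and degenerate point values.
#'
#' @param value point value returned by every draw.
#' @param alpha,beta beta-distribution shape counts (both > 0).
#' @param mean central value: the gamma/normal mean, or the reported central
#'   value of a log-normal quantity.
#' @param se standard error of a gamma-distributed cost (> 0).
#' @param ci_low,ci_high bounds of a 95% confidence interval assumed symmetric
#'   on the log scale.
#' @param sd normal standard deviation (>= 0).
#' @param truncate_zero if `TRUE`, normal draws are truncated below at zero
#'   (by resetting negative draws to zero, so the point mass sits at 0).
#' @param values,probs categorical support and probabilities (`probs` must be
#'   nonnegative and sum to 1 within 1e-9).
#' @param alpha1,beta1,alpha2,beta2 counts of the two betas whose draws are
#'   averaged.
#' @param point deterministic value used when the model is evaluated at
#'   means; defaults to the analytic mean (or, for categorical families, must
#'   be supplied).
#'
#' @return An object of class `sad_dist`.
#' @name sad_dist
NULL

new_dist <- function(family, params, point) {
  structure(list(family = family, params = params, point = point),
            class = "sad_dist")
}

#' @export
print.sad_dist <- function(x, ...) {
  cat("<sad_dist ", x$family, "> point = ", format(x$point), "\n", sep = "")
  invisible(x)
}

#' @rdname sad_dist
#' @export
dist_point <- function(value) {
  stopifnot(is.numeric(value), length(value) == 1L, is.finite(value))
  new_dist("point", list(value = value), point = value)
}

#' @rdname sad_dist
#' @export
dist_beta_counts <- function(alpha, beta, point = NULL) {
  if (!is.numeric(alpha) || !is.numeric(beta) || alpha <= 0 || beta <= 0)
    stop("beta-counts distribution requires alpha > 0 and beta > 0")
  new_dist("beta-counts", list(alpha = alpha, beta = beta),
           point = if (is.null(point)) alpha / (alpha + beta) else point)
}

#' @rdname sad_dist
#' @export
dist_gamma_mean_se <- function(mean, se, point = NULL) {
  if (!is.numeric(mean) || !is.numeric(se) || mean <= 0 || se <= 0)
    stop("gamma-mean-se distribution requires mean > 0 and se > 0")
  mm <- gamma_from_mean_se(mean, se)
  new_dist("gamma-mean-se",
           list(mean = mean, se = se,
                shape = mm[["shape"]], scale = mm[["scale"]]),
           point = if (is.null(point)) mean else point)
}

#' @rdname sad_dist
#' @export
dist_lognormal_ci <- function(mean, ci_low, ci_high, point = NULL) {
  if (!(ci_low > 0 && ci_low < ci_high))
    stop("log-normal-ci distribution requires 0 < ci_low < ci_high")
  meanlog <- (log(ci_low) + log(ci_high)) / 2
  sdlog <- (log(ci_high) - log(ci_low)) / (2 * stats::qnorm(0.975))
  new_dist("log-normal-ci",
           list(mean = mean, ci_low = ci_low, ci_high = ci_high,
                meanlog = meanlog, sdlog = sdlog),
           point = if (is.null(point)) mean else point)
}

#' @rdname sad_dist
#' @export
dist_normal <- function(mean, sd, truncate_zero = FALSE, point = NULL) {
  if (!is.numeric(sd) || sd < 0) stop("normal distribution requires sd >= 0")
  new_dist("normal",
           list(mean = mean, sd = sd, truncate_zero = isTRUE(truncate_zero)),
           point = if (is.null(point)) mean else point)
}

#' @rdname sad_dist
#' @export
dist_categorical <- function(values, probs, point = NULL) {
  if (length(values) != length(probs) || length(values) == 0L)
    stop("categorical distribution requires matching, nonempty values/probs")
  if (any(probs < 0) || abs(sum(probs) - 1) > 1e-9)
    stop("categorical probabilities must be nonnegative and sum to 1")
  new_dist("categorical", list(values = values, probs = probs),
           point = if (is.null(point)) values[which.max(probs)] else point)
}

#' @rdname sad_dist
#' @export
dist_beta_midpoint <- function(alpha1, beta1, alpha2, beta2, point = NULL) {
  if (any(c(alpha1, beta1, alpha2, beta2) <= 0))
    stop("midpoint-of-two-betas requires all four counts > 0")
  new_dist("midpoint-of-two-betas",
           list(alpha1 = alpha1, beta1 = beta1, alpha2 = alpha2, beta2 = beta2),
           point = if (is.null(point))
             (alpha1 / (alpha1 + beta1) + alpha2 / (alpha2 + beta2)) / 2
           else point)
}

#' Analytic mean of a parameter distribution
#'
#' Closed-form expectation of a [sad_dist] object. For a zero-truncated
#' normal this is the mean of the censored variable `max(X, 0)`.
#'
#' @param spec a `sad_dist` object.
#' @return The expectation as a single number.
#' @export
dist_mean <- function(spec) {
  stopifnot(inherits(spec, "sad_dist"))
  p <- spec$params
  switch(spec$family,
    "point" = p$value,
    "beta-counts" = p$alpha / (p$alpha + p$beta),
    "gamma-mean-se" = p$mean,
    "log-normal-ci" = exp(p$meanlog + p$sdlog^2 / 2),
    "normal" = if (p$truncate_zero) {
      z <- p$mean / p$sd
      p$mean * stats::pnorm(z) + p$sd * stats::dnorm(z)
    } else p$mean,
    "categorical" = sum(p$values * p$probs),
    "midpoint-of-two-betas" =
      (p$alpha1 / (p$alpha1 + p$beta1) + p$alpha2 / (p$alpha2 + p$beta2)) / 2,
    stop("unsupported distribution family: ", spec$family)
  )
}

#' Draw from a parameter distribution
#'
#' Samples `n` independent values from a [sad_dist] object using the current
#' R random number stream, so draws are reproducible under `set.seed()`.
#' The midpoint-of-two-betas family draws each beta independently and
#' averages the two draws.
#'
#' @param spec a `sad_dist` object.
#' @param n number of draws.
#' @return Numeric vector of length `n`.
#' @export
sample_dist <- function(spec, n = 1L) {
  stopifnot(inherits(spec, "sad_dist"), n >= 1)
  p <- spec$params
  switch(spec$family,
    "point" = rep(p$value, n),
    "beta-counts" = stats::rbeta(n, p$alpha, p$beta),
    "gamma-mean-se" = stats::rgamma(n, shape = p$shape, scale = p$scale),
    "log-normal-ci" = stats::rlnorm(n, meanlog = p$meanlog, sdlog = p$sdlog),
    "normal" = {
      x <- stats::rnorm(n, p$mean, p$sd)
      if (p$truncate_zero) pmax(x, 0) else x
    },
    "categorical" = p$values[sample.int(length(p$values), n, replace = TRUE,
                                        prob = p$probs)],
    "midpoint-of-two-betas" =
      (stats::rbeta(n, p$alpha1, p$beta1) + stats::rbeta(n, p$alpha2, p$beta2)) / 2,
    stop("unsupported distribution family: ", spec$family)
  )
}

#' Mean of a beta distribution given as counts
#'
#' @param alpha,beta positive shape counts.
#' @return `alpha / (alpha + beta)`.
#' @export
beta_mean_from_counts <- function(alpha, beta) {
  if (any(alpha <= 0) || any(beta <= 0))
    stop("beta counts must both be positive")
  alpha / (alpha + beta)
}

#' Method-of-moments gamma parameters from a mean and standard error
#'
#' @param mean,se positive mean and standard error (same units, e.g. GBP).
#' @return Named vector with `shape = (mean/se)^2` and `scale = se^2/mean`,
#'   so the resulting gamma has exactly the given mean and SE.
#' @export
gamma_from_mean_se <- function(mean, se) {
  if (any(mean <= 0) || any(se <= 0))
    stop("gamma mean and se must both be positive")
  c(shape = (mean / se)^2, scale = se^2 / mean)
}

#' Convert a multi-year probability to an annual probability
#'
#' Constant-hazard conversion `1 - (1 - p)^(1/years)`, the standard
#' actuarial assumption for spreading a cumulative probability over equal
#' yearly intervals. [annual_to_multi_year_prob()] is its inverse
#' (geometric compounding).
#'
#' @param p_multi cumulative probability over the whole period, in `[0, 1)`.
#' @param p_annual annual probability, in `[0, 1)`.
#' @param years number of years in the period (>= 1).
#' @return A probability in `[0, 1)`.
#' @export
multi_year_to_annual_prob <- function(p_multi, years) {
  if (any(years < 1)) stop("years must be >= 1")
  if (any(p_multi < 0) || any(p_multi >= 1))
    stop("p_multi must lie in [0, 1); a probability of 1 implies infinite hazard")
  1 - (1 - p_multi)^(1 / years)
}

#' @rdname multi_year_to_annual_prob
#' @export
annual_to_multi_year_prob <- function(p_annual, years) {
  if (any(years < 1)) stop("years must be >= 1")
  if (any(p_annual < 0) || any(p_annual >= 1))
    stop("p_annual must lie in [0, 1)")
  1 - (1 - p_annual)^years
}

#' First-year relapse probability after pharmacological treatment
#'
#' The point estimate is the midpoint of two pooled relapse risks, each a
#' beta mean: relapse during maintenance treatment in active drug arms, and
#' relapse of drug responders re-randomised to placebo.
#'
#' @param first,second length-2 vectors `c(alpha, beta)` of the two pooled
#'   beta counts.
#' @return Arithmetic mean of the two beta means.
#' @export
drug_relapse_year1 <- function(first = c(107, 293), second = c(222, 170)) {
  (beta_mean_from_counts(first[1], first[2]) +
     beta_mean_from_counts(second[1], second[2])) / 2
}

#' First-year relapse probability after psychological treatment
#'
#' Divides the drug relapse probability by the relapse risk ratio of drugs
#' versus psychological therapy, clipping the result into `[0, 1]`.
#'
#' @param p_drug first-year relapse probability for drugs, in `[0, 1]`.
#' @param rr risk ratio of relapse, drugs versus psychological therapy (> 0).
#' @return A probability in `[0, 1]`.
#' @export
psych_relapse_year1 <- function(p_drug, rr) {
  if (any(p_drug < 0) || any(p_drug > 1)) stop("p_drug must lie in [0, 1]")
  if (any(rr <= 0)) stop("relapse risk ratio must be positive")
  pmin(1, pmax(0, p_drug / rr))
}
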