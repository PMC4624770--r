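#' Net monetary benefit
#'
#' Linearises cost-effectiveness at a willingness-to-pay threshold:
#' `NMB = threshold x QALYs - cost`. The option with the highest NMB at a
#' threshold is the most cost-effective at that threshold.
#'
#' @param cost cost in GBP.
#' @param qaly QALYs.
#' @param threshold willingness to pay per QALY in GBP (>= 0).
#' @return NMB in GBP (vectorised).
#' @export
net_monetary_benefit <- function(cost, qaly, threshold) {
  if (any(threshold < 0)) stop("threshold must be nonnegative")
  threshold * qaly - cost
}

#' Incremental analysis: dominance and the efficiency frontier
#'
#' Classifies every option as on the efficiency frontier, absolutely
#' dominated (another option has no more cost and no fewer QALYs, strictly
#' better in one; exact ties collapse onto the first option in id order) or
#' extendedly dominated (removed by the increasing-ICER sweep: an option
#' whose incremental cost-effectiveness ratio against the previous frontier
#' member exceeds the next one's is beaten by a linear combination of its
#' neighbours). Frontier members are reported with the ICER against the
#' previous member, and frontier ICERs are strictly increasing.
#'
#' @param mean_costs,mean_qalys per-option mean costs and QALYs.
#' @param ids option identifiers (used for deterministic tie-breaks).
#' @return `data.frame` with columns `id`, `cost`, `qaly`, `status`
#'   (`"frontier"`, `"dominated"`, `"extendedly dominated"`) and `icer`
#'   (NA off the frontier and for its cheapest member), in input order.
#' @export
incremental_frontier <- function(mean_costs, mean_qalys, ids = NULL) {
  n <- length(mean_costs)
  if (n < 1 || length(mean_qalys) != n)
    stop("need at least one option with matching costs and QALYs")
  if (is.null(ids)) ids <- as.character(seq_len(n))
  status <- rep("frontier", n)

  # absolute dominance (ties collapse to the first id in sort order)
  ord <- order(mean_qalys, -mean_costs, ids)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i == j) next
      better <- mean_costs[j] <= mean_costs[i] && mean_qalys[j] >= mean_qalys[i]
      strict <- mean_costs[j] < mean_costs[i] || mean_qalys[j] > mean_qalys[i]
      tie_first <- !strict && which(ord == j) < which(ord == i)
      if (better && (strict || tie_first)) { status[i] <- "dominated"; break }
    }
  }

  # extended dominance: enforce strictly increasing ICERs along the frontier
  repeat {
    idx <- which(status == "frontier")
    idx <- idx[order(mean_qalys[idx], mean_costs[idx], ids[idx])]
    if (length(idx) < 3) break
    icers <- diff(mean_costs[idx]) / diff(mean_qalys[idx])
    drop <- which(utils::head(icers, -1) >= utils::tail(icers, -1))
    if (!length(drop)) break
    status[idx[drop[1] + 1]] <- "extendedly dominated"
  }

  icer <- rep(NA_real_, n)
  idx <- which(status == "frontier")
  idx <- idx[order(mean_qalys[idx], mean_costs[idx], ids[idx])]
  if (length(idx) > 1)
    icer[idx[-1]] <- diff(mean_costs[idx]) / diff(mean_qalys[idx])

  data.frame(id = ids, cost = mean_costs, qaly = mean_qalys,
             status = status, icer = icer, row.names = NULL)
}

#' Rank interventions by mean net monetary benefit
#'
#' @param mean_costs,mean_qalys per-option means.
#' @param threshold willingness to pay per QALY in GBP.
#' @param ids option identifiers; ties in NMB break by id order.
#' @return Integer ranks (1 = highest NMB), in input order.
#' @export
rank_interventions <- function(mean_costs, mean_qalys, threshold = 20000,
                               ids = NULL) {
  if (is.null(ids)) ids <- as.character(seq_along(mean_costs))
  nmb <- net_monetary_benefit(mean_costs, mean_qalys, threshold)
  ord <- order(-nmb, ids)
  rank <- integer(length(nmb))
  rank[ord] <- seq_along(nmb)
  rank
}

#' Summarise a probabilistic sensitivity analysis
#'
#' Per-intervention means of cost, QALYs and fraction well at the horizon,
#' mean NMB at the stated threshold, NMB ranking, and the incremental
#' analysis (dominance status and frontier ICERs) computed on the means.
#'
#' @param psa a `sad_psa` object (or any list with `cost`, `qaly`, `well`
#'   matrices and `ids`).
#' @param threshold willingness to pay per QALY in GBP.
#' @param labels optional named vector of display labels.
#' @return `data.frame` of class `sad_cea` with columns `id`, `label`,
#'   `well`, `qaly`, `cost`, `status`, `icer`, `nmb`, `rank`.
#' @export
cea_summary <- function(psa, threshold = 20000, labels = NULL) {
  mean_cost <- colMeans(psa$cost)
  mean_qaly <- colMeans(psa$qaly)
  mean_well <- colMeans(psa$well)
  ids <- psa$ids
  front <- incremental_frontier(mean_cost, mean_qaly, ids)
  nmb <- net_monetary_benefit(mean_cost, mean_qaly, threshold)
  rank <- rank_interventions(mean_cost, mean_qaly, threshold, ids)
  out <- data.frame(id = ids,
                    label = if (is.null(labels)) ids else unname(labels[ids]),
                    well = unname(mean_well), qaly = unname(mean_qaly),
                    cost = unname(mean_cost), status = front$status,
                    icer = front$icer, nmb = unname(nmb), rank = rank,
                    row.names = NULL)
  attr(out, "threshold") <- threshold
  class(out) <- c("sad_cea", class(out))
  out
}

#' @export
print.sad_cea <- function(x, digits = 2, ...) {
  t <- attr(x, "threshold")
  cat("Cost-effectiveness summary",
      if (!is.null(t)) paste0(" (NMB at £", format(t, big.mark = ","), "/QALY)"),
      "\n", sep = "")
  y <- x[order(x$rank), ]
  y$well <- round(100 * y$well, digits)
  y$qaly <- round(y$qaly, digits)
  y$cost <- round(y$cost)
  y$nmb <- round(y$nmb)
  y$icer <- round(y$icer)
  print.data.frame(y, row.names = FALSE)
  invisible(x)
}

#' Cost-effectiveness acceptability frontier
#'
#' For each willingness-to-pay threshold: the option with the highest mean
#' NMB, and the probability that this option is the most cost-effective,
#' measured as the fraction of iterations in which it attains the maximum
#' NMB (iterations with tied maxima contribute equally split weight).
#'
#' @param psa a `sad_psa` object.
#' @param thresholds grid of willingness-to-pay values in GBP/QALY.
#' @return `data.frame` with columns `threshold`, `best` (intervention id)
#'   and `prob`.
#' @export
ceaf <- function(psa, thresholds = seq(0, 50000, by = 250)) {
  if (!length(thresholds)) stop("threshold grid must be nonempty")
  if (nrow(psa$cost) < 1) stop("PSA result is empty")
  out <- data.frame(threshold = thresholds, best = NA_character_,
                    prob = NA_real_)
  for (i in seq_along(thresholds)) {
    nmb <- thresholds[i] * psa$qaly - psa$cost
    mean_nmb <- colMeans(nmb)
    best <- which.max(mean_nmb)   # ties: first id in column order
    row_max <- do.call(pmax, as.data.frame(nmb))
    is_max <- nmb == row_max
    out$best[i] <- psa$ids[best]
    out$prob[i] <- mean(is_max[, best] / rowSums(is_max))
  }
  out
}

#' Cost-effectiveness plane versus a reference intervention
#'
#' Incremental mean costs and QALYs of every intervention against a
#' reference (wait list by default), optionally scaled to a cohort size.
#'
#' @param summary a [cea_summary()] result.
#' @param reference id of the reference intervention.
#' @param cohort_size multiplier applied to both increments.
#' @return `data.frame` with columns `id`, `delta_qaly`, `delta_cost`,
#'   `status`.
#' @export
ce_plane <- function(summary, reference = "wait_list", cohort_size = 1) {
  if (!reference %in% summary$id)
    stop("reference intervention not found: ", reference)
  ref <- summary[summary$id == reference, ]
  data.frame(id = summary$id,
             delta_qaly = (summary$qaly - ref$qaly) * cohort_size,
             delta_cost = (summary$cost - ref$cost) * cohort_size,
             status = summary$status)
}
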