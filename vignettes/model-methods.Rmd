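---
title: "Methods: the social anxiety disorder cost-utility model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the social anxiety disorder cost-utility model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sadcea)
```

## The decision problem

Twenty-eight first-line treatment options for adults with social anxiety
disorder — eleven active drugs, pill placebo, four self-help variants, four
group-based and seven individually delivered psychological therapies, and
wait list — are compared on discounted costs and quality-adjusted life
years (QALYs) from a health-service and personal-social-services
perspective, at 2015 prices. The central tension is between intervention
cost (from £0 for wait list to £2,359 for individually delivered cognitive
therapy) and two benefit drivers: the probability of recovering by the end
of treatment, and the much lower first-year relapse risk after
psychological than after pharmacological treatment.

## Model structure

The model is a hybrid of a decision tree and a two-state Markov cohort
model.

**Decision-tree year.** Initial treatment lasts 12 weeks for every arm.
At its end, a fraction $p_k$ of the cohort on intervention $k$ recovers
("no social anxiety disorder"); the rest remain ill and stop treatment
(no switching). Recoverers on drugs or placebo receive a further 26 weeks
of maintenance treatment; its cost accrues to recoverers only. During the
first post-treatment year recoverers may relapse (probability by relapse
class, below); no re-recovery occurs within that year. The decision tree
therefore spans the 12 treatment weeks plus one full post-treatment year.

**Markov years.** The remaining horizon is run in yearly cycles (4 by
default, i.e. 5 years post-treatment overall). Each cycle, ill members
recover with annual probability 0.0377 and recovered members relapse with
annual probability 0.0409, both derived from 12-year naturalistic
follow-up data by the constant-hazard conversion $1-(1-p)^{1/12}$ — chosen
because it exactly reproduces both published annual values from the
published 12-year beta counts (65/111 and 26/40). A half-cycle correction
credits QALYs and state costs at the average of start- and end-of-cycle
occupancy. The fraction well at the horizon is read after the final
transition, before any averaging.

A note on the timeline: the model span is 12 weeks of treatment plus 5
post-treatment years (1 in the tree, 4 in the Markov model), so maximum
attainable QALYs are $u_{rec}\times(12/52+5)$. This reproduces the
published per-arm totals (e.g. wait list: 3.37 QALYs, £4,593) to the
printed precision at point estimates, which a 40-week first
post-treatment year would not.

## Parameters

| Parameter | Point value | PSA distribution |
|---|---|---|
| Recovery $p_k$, end of treatment | published means | calibrated joint posterior (below) |
| Relapse year 1, drugs & placebo | 0.4169 | midpoint of Beta(107, 293), Beta(222, 170) |
| Relapse risk ratio drugs:psych | 3.00 | log-normal, 95% CI 0.73–12.39 |
| Relapse year 1, psychological | 0.139 | drug draw ÷ RR draw, clipped to [0, 1] |
| Relapse year 1, wait list | 0.0409 | fixed (see below) |
| Annual recovery, years 2–5 | 0.0377 | Beta(65, 111) on the 12-year scale, annualised per draw |
| Annual relapse, years 2–5 | 0.0409 | Beta(26, 40), annualised per draw |
| Utility, recovered / ill | 0.866 / 0.659 | Beta(4572, 707) / Beta(40, 20) |
| Annual state cost, recovered / ill | £645 / £1,037 | gamma by method of moments (SE £93 / £209) |
| GP visits, initial / maintenance | 4 / 3 | categorical (see parameter file) |
| Discount rate | 3.5%/year | fixed |
| Willingness to pay | £20,000/QALY | reporting threshold |

Three reporting quirks are handled deliberately:

* The ill-state utility is reported as mean 0.659 with Beta(40, 20)
  (mean 2/3). Point analyses use 0.659; the PSA samples the reported
  beta, as reported.
* The log-normal relapse risk ratio is sampled with log-scale mean at the
  midpoint of the log CI ($\sqrt{0.73\times 12.39}=3.01$, reproducing the
  stated central value within rounding) and log-sd equal to the log CI
  width over $2\,z_{0.975}$ — the standard convention for a CI symmetric
  on the log scale.
* The wait-list first-year relapse probability is not published. It
  defaults to the annualised years-2–5 relapse value (0.0409), the same
  source and hazard assumption, and is exposed as the
  `relapse_waitlist_y1` parameter.

Probability mass quoted for a set of categorical values ("10%: 3, 5 or 6"
GP visits) is split equally within the set; no other allocation is stated.

## The synthetic recovery posterior

The published evidence synthesis provides only marginal summaries (mean,
median, 95% credible interval) of each intervention's recovery
probability, plus a normal baseline for the wait-list log-odds,
N(−2.629, 1.235). The package reconstructs a joint posterior with the
generative model

$$\mathrm{logit}(p_k) = b + d_k,\qquad b \sim N(-2.629,\,1.235),\qquad
d_k \sim N(\mu_k, \sigma_k^2),$$

with one shared baseline draw $b$ per iteration and independent effects
$d_k$. Calibration maps the published median through the monotone logit,
$\mu_k = \mathrm{logit}(\mathrm{median}_k) + 2.629$, and recovers
$\sigma_k^2$ by subtracting the baseline variance from the squared
logit-scale CrI width over $2\,z_{0.975}$, floored at zero where the
published interval is narrower than the baseline alone implies (this
affects one active row, internet self-help with support, and wait list by
construction). Wait list is pinned at the null effect, making its column
exactly the inverse-logit of the baseline.

What this emulates and what it does not:

* All 28 published means are reproduced within ±0.01 (the means are left
  free; only medians and CrIs are calibrated), medians within ±0.01 and
  CrI bounds within ±0.03, except the mindfulness upper bound: its
  published interval is asymmetric on the logit scale beyond what a
  median-anchored logistic-normal can express, leaving an analytic gap of
  0.032.
* Correlation between interventions arises only through the shared
  baseline. The true posterior of the evidence synthesis also correlates
  the effects themselves, which the published marginals cannot identify.
  Rankings by mean NMB are essentially unaffected (means are matched),
  but probabilities on the acceptability frontier are flatter than with a
  more strongly correlated posterior: the package reproduces the
  published best-option sequence and switch points, while its probability
  of cost-effectiveness at £20,000/QALY (0.55) sits below the published
  0.68. An externally estimated draw matrix can replace the synthetic one
  (`read_posterior()`), which removes this limitation.
* The SMD bridge $\mathrm{LOR} = -(\pi/\sqrt3)\,\mathrm{SMD}$ is exposed
  (`smd_to_recovery_lor()`) for users supplying effects on the
  standardised-mean-difference scale; the default pipeline calibrates
  directly from published probabilities and does not need it.

## Costing

Drug intervention costs combine GP visits (£46.75 each) with 12-week and
26-week acquisition costs, under the published contingencies: 1–2 initial
visits preclude maintenance; a single initial visit halves the 12-week
acquisition cost; zero maintenance visits remove the 26-week acquisition
cost. Maintenance applies only to recoverers. Psychological costs combine
per-person therapist hours (sessions × length × therapists ÷
participants) with the Band 7 unit cost of £110/h, a GP referral visit,
and consumables for self-help (book £20.66; internet hosting £14,000/30
per person plus £13 hardware and overheads). Group-therapy cost is
attendance-invariant (absent participants are not replaced); individual
therapies cost by sessions attended; self-help therapist time is normal
with SD 0.3 × mean, truncated at zero. Costs are carried at full precision
and rounded only for display; published totals that differ by £1–3 embed
upstream rounding (e.g. the £327.27 GP component cell versus the
footnote's 7 × £46.75 = £327.25), so validation compares recomputed
component sums within that rounding.

## Year-1 conventions and numerical choices

Where the published description leaves the within-year timing open, the
package takes the least-informative choice and states it:

* Recoverers' utility ramps linearly from 0.659 to 0.866 across the 12
  treatment weeks; non-recoverers stay flat.
* First-year relapsers are credited the average of the two state
  utilities, and of the two state costs, over the post-treatment year —
  equivalent to a uniformly distributed relapse time.
* State costs begin at the end of treatment (intervention costs cover the
  treatment window), accruing over the post-treatment year.
* Year 1 is undiscounted; Markov cycle $k$ is discounted by
  $(1.035)^{-k}$.
* Occupancy is conserved to 1e−12 by construction; ties in the frontier
  sweep break deterministically (equal QALYs: lower cost wins; full ties
  collapse onto the first id alphabetically).

## Probabilistic analysis and decision metrics

The PSA (default 10,000 iterations) draws, per iteration, one row of the
recovery posterior and one value of every other distribution; all 28 arms
are evaluated on the same draw (common random numbers), which minimises
the Monte Carlo variance of incremental comparisons and makes any arm's
results invariant to which comparators run alongside. One master seed
controls everything; runs are byte-reproducible.

Decision outputs: mean costs, QALYs and fraction well per arm; net
monetary benefit $\lambda Q - C$; the efficiency frontier by absolute
dominance followed by an increasing-ICER sweep for extended dominance
(verified in the test suite against an exhaustive dominance oracle on
random instances); and the cost-effectiveness acceptability frontier over
a £0–£50,000 grid in £250 steps (covering the region where the published
frontier probability crosses 80%), with per-iteration NMB ties split
equally.

## Scenario analyses

`sad_scenarios()` packages the deterministic sensitivity analyses:
therapist banding (self-help at Band 5, £87/h; groups by one Band 7 and
one Band 6 therapist, £101.50 per therapist-hour), alternative utilities
(0.79 ill / 0.91 recovered), post-treatment horizons of 1, 3 and 10 years
(0, 2 and 9 Markov cycles), and fixed relapse risk ratios 1.0–2.0
(replacing the log-normal with a point mass). Scenarios run either
probabilistically under the shared seed or deterministically at point
estimates; both modes are pure functions of a copied model setup, so the
packaged defaults are never mutated.

## Problem sizes used in the checks

The test suite samples 100,000 draws for posterior-calibration checks and
distribution-mean checks, and runs PSAs of 100–2,000 iterations for
engine, reproducibility and stability properties; the packaged default of
10,000 iterations across all 28 arms completes in a few seconds. These
sizes give Monte Carlo standard errors well inside every asserted
tolerance.

## Known limitations

* The synthetic posterior matches published marginals but understates
  cross-effect correlation (see above); CEAF probabilities are
  conservative.
* Drug side effects, treatment switching, productivity losses and
  individual-level heterogeneity (microsimulation) are outside the model,
  as in the source analysis.
* Utilities come from general-population survey states rather than
  trial-based social-anxiety-specific valuations; the alternative-utility
  scenario bounds the impact.
* The first-year relapse risk is class-level (one value for all drugs,
  one for all psychological therapies), reflecting the sparse relapse
  evidence.
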