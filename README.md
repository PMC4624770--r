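# sadcea

Cost-utility modelling of 28 interventions for adults with social anxiety
disorder, from a health-service and personal-social-services perspective.

Social anxiety disorder is a common, persistent anxiety disorder. Effective
treatments range from cheap book-based self-help to individually delivered
cognitive behavioural therapy (CBT) costing over £2,000 per course, with
drugs in between — but drugs carry a much higher risk of relapse after
recovery. `sadcea` is for health economists and methodologists who want a
tested, fully reproducible implementation of the decision model that weighs
these trade-offs: 11 drugs, pill placebo, four self-help variants, four
group therapies, seven individually delivered therapies and wait list.

## The model

Each cohort enters a **decision tree**: 12 weeks of initial treatment, after
which a fraction *p<sub>k</sub>* (intervention *k*'s probability of
recovery) moves to the "no social anxiety disorder" state. Recoverers on
drugs receive 26 weeks of maintenance treatment; during the first
post-treatment year recoverers relapse with probability 0.4169 (drugs and
placebo), 0.4169/RR with RR = 3.0 (psychological interventions, ≈ 14%), or
0.0409 (wait list). Survivors of year 1 enter a **two-state Markov model**
run in yearly cycles (default 4, i.e. a 5-year post-treatment horizon) with
annual recovery 0.0377 and relapse 0.0409, half-cycle correction, and 3.5%
annual discounting. Utilities are 0.866 (recovered) and 0.659 (ill) with
linear transitions; annual state costs are £645 and £1,037.

Evidence on recovery enters as a joint posterior across all 28
interventions. The package reconstructs it with a **calibrated
logistic-normal sampler**: per draw, logit(*p<sub>k</sub>*) = *b* +
*d<sub>k</sub>*, with a shared wait-list baseline *b* ~ N(−2.629, 1.235)
and per-intervention effects *d<sub>k</sub>* ~ N(μ<sub>k</sub>,
σ<sub>k</sub>²) calibrated so each marginal reproduces its published
median and 95% credible interval. Probabilistic sensitivity analysis
(default 10,000 iterations, common random numbers across arms) propagates
every input distribution; outputs are mean costs, QALYs, net monetary
benefit (NMB = λ·QALYs − cost), the efficiency frontier with extended
dominance and ICERs, and the cost-effectiveness acceptability frontier
(CEAF).

## Worked example

```r
library(sadcea)

model <- sad_model()                       # packaged parameters + cost tables
psa   <- run_psa(model, n_iter = 10000, seed = 1)
cea   <- cea_summary(psa, threshold = 20000,
                     labels = setNames(model$interventions$label,
                                       model$interventions$id))
print(head(cea[order(cea$rank),
               c("label", "well", "qaly", "cost", "status", "icer", "nmb", "rank")], 4))
```

```
Cost-effectiveness summary
         label  well qaly cost               status icer   nmb rank
     ICBT, C&W 49.89 3.77 6185             frontier 9744 69168    1
 ICBT, general 41.02 3.66 5718 extendedly dominated   NA 67489    2
    Phenelzine 34.68 3.60 4567             frontier 2087 67465    3
    SHNS, book 33.43 3.57 4499             frontier   NA 66876    4
```

(`well` is printed as a percentage.) Reading this: individually delivered
cognitive therapy (Clark & Wells model)
leaves 49.9% of the cohort free of social anxiety disorder five years after
treatment, yields 3.77 discounted QALYs at a mean discounted cost of £6,185,
and has the highest net monetary benefit at £20,000/QALY despite the highest
intervention cost. The efficiency frontier runs book-based self-help →
phenelzine → ICBT (C&W); generic individual CBT is extendedly dominated (a
mix of phenelzine and ICBT C&W beats it). The acceptability frontier

```r
curve <- ceaf(psa)
unique(curve$best)
#> [1] "shns_book"  "phenelzine" "icbt_cw"
```

switches from book-based self-help to phenelzine at ~£2,000/QALY and to
ICBT (C&W) at ~£9,500/QALY. Scenario analyses
(`run_scenario_suite(model, sad_scenarios())`) cover therapist banding,
alternative utilities (0.79/0.91), 1/3/10-year horizons and relapse risk
ratios 1.0–2.0; at a 1-year horizon phenelzine leads and ICBT (C&W) drops
to 17th, and with an equal relapse risk phenelzine leads with ICBT (C&W)
second.

`sad_validate()` recomputes every derived parameter and cost component from
its primitives and reports pass/fail. `sad_run("out/")` writes the summary
table, frontier, CEAF curve, cost-effectiveness plane and a JSON run
manifest.

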