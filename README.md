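# hccmarkov

A Markov cohort decision model comparing **liver resection (LR)** with
**transarterial chemoembolization (TACE)** for intermediate-stage
hepatocellular carcinoma (HCC) in compensated cirrhotic patients.

Intermediate-stage (BCLC B) HCC is conventionally treated with TACE, but a
growing observational literature suggests that resection, where feasible,
yields better overall survival. Randomized head-to-head evidence is scarce,
so the question is well suited to a decision-analytic state-transition
model: each strategy is represented as a set of health states with annual
transition probabilities pooled from the literature, and the model simulates
the full disease course over a 15-year horizon. The package is aimed at
health-economics and clinical-epidemiology researchers who want a fully
scriptable, testable version of this analysis — every stage, from parameter
pooling to probabilistic sensitivity analysis, is an ordinary R function
operating on data frames.

## The model

Fifteen health states across two arms (7 for LR, 8 for TACE), with death the
absorbing state of each arm. Cycle length is 1 year; the horizon is 15
cycles; life expectancy uses the half-cycle (trapezoid) correction

    LE = ½S(0) + Σ_{k=1..14} S(k) + ½S(15),

where S(k) is the alive proportion at cycle boundary k. The entry cycle
resolves the initial treatment: perioperative death (p = 0.033) and
incomplete resection (p = 0.114, routed to progressive disease) for LR; the
initial response draw (CR/PR/SD/PD = 0.156/0.494/0.202/0.148) for TACE.
Disease-free patients face annual recurrence (p = 0.245) and the summed
background mortality of the general population and cirrhosis
(0.055 + 0.027 = 0.082); progressive disease carries its own annual
mortality (0.746).

Literature inputs are converted and pooled by the parameter layer:

* **DEALE conversions** — a median survival t gives an annual event
  probability 1 − 0.5^(1/t); a surviving fraction s at horizon t gives
  rate μ = −ln(s)/t and probability 1 − e^(−μ).
* **Freeman–Tukey double-arcsine pooling** — per-study proportions are
  transformed by y = ½[asin√(x/(n+1)) + asin√((x+1)/(n+1))],
  var = 1/(4n+2), pooled with DerSimonian–Laird random effects, and
  back-transformed with the harmonic-mean-n inversion.
* **Wilson score intervals** for binomial proportions.

Around the deterministic base case the package provides one-way/two-way
sensitivity analyses and tornado diagrams over the published 95% CIs, a
second-order Monte Carlo probabilistic sensitivity analysis (per-patient
Beta-distributed parameter draws plus individual trajectory simulation), and
a synthetic patient-level validation cohort with propensity-score matching,
Kaplan–Meier comparison and multivariable Cox analysis.

## Worked example

```r
library(hccmarkov)

bc <- run_base_case()        # built-in literature-derived parameters
glance(bc)
#> # A tibble: 2 × 6
#>   arm   life_expectancy_years life_expectancy_months survival_1y survival_3y survival_5y
#> 1 LR                     6.48                   77.8       0.888       0.609       0.473
#> 2 TACE                   3.98                   47.8       0.835       0.469       0.265
```

Expected overall survival is 77.8 months after resection versus 47.8 months
after chemoembolization — resection roughly doubles the modelled life
expectancy at this stage — with 5-year survival 47.3% versus 26.5%.
`autoplot(bc)` draws both survival curves.

```r
torn <- tornado(hcc_parameters(), "TACE")
head(tibble::as_tibble(torn), 3)
#> # A tibble: 3 × 4
#>   parameter os_low os_high swing
#> 1 p_tace_cr   3.27    5.23 1.96
#> 2 p_tace_pd   4.69    2.94 1.75
#> 3 p_tace_pr   3.62    4.53 0.902
```

TACE survival is most sensitive to the complete-response rate (expected OS
moves from 3.3 to 5.2 years across its CI), then the progressive-disease
rate. One-way and two-way analyses over all parameter CIs never produce a
crossing: resection retains the survival advantage even at the best case
for TACE (`one_way()`, `two_way()`, attribute `crossing`).

```r
psa <- run_psa(hcc_parameters(), n_patients = 10000, seed = 1)
psa
#> PSA (combined mode, seed 1)
#>   LR   mean OS 6.550 yr (95% CI 6.444-6.658)
#>   TACE mean OS 4.059 yr (95% CI 3.985-4.137)
#>   diff 2.491 yr (95% CI 2.366-2.614), p = 4.35e-306
```

The between-arm difference of about 2.5 years of life expectancy is robust
to parameter uncertainty: its 95% CI excludes zero by a wide margin.

The synthetic validation layer generates a patient-level cohort (701 LR /
1034 TACE) calibrated to the published baseline table and pre-matching
survival rates, then runs the published validation pipeline end to end:

```r
coh <- generate_cohort(701, 1034, seed = 1)
m   <- fit_propensity_and_match(coh)
compare_survival(m)      # KM rates, medians, log-rank p
multivariable_hazards(coh)
```

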