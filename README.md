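# msdaf

Predicting clinical disease activity after a treatment switch in
relapsing-remitting multiple sclerosis (RRMS).

When an RRMS patient keeps relapsing on a first-line ("platform")
injectable therapy and is switched to higher-dose subcutaneous interferon
beta-1a, the clinical question is *who will break through anyway*. `msdaf`
implements the full analysis chain used to answer it from longitudinal
Kurtzke functional-system (KFS) records:

1. **Endpoint derivation.** A *qualifying relapse* is a sudden
   neurological worsening lasting > 24 h, preceded by ≥ 30 days of
   stability, without fever/infection, causing a 2-grade increase in one
   KFS or 1-grade increases in two or more (bowel/bladder and
   cerebral/mental changes excluded). *Sustained disability progression*
   is an EDSS increase ≥ 1.0 from baseline confirmed 3 months later.
   *Clinical disease activity-free* (cDAF) status survives until the
   first of the two:
   `T_cDAF = min(T_relapse, T_progression)`, censored at the last
   assessment.
2. **Predictor coding.** The *index relapse* (last relapse before the
   switch) is *monosymptomatic* if exactly one of the relapse-defining
   systems (pyramidal, cerebellar, brainstem, sensory, visual) is
   affected, *polysymptomatic* if two or more; plus dominant symptom,
   most affected baseline KFS, pre-baseline relapse count, EDSS, age and
   prior therapy.
3. **Survival analysis.** Kaplan-Meier landmark probabilities at months
   6/12/18/24, log-rank tests, and Cox proportional-hazards models
   (Efron ties, Wald CIs, score test), via the `survival` package.
4. **Dual-gated survival CART** — the core estimator, `dgcart()`. At each
   node, every candidate variable is searched over binary cut-points
   (thresholds between observed values, decile grid for continuous
   variables, one-vs-rest for categorical ones); the split with the
   smallest Cox score-test p-value is accepted only if *both* the score
   test and the log-rank test on the resulting children reach p < α
   (default 0.05) and both children keep ≥ 5 subjects. Branches end when
   no split passes.
5. **Synthetic cohort generator.** Because individual-level study data
   are not public, a seeded generator emulates the study population:
   two phenotype groups with the published baseline marginals,
   piecewise-exponential relapse/progression processes calibrated to the
   published Kaplan-Meier profiles, a 0/6/12/18/24-month visit schedule
   with ± 4-week jitter, confirmation visits, and 22.3% early
   termination.

## Worked example

```r
library(msdaf)

coh <- simulate_cohort(cohort_config(n_subjects = 300, seed = 42))
d   <- analysis_frame(coh, "cDAF")          # time, event, covariates

round(node_summary(d$time, d$event), 3)     # KM landmark probabilities
#>  month6 month12 month18 month24
#>   0.846   0.678   0.570   0.532

cox_fit(d, "poly")
#> Cox proportional-hazards fit (efron ties): n = 300, events = 130
#>       coef    HR lower95 upper95 wald_p
#> poly 0.803 2.231    1.57   3.171      0
#> Score test: chisq = 21.13 on 1 df, p = 4.299e-06

fit <- dgcart(survival::Surv(time, event) ~ poly + relapse_count_2y +
                sex + dominant_symptom + baseline_edss +
                most_affected_kfs + prior_dmt + age_at_baseline +
                age_at_first_symptom, data = d)
fit
#> Dual-gated survival tree: n = 300, events = 130, alpha = 0.05, min node = 5
#> <root> n=300 events=130  month24=53.2%
#>   split: poly > 0.5 (score p=4.3e-06, log-rank p=4.3e-06)
#>   [not poly > 0.5] n=161 events=52  month24=64.9%
#>   ...
```

About half the cohort stays free of clinical disease activity over two
years; a polysymptomatic index relapse roughly doubles the hazard of
renewed activity (HR ≈ 2) and is the first split of the tree, with
month-24 cDAF ≈ 65% in the monosymptomatic branch versus ≈ 40% in the
polysymptomatic branch.

The whole pipeline (tables, KM curves, fits, both tree variants, run
manifest) is available as one call, or from a shell:

```r
run_pipeline("out/", seed = 1)
```

```sh
Rscript inst/scripts/msdaf.R all --output out --seed 1
```

## Package layout

- `R/kfs.R`, `R/endpoints.R` — KFS profiles, relapse rules, endpoint
  derivation
- `R/cohort.R`, `R/experiments.R`, `R/io.R` — synthetic cohort
  generator, simulation-study configurations, CSV interfaces
- `R/survtools.R`, `R/baseline.R` — survival and baseline statistics
- `R/dgcart.R` — the dual-gated survival tree and its S3 methods
- `R/pipeline.R` — end-to-end pipeline, table validation, manifest
- `vignettes/disease-activity-trees.Rmd` — models, assumptions and
  design choices
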