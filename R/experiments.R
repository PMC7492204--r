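#' Cohort configuration for controlled simulation studies
#'
#' Builds a [cohort_config()] for null and planted-effect experiments:
#' every covariate marginal is shared between the phenotype groups (ages
#' and EDSS at their whole-population values, the pooled relapse-count
#' distribution, 75% female in both groups), so that the only
#' covariate-hazard associations present are the ones planted through
#' `log_hr`. Baseline hazards are constant over follow-up at
#' study-typical intensities (a ~44% two-year event fraction at the null
#' default) and early termination keeps its 22.3% target.
#'
#' With `log_hr = c()` this is a global null: no covariate affects the
#' hazard. With e.g. `log_hr = c(poly = log(2), count2plus_mono =
#' log(1.8))` it plants a two-level structure (a root phenotype effect
#' and, nested within the monosymptomatic group, a relapse-count
#' threshold effect at 2 or more relapses) whose recovery by [dgcart()]
#' can be scored against the generating truth. The covariate names
#' understood by the event process are `poly`, `mono`, `sex_male`,
#' `age_at_baseline`, `age_at_first_symptom`, `baseline_edss`,
#' `relapse_count_2y`, `count2plus` and `count2plus_mono`.
#'
#' @param n_subjects Cohort size.
#' @param seed Root seed.
#' @param log_hr Named log hazard-ratios of the planted effects.
#' @param relapse_hazard,progression_hazard Constant baseline intensities
#'   (events/month).
#' @param dropout_rate_target Early-termination fraction by month 24.
#' @return A [cohort_config()].
#' @export
simulation_study_config <- function(n_subjects, seed, log_hr = numeric(0),
                                    relapse_hazard = 0.02,
                                    progression_hazard = 0.004,
                                    dropout_rate_target = 0.223) {
  shared_counts <- c(`1` = 145, `2` = 93, `3` = 50, `4` = 12) / 300
  shared_edss <- default_edss_dist()$poly
  hz <- hazard_spec(
    relapse_hazard = rep(relapse_hazard, 4),
    progression_hazard = rep(progression_hazard, 4),
    log_hr = log_hr,
    dropout_hazard = -log(1 - dropout_rate_target) / 24)
  cohort_config(
    n_subjects = n_subjects, seed = seed, hazard = hz,
    prop_female = c(mono = 0.75, poly = 0.75),
    age_baseline = list(mono = c(mean = 38.1, sd = 10.1),
                        poly = c(mean = 38.1, sd = 10.1)),
    age_onset = list(mono = c(mean = 30.3, sd = 9.7),
                     poly = c(mean = 30.3, sd = 9.7)),
    edss_dist = list(mono = shared_edss, poly = shared_edss),
    relapse_count_dist = list(mono = shared_counts, poly = shared_counts),
    dropout_rate_target = dropout_rate_target)
}

#' Endpoint-plus-covariate analysis frame for one cohort
#'
#' Convenience join of [derive_endpoints()] and [cohort_covariates()] for
#' one endpoint: the per-subject `(time, event, covariates)` frame the
#' survival and tree stages consume.
#'
#' @param cohort An `msdaf_cohort`.
#' @param endpoint `"cDAF"`, `"relapse_free"` or `"progression_free"`.
#' @param horizon Months.
#' @return Data frame with one row per subject.
#' @export
analysis_frame <- function(cohort, endpoint = "cDAF", horizon = 24) {
  merge(derive_endpoints(cohort, endpoint, horizon = horizon),
        cohort_covariates(cohort), by = "subject_id")
}
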