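# Endpoint derivation: qualifying relapses, sustained EDSS progression and
# the combined clinical disease activity-free (cDAF) time-to-event outcome.

# Protocol visit window: +/- 4 weeks, expressed in months.
weeks_to_months <- function(w) w * 12 / 52

#' Construct a patient record
#'
#' One subject's baseline covariates, pre-baseline relapse history and
#' post-baseline visit/relapse stream. Visits are held as a data frame with
#' one row per assessment: `month` (0 = baseline, strictly increasing),
#' `edss`, and one column per functional system of [kfs_systems()].
#'
#' Eligibility invariants are enforced: a baseline visit at month 0, at
#' least one relapse in the 2 pre-baseline years, and baseline EDSS on the
#' half-point grid with a maximum of 6.5.
#'
#' @param subject_id Identifier.
#' @param sex `"female"` or `"male"`.
#' @param age_at_baseline,age_at_first_symptom Years.
#' @param baseline_edss EDSS at baseline (0--6.5 in 0.5 steps).
#' @param baseline_kfs A [kfs_profile()].
#' @param prior_dmt One of `"scIFNb1a22"`, `"imIFNb1a"`, `"glatiramer"`,
#'   `"scIFNb1b"`.
#' @param dmt_duration Years on the prior therapy.
#' @param prebaseline_relapse_count_2y Relapses in the 2 years before
#'   baseline (at least 1).
#' @param index_relapse The last pre-baseline relapse, a [relapse_event()].
#' @param visits Data frame of assessments (see above).
#' @param postbaseline_relapses List of [relapse_event()]s with positive
#'   onset months.
#' @param termination_month Month of early termination, or `NA` if the
#'   subject completed follow-up.
#' @return List of class `patient_record`.
#' @export
patient_record <- function(subject_id, sex, age_at_baseline,
                           age_at_first_symptom, baseline_edss, baseline_kfs,
                           prior_dmt, dmt_duration,
                           prebaseline_relapse_count_2y, index_relapse,
                           visits, postbaseline_relapses = list(),
                           termination_month = NA_real_) {
  stopifnot(inherits(baseline_kfs, "kfs_profile"),
            inherits(index_relapse, "relapse_event"),
            is.data.frame(visits))
  need <- c("month", "edss", kfs_systems())
  miss <- setdiff(need, names(visits))
  if (length(miss)) stop("visits table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(visits) < 1 || visits$month[1] != 0)
    stop("baseline visit at month 0 is required")
  if (is.unsorted(visits$month, strictly = TRUE))
    stop("visit months must be strictly increasing")
  if (prebaseline_relapse_count_2y < 1)
    stop("eligibility requires at least one pre-baseline relapse")
  if (!edss_on_grid(baseline_edss) || baseline_edss > 6.5)
    stop("baseline EDSS must lie on the half-point grid 0-6.5")
  structure(
    list(subject_id = subject_id, sex = sex,
         age_at_baseline = age_at_baseline,
         age_at_first_symptom = age_at_first_symptom,
         disease_duration = age_at_baseline - age_at_first_symptom,
         baseline_edss = baseline_edss, baseline_kfs = baseline_kfs,
         prior_dmt = prior_dmt, dmt_duration = dmt_duration,
         prebaseline_relapse_count_2y = as.integer(prebaseline_relapse_count_2y),
         index_relapse = index_relapse, visits = visits,
         postbaseline_relapses = postbaseline_relapses,
         termination_month = as.numeric(termination_month)),
    class = "patient_record")
}

edss_on_grid <- function(x) {
  is.finite(x) & x >= 0 & abs(x * 2 - round(x * 2)) < 1e-9
}

#' Time of sustained EDSS progression
#'
#' Scans a subject's post-baseline assessments for the earliest visit at
#' which EDSS exceeds the baseline score by at least 1.0 point and a
#' confirmation assessment about 3 months later (within the +/- 4 week
#' protocol window) again shows an increase of at least 1.0. An increase
#' without a qualifying confirmation assessment is not progression.
#'
#' @param rec A [patient_record()].
#' @param confirm_window_weeks Half-width of the window around month
#'   `m + 3` in which a confirmation assessment is accepted (default 4).
#' @return The month of the progression visit, or `NA` if no sustained
#'   progression occurred.
#' @export
derive_progression_time <- function(rec, confirm_window_weeks = 4) {
  stopifnot(inherits(rec, "patient_record"))
  v <- rec$visits
  base <- v$edss[v$month == 0][1]
  w <- weeks_to_months(confirm_window_weeks)
  cand <- which(v$month > 0 & (v$edss - base) >= 1.0)
  for (i in cand) {
    m <- v$month[i]
    conf <- which(v$month > m & abs(v$month - (m + 3)) <= w + 1e-9)
    if (length(conf) && any((v$edss[conf] - base) >= 1.0))
      return(m)
  }
  NA_real_
}

#' Derive a time-to-event endpoint for one subject
#'
#' Builds the subject's outcome for one of the three study endpoints:
#' \describe{
#'   \item{`relapse_free`}{time of the first post-baseline qualifying
#'     relapse (at its onset date);}
#'   \item{`progression_free`}{time of sustained EDSS progression
#'     ([derive_progression_time()], detected at scheduled visits);}
#'   \item{`cDAF`}{the minimum of the two -- clinical disease activity-free
#'     status ends at the first relapse or progression.}
#' }
#' Subjects without an event inside the horizon are censored at the
#' earliest of early termination, last assessment, and the horizon.
#'
#' @param rec A [patient_record()].
#' @param kind `"cDAF"`, `"relapse_free"` or `"progression_free"`.
#' @param horizon Months of follow-up considered (default 24).
#' @return List of class `endpoint_outcome` with fields `endpoint_kind`,
#'   `time` (months), `event` (logical) and `censoring_reason`
#'   (`"end_of_observation"`, `"early_termination"`, or `NA` for events).
#' @export
derive_endpoint <- function(rec, kind = c("cDAF", "relapse_free",
                                          "progression_free"),
                            horizon = 24) {
  kind <- match.arg(kind)
  stopifnot(inherits(rec, "patient_record"), horizon > 0)
  if (!any(rec$visits$month > 0))
    stop("malformed record: no post-baseline visits for subject ",
         rec$subject_id)

  relapse_time <- NA_real_
  qual <- vapply(rec$postbaseline_relapses, function(r)
    r$onset_month > 0 && is_qualifying_relapse(r), logical(1))
  if (any(qual))
    relapse_time <- min(vapply(rec$postbaseline_relapses[qual],
                               `[[`, numeric(1), "onset_month"))
  prog_time <- derive_progression_time(rec)

  ev_time <- switch(kind,
    relapse_free = relapse_time,
    progression_free = prog_time,
    cDAF = suppressWarnings(min(relapse_time, prog_time, na.rm = TRUE)))
  if (!is.finite(ev_time)) ev_time <- NA_real_

  if (!is.na(ev_time) && ev_time <= horizon) {
    out <- list(endpoint_kind = kind, time = ev_time, event = TRUE,
                censoring_reason = NA_character_)
  } else {
    last_visit <- max(rec$visits$month)
    cens <- min(rec$termination_month, last_visit, horizon, na.rm = TRUE)
    reason <- if (!is.na(rec$termination_month) &&
                  rec$termination_month <= min(last_visit, horizon))
      "early_termination" else "end_of_observation"
    out <- list(endpoint_kind = kind, time = cens, event = FALSE,
                censoring_reason = reason)
  }
  if (out$time <= 0)
    stop("malformed record: non-positive follow-up for subject ",
         rec$subject_id)
  structure(out, class = "endpoint_outcome")
}

#' Derive endpoints for a whole cohort
#'
#' @param cohort List of [patient_record()]s (e.g. from
#'   [simulate_cohort()]).
#' @param kinds Endpoint kinds to derive.
#' @param horizon Months of follow-up (default 24).
#' @return Data frame with columns `subject_id`, `endpoint`, `time`,
#'   `event` (0/1) and `censoring_reason`.
#' @export
derive_endpoints <- function(cohort,
                             kinds = c("cDAF", "relapse_free",
                                       "progression_free"),
                             horizon = 24) {
  rows <- lapply(cohort, function(rec) {
    do.call(rbind, lapply(kinds, function(k) {
      o <- derive_endpoint(rec, k, horizon)
      data.frame(subject_id = rec$subject_id, endpoint = k,
                 time = o$time, event = as.integer(o$event),
                 censoring_reason = ifelse(is.na(o$censoring_reason), "",
                                           o$censoring_reason),
                 stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Baseline covariate table for a cohort
#'
#' Flattens patient records into the one-row-per-subject analysis frame
#' used by the survival and tree stages: demographics, prior therapy,
#' pre-baseline relapse count, index-relapse phenotype (`"mono"`/`"poly"`
#' plus the 0/1 indicator `poly`), dominant symptom of the index relapse
#' and the most affected baseline functional system.
#'
#' @param cohort List of [patient_record()]s.
#' @return Data frame, one row per subject.
#' @export
cohort_covariates <- function(cohort) {
  out <- do.call(rbind, lapply(cohort, function(rec) {
    phen <- classify_index_relapse(rec$index_relapse)
    data.frame(
      subject_id = rec$subject_id,
      sex = rec$sex,
      age_at_baseline = rec$age_at_baseline,
      age_at_first_symptom = rec$age_at_first_symptom,
      disease_duration = rec$disease_duration,
      baseline_edss = rec$baseline_edss,
      prior_dmt = rec$prior_dmt,
      dmt_duration = rec$dmt_duration,
      relapse_count_2y = rec$prebaseline_relapse_count_2y,
      index_phenotype = phen,
      poly = as.integer(phen == "poly"),
      dominant_symptom = dominant_symptom(rec$index_relapse),
      most_affected_kfs = most_affected_kfs(rec$baseline_kfs),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
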