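# Delimited-text interfaces: a cohort is exchanged as three CSV tables
# (patients, visits, relapses) so each pipeline stage can run standalone.

#' Write a cohort to three CSV tables
#'
#' Writes `patients.csv` (one row per subject: baseline covariates and the
#' baseline KFS profile), `visits.csv` (subject, month, EDSS, eight KFS
#' scores) and `relapses.csv` (subject, onset month -- negative for the
#' pre-baseline index relapse -- per-system grade increases and the three
#' qualifying-rule flags). All tables are comma-separated UTF-8 with a
#' header row.
#'
#' @param cohort An `msdaf_cohort` / list of [patient_record()]s.
#' @param dir Output directory (created if missing).
#' @return Invisibly, the paths of the three files.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  pat <- do.call(rbind, lapply(cohort, function(r) {
    k <- as.list(as.integer(r$baseline_kfs))
    names(k) <- paste0("kfs_", kfs_systems())
    cbind(data.frame(subject_id = r$subject_id, sex = r$sex,
                     age_at_baseline = r$age_at_baseline,
                     age_at_first_symptom = r$age_at_first_symptom,
                     baseline_edss = r$baseline_edss,
                     prior_dmt = r$prior_dmt, dmt_duration = r$dmt_duration,
                     relapse_count_2y = r$prebaseline_relapse_count_2y,
                     termination_month = r$termination_month,
                     stringsAsFactors = FALSE),
          as.data.frame(k))
  }))
  vis <- do.call(rbind, lapply(cohort, function(r)
    cbind(data.frame(subject_id = r$subject_id), r$visits)))
  rel_rows <- lapply(cohort, function(r) {
    evs <- c(list(r$index_relapse), r$postbaseline_relapses)
    do.call(rbind, lapply(evs, function(e) {
      d <- as.list(as.integer(e$system_deltas))
      names(d) <- paste0("delta_", kfs_systems())
      cbind(data.frame(subject_id = r$subject_id,
                       onset_month = e$onset_month,
                       stringsAsFactors = FALSE),
            as.data.frame(d),
            data.frame(duration_gt_24h = as.integer(e$duration_gt_24h),
                       fever_or_infection = as.integer(e$fever_or_infection),
                       preceded_by_30d_stability =
                         as.integer(e$preceded_by_30d_stability)))
    }))
  })
  rel <- do.call(rbind, rel_rows)
  paths <- file.path(dir, c("patients.csv", "visits.csv", "relapses.csv"))
  utils::write.csv(pat, paths[1], row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(vis, paths[2], row.names = FALSE, fileEncoding = "UTF-8")
  utils::write.csv(rel, paths[3], row.names = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}

#' Read a cohort back from its three CSV tables
#'
#' Inverse of [write_cohort()]. The index relapse of each subject is the
#' latest pre-baseline row (negative onset month) of `relapses.csv`.
#'
#' @param dir Directory containing `patients.csv`, `visits.csv`,
#'   `relapses.csv`.
#' @return An `msdaf_cohort`.
#' @export
read_cohort <- function(dir) {
  pat <- utils::read.csv(file.path(dir, "patients.csv"),
                         stringsAsFactors = FALSE)
  vis <- utils::read.csv(file.path(dir, "visits.csv"),
                         stringsAsFactors = FALSE)
  rel <- utils::read.csv(file.path(dir, "relapses.csv"),
                         stringsAsFactors = FALSE)
  records <- lapply(seq_len(nrow(pat)), function(i) {
    p <- pat[i, ]
    kf <- as.list(stats::setNames(
      as.integer(unlist(p[paste0("kfs_", kfs_systems())])), kfs_systems()))
    v <- vis[vis$subject_id == p$subject_id, c("month", "edss",
                                               kfs_systems())]
    v <- v[order(v$month), , drop = FALSE]
    rownames(v) <- NULL
    rr <- rel[rel$subject_id == p$subject_id, , drop = FALSE]
    mk_ev <- function(row) {
      relapse_event(row$onset_month,
                    deltas = stats::setNames(
                      as.integer(unlist(row[paste0("delta_", kfs_systems())])),
                      kfs_systems()),
                    duration_gt_24h = row$duration_gt_24h == 1,
                    fever_or_infection = row$fever_or_infection == 1,
                    preceded_by_30d_stability =
                      row$preceded_by_30d_stability == 1)
    }
    pre <- rr[rr$onset_month < 0, , drop = FALSE]
    if (!nrow(pre)) stop("subject ", p$subject_id, " has no index relapse")
    idx <- mk_ev(pre[which.max(pre$onset_month), ])
    post_rows <- rr[rr$onset_month > 0, , drop = FALSE]
    post <- lapply(seq_len(nrow(post_rows)),
                   function(j) mk_ev(post_rows[j, ]))
    patient_record(
      subject_id = p$subject_id, sex = p$sex,
      age_at_baseline = p$age_at_baseline,
      age_at_first_symptom = p$age_at_first_symptom,
      baseline_edss = p$baseline_edss,
      baseline_kfs = do.call(kfs_profile, kf),
      prior_dmt = p$prior_dmt, dmt_duration = p$dmt_duration,
      prebaseline_relapse_count_2y = p$relapse_count_2y,
      index_relapse = idx, visits = v, postbaseline_relapses = post,
      termination_month = p$termination_month)
  })
  structure(records, class = "msdaf_cohort")
}

#' Read / write a flat key-value configuration file
#'
#' A minimal `key = value` text format for the scalar generator settings
#' (`n_subjects`, `prop_poly`, `dropout_rate_target`, `visit_window_weeks`,
#' `horizon`, `seed`). Unknown keys raise an error; omitted keys keep
#' their defaults (which encode the published baseline marginals).
#'
#' @param path File path.
#' @return For `read_cohort_config`, a [cohort_config()].
#' @export
read_cohort_config <- function(path) {
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  args <- list()
  allowed <- c("n_subjects", "prop_poly", "dropout_rate_target",
               "visit_window_weeks", "horizon", "seed")
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2) stop("malformed config line: ", ln)
    key <- trimws(kv[1]); val <- trimws(kv[2])
    if (!key %in% allowed)
      stop("unknown configuration key: ", key)
    args[[key]] <- as.numeric(val)
  }
  do.call(cohort_config, args)
}

#' @rdname read_cohort_config
#' @param config A [cohort_config()].
#' @export
write_cohort_config <- function(config, path) {
  keys <- c("n_subjects", "prop_poly", "dropout_rate_target",
            "visit_window_weeks", "horizon", "seed")
  writeLines(sprintf("%s = %s", keys,
                     vapply(config[keys], format, character(1))),
             path)
  invisible(path)
}
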