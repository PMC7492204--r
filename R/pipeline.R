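# End-to-end pipeline: simulate or ingest a cohort, validate the tables,
# derive endpoints, run baseline statistics and univariate survival
# analyses, fit the dual-gated trees, and write all outputs with a run
# manifest.

#' Validate cohort CSV tables
#'
#' Checks the schema and study invariants of a cohort exchanged as CSV
#' tables: required columns, EDSS on the half-point grid with baseline at
#' most 6.5, KFS grades in range, strictly increasing visit months with a
#' baseline visit, at least one pre-baseline relapse per subject, and
#' non-negative relapse grade increases. Violations are reported, not
#' raised.
#'
#' @param dir Directory with `patients.csv`, `visits.csv`, `relapses.csv`.
#' @return Data frame with columns `table`, `row`, `subject_id`, `rule`
#'   (zero rows when the tables are clean).
#' @export
validate_tables <- function(dir) {
  out <- list()
  note <- function(table, row, subject, rule)
    out[[length(out) + 1]] <<- data.frame(
      table = table, row = row, subject_id = subject, rule = rule,
      stringsAsFactors = FALSE)
  paths <- file.path(dir, c("patients.csv", "visits.csv", "relapses.csv"))
  names(paths) <- c("patients", "visits", "relapses")
  tabs <- list()
  for (nm in names(paths)) {
    if (!file.exists(paths[[nm]])) {
      note(nm, NA, NA, "missing table")
      next
    }
    tabs[[nm]] <- utils::read.csv(paths[[nm]], stringsAsFactors = FALSE)
  }
  empty <- data.frame(table = character(0), row = integer(0),
                      subject_id = character(0), rule = character(0))
  if (length(out)) return(do.call(rbind, out))

  pat <- tabs$patients; vis <- tabs$visits; rel <- tabs$relapses
  need_pat <- c("subject_id", "sex", "age_at_baseline",
                "age_at_first_symptom", "baseline_edss", "prior_dmt",
                "dmt_duration", "relapse_count_2y", "termination_month",
                paste0("kfs_", kfs_systems()))
  for (col in setdiff(need_pat, names(pat)))
    note("patients", NA, NA, paste("missing column", col))
  need_vis <- c("subject_id", "month", "edss", kfs_systems())
  for (col in setdiff(need_vis, names(vis)))
    note("visits", NA, NA, paste("missing column", col))
  need_rel <- c("subject_id", "onset_month",
                paste0("delta_", kfs_systems()),
                "duration_gt_24h", "fever_or_infection",
                "preceded_by_30d_stability")
  for (col in setdiff(need_rel, names(rel)))
    note("relapses", NA, NA, paste("missing column", col))
  if (length(out)) return(do.call(rbind, out))

  for (i in seq_len(nrow(pat))) {
    p <- pat[i, ]
    if (!edss_on_grid(p$baseline_edss) || p$baseline_edss > 6.5)
      note("patients", i, p$subject_id,
           "baseline EDSS must be on the half-point grid with maximum 6.5")
    if (p$relapse_count_2y < 1)
      note("patients", i, p$subject_id,
           "eligibility requires at least one pre-baseline relapse")
    k <- as.numeric(unlist(p[paste0("kfs_", kfs_systems())]))
    if (any(!(k %in% c(0:6, 9))))
      note("patients", i, p$subject_id, "KFS grade outside {0..6, 9}")
  }
  for (sid in unique(vis$subject_id)) {
    v <- vis[vis$subject_id == sid, ]
    if (!any(v$month == 0))
      note("visits", NA, sid, "baseline visit at month 0 missing")
    if (is.unsorted(v$month, strictly = TRUE) && is.unsorted(sort(v$month),
                                                             strictly = TRUE))
      note("visits", NA, sid, "duplicate visit months")
    if (any(!edss_on_grid(v$edss)))
      note("visits", NA, sid, "EDSS off the half-point grid")
  }
  for (i in seq_len(nrow(rel))) {
    d <- as.numeric(unlist(rel[i, paste0("delta_", kfs_systems())]))
    if (any(d < 0))
      note("relapses", i, rel$subject_id[i],
           "negative system grade increase")
  }
  pre <- table(rel$subject_id[rel$onset_month < 0])
  for (sid in setdiff(pat$subject_id, names(pre)))
    note("relapses", NA, sid, "no pre-baseline index relapse")
  if (length(out)) do.call(rbind, out) else empty
}

km_curves_frame <- function(endpoints, covariates) {
  rows <- list()
  for (ep in unique(endpoints$endpoint)) {
    e <- endpoints[endpoints$endpoint == ep, ]
    e <- merge(e, covariates[, c("subject_id", "index_phenotype")],
               by = "subject_id")
    for (grp in c("all", "mono", "poly")) {
      sel <- if (grp == "all") rep(TRUE, nrow(e)) else e$index_phenotype == grp
      if (!any(sel)) next
      cv <- km_estimate(e$time[sel], e$event[sel])
      rows[[length(rows) + 1]] <- data.frame(
        endpoint = ep, group = grp, time = cv$time, n_risk = cv$n_risk,
        n_event = cv$n_event, survival = cv$surv,
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

univariate_fits <- function(endpoints, covariates, horizon) {
  out <- list()
  for (ep in unique(endpoints$endpoint)) {
    e <- merge(endpoints[endpoints$endpoint == ep, ], covariates,
               by = "subject_id")
    if (sum(e$event) == 0) {
      out[[ep]] <- list(skipped = TRUE,
                        reason = "no events for this endpoint")
      next
    }
    fit <- cox_fit(e, "poly")
    lr <- logrank_test(e$time, e$event, e$poly)
    curve_all <- km_estimate(e$time, e$event)
    out[[ep]] <- list(
      skipped = FALSE,
      n = nrow(e), n_events = sum(e$event),
      km_landmarks = as.list(node_summary(e$time, e$event)),
      cox_mono_vs_poly = list(
        hr = unname(fit$hr["poly"]),
        ci95 = as.numeric(fit$ci95["poly", ]),
        wald_p = unname(fit$wald_p["poly"]),
        score_p = fit$score_p),
      logrank = list(chisq = unname(lr$statistic), df = unname(lr$parameter),
                     p = lr$p.value))
  }
  out
}

#' Run the full analysis pipeline
#'
#' Simulates (or reads) a cohort, validates its tables, derives the three
#' endpoints, and writes: `patients.csv`/`visits.csv`/`relapses.csv` (when
#' simulating), `endpoints.csv`, `table1.csv`, `km_curves.csv`,
#' `fits.json`, `tree_A.json`/`tree_B.json` and `manifest.json` into
#' `output_dir`.
#'
#' @param output_dir Output directory (created if needed).
#' @param input_dir Directory with an existing cohort, or `NULL` to
#'   simulate.
#' @param config A [cohort_config()] used when simulating (its seed is
#'   overridden by `seed` when that is given).
#' @param seed Optional integer overriding the config seed.
#' @param variant Tree model variant(s): `"A"`, `"B"` or `"both"`.
#' @param alpha,min_node,horizon Tree gate level, minimum child size and
#'   follow-up horizon.
#' @return Invisibly, the manifest (also written as JSON): seed, per-stage
#'   row/event counts, file digests, timestamp.
#' @export
run_pipeline <- function(output_dir, input_dir = NULL,
                         config = cohort_config(), seed = NULL,
                         variant = "both", alpha = 0.05, min_node = 5,
                         horizon = 24) {
  if (!dir.exists(output_dir)) dir.create(output_dir, recursive = TRUE)
  t0 <- Sys.time()
  if (is.null(input_dir)) {
    if (!is.null(seed)) config$seed <- as.integer(seed)
    cohort <- simulate_cohort(config)
    write_cohort(cohort, output_dir)
    cohort_dir <- output_dir
  } else {
    cohort_dir <- input_dir
    cohort <- read_cohort(input_dir)
  }
  violations <- validate_tables(cohort_dir)
  if (nrow(violations))
    warning(nrow(violations), " table validation violation(s); see manifest")

  endpoints <- derive_endpoints(cohort, horizon = horizon)
  covariates <- cohort_covariates(cohort)
  utils::write.csv(endpoints, file.path(output_dir, "endpoints.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")

  tab1 <- table1_report(covariates)
  utils::write.csv(tab1, file.path(output_dir, "table1.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")

  km <- km_curves_frame(endpoints, covariates)
  utils::write.csv(km, file.path(output_dir, "km_curves.csv"),
                   row.names = FALSE, fileEncoding = "UTF-8")

  fits <- univariate_fits(endpoints, covariates, horizon)
  jsonlite::write_json(fits, file.path(output_dir, "fits.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  cdaf <- merge(endpoints[endpoints$endpoint == "cDAF", ], covariates,
                by = "subject_id")
  variants <- if (variant == "both") c("A", "B") else variant
  tree_files <- character(0)
  for (vt in variants) {
    if (sum(cdaf$event) == 0) break
    fml <- stats::as.formula(paste(
      "survival::Surv(time, event) ~",
      paste(cdaf_candidates(vt), collapse = " + ")))
    tree <- dgcart(fml, cdaf, alpha = alpha, min_node = min_node)
    f <- file.path(output_dir, sprintf("tree_%s.json", vt))
    write_tree_json(tree, f)
    tree_files <- c(tree_files, f)
  }

  files <- c(file.path(output_dir, c("endpoints.csv", "table1.csv",
                                     "km_curves.csv", "fits.json")),
             tree_files,
             file.path(cohort_dir, c("patients.csv", "visits.csv",
                                     "relapses.csv")))
  files <- files[file.exists(files)]
  manifest <- list(
    tool = paste("msdaf", as.character(utils::packageVersion("msdaf"))),
    seed = config$seed,
    timestamp = format(t0, "%Y-%m-%dT%H:%M:%S%z"),
    n_subjects = length(cohort),
    n_endpoint_rows = nrow(endpoints),
    n_events = stats::setNames(
      lapply(split(endpoints$event, endpoints$endpoint), sum),
      names(split(endpoints$event, endpoints$endpoint))),
    n_validation_violations = nrow(violations),
    files = stats::setNames(as.list(unname(tools::md5sum(files))),
                            basename(files)))
  jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
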