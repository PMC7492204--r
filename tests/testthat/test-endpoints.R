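# Clinical endpoint rules: qualifying relapse, index-relapse phenotype,
# most affected KFS, dominant symptom, sustained progression, and the
# combined cDAF outcome.

favorable <- function(...) relapse_event(1, ...)

test_that("qualifying relapse rule follows the 2-grade / two 1-grade criterion", {
  expect_true(is_qualifying_relapse(favorable(pyramidal = 2)))
  expect_true(is_qualifying_relapse(favorable(sensory = 1, visual = 1)))
  # bowel/bladder and cerebral/mental changes are excluded from the count
  expect_false(is_qualifying_relapse(favorable(bowel_bladder = 2,
                                               cerebral_mental = 1)))
  # a single eligible 1-grade increase is not enough
  expect_false(is_qualifying_relapse(favorable(sensory = 1)))
  # "other" counts towards the rule (only bowel/bladder and cerebral/mental
  # are excluded)
  expect_true(is_qualifying_relapse(favorable(other = 2)))
})

test_that("qualifying relapse requires the duration/stability/no-fever flags", {
  expect_false(is_qualifying_relapse(
    relapse_event(1, pyramidal = 2, fever_or_infection = TRUE)))
  expect_false(is_qualifying_relapse(
    relapse_event(1, pyramidal = 2, duration_gt_24h = FALSE)))
  expect_false(is_qualifying_relapse(
    relapse_event(1, pyramidal = 2, preceded_by_30d_stability = FALSE)))
})

test_that("index relapse phenotype counts only the five relapse-defining systems", {
  expect_identical(classify_index_relapse(favorable(pyramidal = 2)), "mono")
  expect_identical(classify_index_relapse(favorable(pyramidal = 1,
                                                    cerebellar = 1)), "poly")
  # accompanying bowel/bladder or cerebral/mental worsening never flips mono
  expect_identical(classify_index_relapse(
    favorable(visual = 2, bowel_bladder = 1, cerebral_mental = 1)), "mono")
  expect_error(classify_index_relapse(favorable(bowel_bladder = 2,
                                                cerebral_mental = 1)),
               "excluded systems")
})

test_that("most affected KFS takes the argmax, pools rare systems, skips 9", {
  expect_identical(most_affected_kfs(kfs_profile(pyramidal = 3, sensory = 2)),
                   "pyramidal")
  expect_identical(most_affected_kfs(kfs_profile(brainstem = 4)), "others")
  expect_identical(most_affected_kfs(kfs_profile(bowel_bladder = 4)), "others")
  # 9 encodes unknown and is never the argmax
  expect_identical(most_affected_kfs(kfs_profile(pyramidal = 9, sensory = 2)),
                   "sensory")
  expect_error(most_affected_kfs(
    do.call(kfs_profile, as.list(setNames(rep(9, 8), kfs_systems())))),
    "unknown")
})

test_that("two-way score ties resolve by the fixed priority order, exhaustively", {
  pri <- kfs_priority()
  to_cat <- function(sys) {
    if (sys %in% c("brainstem", "bowel_bladder", "cerebral_mental", "other"))
      "others" else sys
  }
  for (i in seq_along(pri)) {
    for (j in seq_along(pri)) {
      if (i >= j) next
      args <- setNames(as.list(rep(0, 2)), c(pri[i], pri[j]))
      args[[1]] <- 3; args[[2]] <- 3
      p <- do.call(kfs_profile, args)
      expect_identical(most_affected_kfs(p), to_cat(pri[i]),
                       label = sprintf("tie %s vs %s", pri[i], pri[j]))
    }
  }
})

test_that("dominant symptom is the largest eligible delta with priority tie-break", {
  expect_identical(dominant_symptom(favorable(sensory = 2, pyramidal = 1)),
                   "sensory")
  expect_identical(dominant_symptom(favorable(visual = 2)), "visual")
  # exhaustive two-way tie enumeration over the five eligible systems
  elig <- c("pyramidal", "cerebellar", "brainstem", "sensory", "visual")
  pri <- intersect(kfs_priority(), elig)
  for (a in elig) for (b in elig) {
    if (a == b) next
    args <- setNames(list(2, 2), c(a, b))
    r <- do.call(favorable, args)
    expected <- pri[min(match(c(a, b), pri))]
    expect_identical(dominant_symptom(r), expected,
                     label = sprintf("tie %s vs %s", a, b))
  }
})

make_record <- function(visit_months, edss, termination = NA_real_,
                        relapses = list()) {
  v <- data.frame(month = visit_months, edss = edss)
  for (s in kfs_systems()) v[[s]] <- 0L
  patient_record(
    subject_id = "T1", sex = "female", age_at_baseline = 35,
    age_at_first_symptom = 28, baseline_edss = edss[1],
    baseline_kfs = kfs_profile(pyramidal = 2),
    prior_dmt = "glatiramer", dmt_duration = 2,
    prebaseline_relapse_count_2y = 1,
    index_relapse = relapse_event(-3, pyramidal = 2),
    visits = v, postbaseline_relapses = relapses,
    termination_month = termination)
}

test_that("sustained progression needs a confirmed >= 1.0 EDSS increase", {
  # confirmed at the 3-month confirmation visit
  r <- make_record(c(0, 6, 12, 15, 18, 24), c(2, 2, 3, 3, 3, 3))
  expect_equal(derive_progression_time(r), 12)
  # unconfirmed: back at baseline level three months later
  r2 <- make_record(c(0, 6, 12, 15, 18, 24), c(2, 2, 3, 2, 2, 2))
  expect_true(is.na(derive_progression_time(r2)))
  # sub-threshold increases never progress
  r3 <- make_record(c(0, 6, 12, 15, 18, 24), c(2, 2.5, 2.5, 2.5, 2.5, 2.5))
  expect_true(is.na(derive_progression_time(r3)))
  # missing confirmation assessment: no progression
  r4 <- make_record(c(0, 6, 12, 18, 24), c(2, 2, 3, 2, 2))
  expect_true(is.na(derive_progression_time(r4)))
})

test_that("deleting the confirmation visit converts progression to non-event", {
  with_conf <- make_record(c(0, 6, 12, 15, 18, 24), c(2, 2, 3, 3, 3, 3))
  expect_equal(derive_progression_time(with_conf), 12)
  v <- with_conf$visits[with_conf$visits$month != 15, ]
  without_conf <- make_record(v$month, v$edss)
  # the 18-month visit is outside the 3-month +/- 4-week confirmation window
  expect_true(is.na(derive_progression_time(without_conf)))
})

test_that("cDAF is the minimum of relapse and progression times", {
  rel8 <- list(relapse_event(8, pyramidal = 2))
  r <- make_record(c(0, 6, 12, 18, 24), c(2, 2, 2, 2, 2), relapses = rel8)
  o <- derive_endpoint(r, "cDAF")
  expect_true(o$event); expect_equal(o$time, 8)

  # progression at 6 precedes a relapse at 10
  r2 <- make_record(c(0, 6, 9, 12, 18, 24), c(2, 3, 3, 3, 3, 3),
                    relapses = list(relapse_event(10, sensory = 2)))
  o2 <- derive_endpoint(r2, "cDAF")
  expect_true(o2$event); expect_equal(o2$time, 6)
  expect_equal(derive_endpoint(r2, "relapse_free")$time, 10)
  expect_equal(derive_endpoint(r2, "progression_free")$time, 6)
})

test_that("non-qualifying relapses never end cDAF status", {
  fever <- list(relapse_event(8, pyramidal = 2, fever_or_infection = TRUE))
  r <- make_record(c(0, 6, 12, 18, 24), c(2, 2, 2, 2, 2), relapses = fever)
  o <- derive_endpoint(r, "cDAF")
  expect_false(o$event)
  expect_equal(o$time, 24)
})

test_that("censoring lands on min(termination, last visit, horizon)", {
  # early termination at month 16 with its termination assessment
  r <- make_record(c(0, 6, 12, 16), c(2, 2, 2, 2), termination = 16)
  o <- derive_endpoint(r, "cDAF")
  expect_false(o$event)
  expect_equal(o$time, 16)
  expect_identical(o$censoring_reason, "early_termination")
  # without the termination assessment, the last visit caps follow-up
  r1 <- make_record(c(0, 6, 12), c(2, 2, 2), termination = 16)
  o1 <- derive_endpoint(r1, "cDAF")
  expect_false(o1$event)
  expect_equal(o1$time, 12)

  r2 <- make_record(c(0, 6, 12, 18, 24), c(2, 2, 2, 2, 2))
  o2 <- derive_endpoint(r2, "cDAF")
  expect_false(o2$event)
  expect_equal(o2$time, 24)
  expect_identical(o2$censoring_reason, "end_of_observation")

  expect_error(derive_endpoint(make_record(0, 2), "cDAF"),
               "no post-baseline visits")
})

test_that("cohort-level properties: cDAF = min rule, monotonicity, partition", {
  coh <- simulate_cohort(cohort_config(n_subjects = 120, seed = 11))
  ep <- derive_endpoints(coh)
  wide <- reshape(ep[, c("subject_id", "endpoint", "time", "event")],
                  idvar = "subject_id", timevar = "endpoint",
                  direction = "wide")
  ev <- wide$event.cDAF == 1
  expect_true(all(abs(wide$time.cDAF[ev] -
                        pmin(wide$time.relapse_free[ev],
                             wide$time.progression_free[ev])) < 1e-9))
  expect_identical(wide$event.cDAF,
                   as.integer(wide$event.relapse_free |
                                wide$event.progression_free))

  # adding an observed qualifying relapse never increases a subject's
  # cDAF time (subjects already off study before month 5 cannot have an
  # observed relapse there, so they are skipped)
  for (rec in coh[1:25]) {
    before <- derive_endpoint(rec, "cDAF")
    if (before$time <= 5) next
    rec$postbaseline_relapses <- c(rec$postbaseline_relapses,
                                   list(relapse_event(5, pyramidal = 2)))
    after <- derive_endpoint(rec, "cDAF")
    expect_lte(after$time, before$time)
  }

  # phenotype partition: mono + poly counts sum to n
  cv <- cohort_covariates(coh)
  expect_equal(sum(cv$index_phenotype == "mono") +
                 sum(cv$index_phenotype == "poly"), length(coh))
})
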