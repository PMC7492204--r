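#' Kurtzke functional system names
#'
#' The eight Kurtzke functional systems (KFS) underlying the EDSS, in the
#' fixed order used throughout the package. `kfs_priority()` returns the
#' deterministic tie-break order used when two systems are equally affected:
#' pyramidal > cerebellar > brainstem > sensory > visual, with the
#' non-relapse-defining systems (bowel/bladder, cerebral/mental, other)
#' ranked last. The tie-break replaces the investigator arbitration a
#' clinical study would use, so that derived categories are reproducible.
#'
#' @return Character vector of system names.
#' @export
kfs_systems <- function() {
  c("pyramidal", "cerebellar", "brainstem", "sensory",
    "bowel_bladder", "visual", "cerebral_mental", "other")
}

#' @rdname kfs_systems
#' @export
kfs_priority <- function() {
  c("pyramidal", "cerebellar", "brainstem", "sensory", "visual",
    "bowel_bladder", "cerebral_mental", "other")
}

# Systems that define relapse phenotype and dominant symptom.
kfs_eligible_phenotype <- function() {
  c("pyramidal", "cerebellar", "brainstem", "sensory", "visual")
}

# Systems whose score changes count towards a qualifying relapse
# (bowel/bladder and cerebral/mental changes are excluded).
kfs_eligible_qualifying <- function() {
  setdiff(kfs_systems(), c("bowel_bladder", "cerebral_mental"))
}

#' Construct a KFS score profile
#'
#' One assessment of the eight functional systems. Scores are integer grades;
#' `9` encodes "unknown". Grades are validated against the range 0--6
#' (system-specific maxima are not enforced beyond this).
#'
#' @param pyramidal,cerebellar,brainstem,sensory,bowel_bladder,visual,cerebral_mental,other
#'   Integer grades in `{0..6, 9}`.
#' @return Named integer vector of class `kfs_profile`.
#' @examples
#' kfs_profile(pyramidal = 3, sensory = 1)
#' @export
kfs_profile <- function(pyramidal = 0, cerebellar = 0, brainstem = 0,
                        sensory = 0, bowel_bladder = 0, visual = 0,
                        cerebral_mental = 0, other = 0) {
  p <- c(pyramidal = pyramidal, cerebellar = cerebellar,
         brainstem = brainstem, sensory = sensory,
         bowel_bladder = bowel_bladder, visual = visual,
         cerebral_mental = cerebral_mental, other = other)
  if (any(is.na(p)) || any(p != round(p)) || any(!(p %in% c(0:6, 9))))
    stop("KFS scores must be integer grades in {0..6} or 9 (unknown)")
  structure(as.integer(p), names = kfs_systems(), class = "kfs_profile")
}

#' @export
print.kfs_profile <- function(x, ...) {
  cat("KFS profile:\n")
  print(stats::setNames(as.integer(x), names(x)))
  invisible(x)
}

#' Construct a relapse event
#'
#' A relapse is recorded with its onset time relative to baseline (negative
#' for pre-baseline relapses, e.g. the index relapse), the per-system KFS
#' grade increases it caused, and the three flags that enter the qualifying
#' rule: symptom duration beyond 24 hours, concurrent fever or infection,
#' and at least 30 days of preceding clinical stability.
#'
#' @param onset_month Months from baseline; may be negative.
#' @param ... Named per-system grade increases (e.g. `pyramidal = 2`);
#'   unnamed systems default to 0. Alternatively pass `deltas` as a full
#'   named vector.
#' @param deltas Optional named numeric vector of grade increases over the
#'   systems of [kfs_systems()].
#' @param duration_gt_24h Logical; symptoms lasted more than 24 hours.
#' @param fever_or_infection Logical; a concurrent fever or infection offers
#'   an alternative explanation and disqualifies the relapse.
#' @param preceded_by_30d_stability Logical; at least 30 days of stability or
#'   improvement preceded onset.
#' @return List of class `relapse_event`.
#' @examples
#' relapse_event(-2, pyramidal = 2)
#' @export
relapse_event <- function(onset_month, ..., deltas = NULL,
                          duration_gt_24h = TRUE,
                          fever_or_infection = FALSE,
                          preceded_by_30d_stability = TRUE) {
  d <- stats::setNames(rep(0L, 8L), kfs_systems())
  dots <- c(list(...), if (!is.null(deltas)) as.list(deltas))
  if (length(dots)) {
    bad <- setdiff(names(dots), kfs_systems())
    if (length(bad)) stop("unknown KFS system(s): ", paste(bad, collapse = ", "))
    d[names(dots)] <- as.integer(unlist(dots))
  }
  if (any(d < 0)) stop("system grade increases must be >= 0")
  structure(
    list(onset_month = as.numeric(onset_month),
         system_deltas = d,
         duration_gt_24h = isTRUE(duration_gt_24h),
         fever_or_infection = isTRUE(fever_or_infection),
         preceded_by_30d_stability = isTRUE(preceded_by_30d_stability)),
    class = "relapse_event")
}

#' Does a relapse qualify as a clinical disease activity event?
#'
#' A qualifying relapse must last longer than 24 hours, be preceded by at
#' least 30 days of clinical stability, lack a concurrent fever/infection,
#' and cause either a 2-grade increase in at least one functional system or
#' a 1-grade increase in at least two systems -- where changes in
#' bowel/bladder and cerebral/mental function are excluded from the count.
#'
#' @param r A [relapse_event()].
#' @return Logical scalar.
#' @export
is_qualifying_relapse <- function(r) {
  stopifnot(inherits(r, "relapse_event"))
  if (!r$duration_gt_24h || !r$preceded_by_30d_stability || r$fever_or_infection)
    return(FALSE)
  d <- r$system_deltas[kfs_eligible_qualifying()]
  max(d) >= 2 || sum(d >= 1) >= 2
}

#' Classify an index relapse as monosymptomatic or polysymptomatic
#'
#' Counts the relapse-defining systems (pyramidal, cerebellar, brainstem,
#' sensory, visual) with any grade increase. Exactly one affected system is
#' monosymptomatic; two or more is polysymptomatic. Accompanying
#' bowel/bladder or cerebral/mental worsening never changes the phenotype.
#'
#' @param r A [relapse_event()] (assumed to be a qualifying relapse).
#' @return `"mono"` or `"poly"`.
#' @export
classify_index_relapse <- function(r) {
  stopifnot(inherits(r, "relapse_event"))
  n <- sum(r$system_deltas[kfs_eligible_phenotype()] >= 1)
  if (n == 0)
    stop("relapse affects only excluded systems; phenotype undefined")
  if (n == 1) "mono" else "poly"
}

#' Most affected baseline functional system
#'
#' Returns the category of the highest-scoring system in a baseline KFS
#' profile, ignoring scores of 9 (unknown). Ties are broken by the fixed
#' priority order of [kfs_priority()]. Because brainstem, bowel/bladder,
#' cerebral/mental and "other" occur rarely as the leading system, they are
#' pooled into a single `"others"` category for analysis.
#'
#' @param p A [kfs_profile()].
#' @return One of `"pyramidal"`, `"sensory"`, `"cerebellar"`, `"visual"`,
#'   `"others"`.
#' @export
most_affected_kfs <- function(p) {
  stopifnot(inherits(p, "kfs_profile"))
  s <- stats::setNames(as.integer(p), names(p))
  s <- s[s != 9L]
  if (!length(s)) stop("all KFS scores unknown (9); most affected undefined")
  pri <- intersect(kfs_priority(), names(s))
  s <- s[pri]
  winner <- pri[which.max(s)]  # which.max takes the first max, i.e. priority order
  if (winner %in% c("brainstem", "bowel_bladder", "cerebral_mental", "other"))
    "others"
  else
    winner
}

#' Dominant symptom of a relapse
#'
#' The relapse-defining system with the largest grade increase; ties are
#' broken by the fixed priority order of [kfs_priority()].
#'
#' @param r A [relapse_event()] affecting at least one relapse-defining
#'   system.
#' @return One of `"pyramidal"`, `"sensory"`, `"visual"`, `"brainstem"`,
#'   `"cerebellar"`.
#' @export
dominant_symptom <- function(r) {
  stopifnot(inherits(r, "relapse_event"))
  d <- r$system_deltas[kfs_eligible_phenotype()]
  if (all(d == 0))
    stop("relapse affects only excluded systems; dominant symptom undefined")
  pri <- intersect(kfs_priority(), kfs_eligible_phenotype())
  d <- d[pri]
  pri[which.max(d)]
}
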