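# Group-comparison statistics for the baseline characteristics table:
# pooled two-sample t (also from printed summary statistics), Pearson
# chi-square, Wilcoxon rank-sum and Mood's median test.

#' Pooled two-sample t-test from summary statistics
#'
#' Two-sided two-sample t-test computed from group means, SDs and sizes,
#' so published "mean +/- SD (n)" rows can be re-tested without raw data.
#' The pooled-variance form (df = n1 + n2 - 2) is the default; Welch's
#' unequal-variance form is available.
#'
#' @param mean1,sd1,n1 Summary statistics of group 1.
#' @param mean2,sd2,n2 Summary statistics of group 2.
#' @param welch Use the Welch-Satterthwaite form instead of pooling.
#' @return An object of class `htest`.
#' @examples
#' ttest_from_summary(36.4, 10.0, 160, 40.0, 10.0, 140)
#' @export
ttest_from_summary <- function(mean1, sd1, n1, mean2, sd2, n2,
                               welch = FALSE) {
  stopifnot(sd1 >= 0, sd2 >= 0, n1 >= 2, n2 >= 2)
  if (welch) {
    se2 <- sd1^2 / n1 + sd2^2 / n2
    df <- se2^2 / ((sd1^2 / n1)^2 / (n1 - 1) + (sd2^2 / n2)^2 / (n2 - 1))
    se <- sqrt(se2)
  } else {
    df <- n1 + n2 - 2
    if (df < 1) stop("insufficient degrees of freedom")
    sp2 <- ((n1 - 1) * sd1^2 + (n2 - 1) * sd2^2) / df
    se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  }
  if (se == 0) {
    if (mean1 == mean2) {
      tstat <- 0; p <- 1
    } else stop("zero variance with unequal means")
  } else {
    tstat <- (mean1 - mean2) / se
    p <- 2 * stats::pt(-abs(tstat), df)
  }
  structure(list(
    statistic = c(t = tstat), parameter = c(df = df), p.value = p,
    estimate = c(`mean difference` = mean1 - mean2),
    method = if (welch) "Welch two-sample t-test (from summary statistics)"
             else "Pooled two-sample t-test (from summary statistics)",
    data.name = sprintf("group summaries (n = %d, %d)", n1, n2)),
    class = "htest")
}

#' Pearson chi-square test on a contingency table
#'
#' Pearson's chi-square without continuity correction, df = (r-1)(c-1).
#' The likelihood-ratio (G^2) variant is available; published tables do
#' not always say which was used and the two can round to different
#' p-values.
#'
#' @param counts Matrix of non-negative counts.
#' @param method `"pearson"` (default) or `"lr"`.
#' @return An object of class `htest`.
#' @examples
#' pearson_chi2(matrix(c(123, 101, 37, 39), nrow = 2))
#' @export
pearson_chi2 <- function(counts, method = c("pearson", "lr")) {
  method <- match.arg(method)
  counts <- as.matrix(counts)
  if (any(counts < 0) || sum(counts) <= 0)
    stop("counts must be non-negative with positive total")
  if (any(rowSums(counts) == 0) || any(colSums(counts) == 0))
    stop("zero row or column marginal")
  if (method == "pearson") {
    ht <- suppressWarnings(stats::chisq.test(counts, correct = FALSE))
    ht$method <- "Pearson chi-square test (no continuity correction)"
    return(ht)
  }
  exp <- outer(rowSums(counts), colSums(counts)) / sum(counts)
  obs <- counts
  g2 <- 2 * sum(ifelse(obs > 0, obs * log(obs / exp), 0))
  df <- (nrow(counts) - 1) * (ncol(counts) - 1)
  structure(list(
    statistic = c(`G-squared` = g2), parameter = c(df = df),
    p.value = stats::pchisq(g2, df, lower.tail = FALSE),
    method = "Likelihood-ratio chi-square test",
    data.name = "counts"), class = "htest")
}

#' Wilcoxon rank-sum test
#'
#' Two-sided rank-sum test with midranks for ties. By default the normal
#' approximation with tie-corrected variance (no continuity correction) is
#' used, matching large-sample practice; for small samples
#' (`min(n) < exact_below`, default 15) without ties the exact distribution
#' is used.
#'
#' @param x,y Numeric samples.
#' @param exact `NULL` (choose by sample size), `TRUE` or `FALSE`.
#' @param exact_below Size threshold for the automatic exact mode.
#' @return An object of class `htest`.
#' @export
wilcoxon_ranksum <- function(x, y, exact = NULL, exact_below = 15) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0
  if (is.null(exact)) exact <- min(length(x), length(y)) < exact_below && !ties
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, exact = exact, correct = FALSE))
  ht
}

#' Mood's median test
#'
#' Dichotomises the pooled sample at its median and tests the resulting
#' group-by-side 2x2 table with Pearson's chi-square (no continuity
#' correction). Values at or below the pooled median count as "low".
#'
#' @param x,y Numeric samples.
#' @return An object of class `htest`.
#' @export
mood_median_test <- function(x, y) {
  if (!length(x) || !length(y)) stop("both samples must be non-empty")
  med <- stats::median(c(x, y))
  tab <- rbind(c(sum(x > med), sum(x <= med)),
               c(sum(y > med), sum(y <= med)))
  if (sum(tab[, 1]) == 0 || sum(tab[, 2]) == 0)
    stop("degenerate pooled median: no values on one side")
  ht <- pearson_chi2(tab)
  ht$method <- "Mood's median test (chi-square, no continuity correction)"
  ht
}

#' Baseline characteristics report with group comparisons
#'
#' Builds a Table-1-shaped report from a cohort covariate frame: group
#' summaries (mono- vs polysymptomatic index relapse) and a p-value per
#' row, with the method conventional for each variable type -- pooled t
#' for ages, Wilcoxon rank-sum for skewed continuous variables (disease
#' duration, therapy duration), median test for EDSS and relapse counts,
#' and Pearson chi-square for categorical variables.
#'
#' @param covariates Data frame from [cohort_covariates()].
#' @return Data frame with columns `variable`, `total`, `mono`, `poly`,
#'   `p_value`, `method`.
#' @export
table1_report <- function(covariates) {
  cv <- covariates
  g <- cv$index_phenotype
  mono <- cv[g == "mono", ]; poly <- cv[g == "poly", ]
  msd <- function(x) sprintf("%.1f ± %.1f", mean(x), stats::sd(x))
  mrng <- function(x) sprintf("%.1f (%.1f-%.1f)", stats::median(x),
                              min(x), max(x))
  npct <- function(x, lev) sprintf("%d (%.1f%%)", sum(x == lev),
                                   100 * mean(x == lev))
  rows <- list()
  add <- function(variable, total, m, p, pval, method)
    rows[[length(rows) + 1]] <<- data.frame(
      variable = variable, total = total, mono = m, poly = p,
      p_value = pval, method = method, stringsAsFactors = FALSE)

  t_age <- ttest_from_summary(mean(mono$age_at_baseline),
                              stats::sd(mono$age_at_baseline), nrow(mono),
                              mean(poly$age_at_baseline),
                              stats::sd(poly$age_at_baseline), nrow(poly))
  add("Age at baseline, yrs (mean ± SD)", msd(cv$age_at_baseline),
      msd(mono$age_at_baseline), msd(poly$age_at_baseline),
      t_age$p.value, "t-test")

  sex_tab <- table(g, cv$sex)
  add("Female, n (%)", npct(cv$sex, "female"), npct(mono$sex, "female"),
      npct(poly$sex, "female"), pearson_chi2(sex_tab)$p.value, "chi-square")

  t_onset <- ttest_from_summary(mean(mono$age_at_first_symptom),
                                stats::sd(mono$age_at_first_symptom),
                                nrow(mono),
                                mean(poly$age_at_first_symptom),
                                stats::sd(poly$age_at_first_symptom),
                                nrow(poly))
  add("Age at first MS symptom, yrs (mean ± SD)",
      msd(cv$age_at_first_symptom), msd(mono$age_at_first_symptom),
      msd(poly$age_at_first_symptom), t_onset$p.value, "t-test")

  add("Disease duration, yrs, median (range)", mrng(cv$disease_duration),
      mrng(mono$disease_duration), mrng(poly$disease_duration),
      wilcoxon_ranksum(mono$disease_duration, poly$disease_duration)$p.value,
      "Wilcoxon")

  add("EDSS, median (range)", mrng(cv$baseline_edss),
      mrng(mono$baseline_edss), mrng(poly$baseline_edss),
      mood_median_test(mono$baseline_edss, poly$baseline_edss)$p.value,
      "median test")

  add("Relapses 2 yrs prior, median (range)", mrng(cv$relapse_count_2y),
      mrng(mono$relapse_count_2y), mrng(poly$relapse_count_2y),
      mood_median_test(mono$relapse_count_2y, poly$relapse_count_2y)$p.value,
      "median test")

  for (spec in list(c("dominant_symptom", "Dominant symptom of index relapse"),
                    c("most_affected_kfs", "Most disabled KFS"),
                    c("prior_dmt", "DMT prior to baseline"))) {
    v <- spec[1]; lab <- spec[2]
    tab <- table(g, cv[[v]])
    pv <- tryCatch(pearson_chi2(tab)$p.value, error = function(e) NA_real_)
    add(paste0(lab, ", n (%)"), "", "", "", pv, "chi-square")
    for (lev in colnames(tab))
      add(paste0("  ", lev), npct(cv[[v]], lev), npct(mono[[v]], lev),
          npct(poly[[v]], lev), NA_real_, "")
  }

  add("Duration of DMT, yrs, median (range)", mrng(cv$dmt_duration),
      mrng(mono$dmt_duration), mrng(poly$dmt_duration),
      wilcoxon_ranksum(mono$dmt_duration, poly$dmt_duration)$p.value,
      "Wilcoxon")

  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
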