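# Kaplan-Meier / log-rank / Cox utilities behind the analysis pipeline.
# All fitting is delegated to the survival package; these wrappers fix the
# conventions used throughout (right-continuous step functions, Efron ties
# by default, score test reported alongside Wald inference).

#' Kaplan-Meier product-limit estimate
#'
#' @param time Positive event/censoring times in months.
#' @param event Event indicator (1/TRUE = event, 0/FALSE = censored).
#'   Censored and event times tied at the same value are handled
#'   events-first, as in the product-limit estimator.
#' @return Object of class `km_curve`: a data frame with columns `time`,
#'   `n_risk`, `n_event`, `n_censor` and `surv` (one row per distinct
#'   observed time), with `n` as an attribute.
#' @examples
#' km_estimate(c(2, 4, 6), c(1, 0, 1))
#' @export
km_estimate <- function(time, event) {
  stopifnot(length(time) >= 1, length(time) == length(event))
  if (any(!is.finite(time)) || any(time <= 0))
    stop("times must be finite and positive")
  fit <- survival::survfit(survival::Surv(time, as.integer(event)) ~ 1,
                           conf.type = "none")
  out <- data.frame(time = fit$time, n_risk = fit$n.risk,
                    n_event = fit$n.event, n_censor = fit$n.censor,
                    surv = fit$surv)
  attr(out, "n") <- length(time)
  class(out) <- c("km_curve", "data.frame")
  out
}

#' Survival probability at a landmark time
#'
#' Reads the Kaplan-Meier step function at `t`, right-continuously: at an
#' event time the post-jump value is returned, and times before the first
#' observed time give 1. Landmark cDAF/relapse-free percentages are
#' computed this way.
#'
#' @param curve A `km_curve` from [km_estimate()].
#' @param t Months (vectorised), `t >= 0`.
#' @return Survival probabilities.
#' @export
km_prob_at <- function(curve, t) {
  stopifnot(inherits(curve, "km_curve"), all(t >= 0))
  vapply(t, function(ti) {
    i <- which(curve$time <= ti + 1e-12)
    if (!length(i)) 1.0 else curve$surv[max(i)]
  }, numeric(1))
}

#' Log-rank test across groups
#'
#' Standard (unweighted) log-rank chi-square comparing the survival
#' distributions of two or more groups, with `groups - 1` degrees of
#' freedom.
#'
#' @param time,event Follow-up times and event indicators.
#' @param group Group labels (>= 2 non-empty groups, >= 1 event overall).
#' @return An object of class `htest` with `statistic`, `parameter` (df)
#'   and `p.value`.
#' @export
logrank_test <- function(time, event, group) {
  stopifnot(length(time) == length(event), length(time) == length(group))
  group <- as.factor(as.character(group))
  if (nlevels(group) < 2) stop("need at least two groups")
  if (sum(event) < 1) stop("log-rank test requires at least one event")
  sd <- survival::survdiff(survival::Surv(time, as.integer(event)) ~ group)
  df <- length(sd$n) - 1
  structure(list(
    statistic = c(chisq = unname(sd$chisq)),
    parameter = c(df = df),
    p.value = stats::pchisq(sd$chisq, df, lower.tail = FALSE),
    method = "Log-rank test",
    data.name = deparse(substitute(time))), class = "htest")
}

#' Cox proportional-hazards fit with score-test inference
#'
#' Fits a Cox model by partial-likelihood maximisation (Newton iterations,
#' Efron tie correction by default; Breslow available for the classical
#' score-test/log-rank identity). Reports per-covariate hazard ratios with
#' Wald 95% confidence intervals on the log scale, plus the global score
#' test evaluated at coefficient zero -- the statistic used for split
#' search in the disease-activity tree.
#'
#' @param data Data frame containing `time`, `event` and the covariates.
#' @param covariates Character vector of covariate column names (must be
#'   non-constant).
#' @param ties `"efron"` (default) or `"breslow"`.
#' @param time_col,event_col Column names for follow-up time and event
#'   indicator.
#' @return Object of class `cox_fit` with elements `coefficients`, `se`,
#'   `hr`, `ci95` (matrix with columns `low`, `high`), `wald_p`,
#'   `score_stat`, `score_df`, `score_p`, `converged`, `n`, `n_events`.
#' @export
cox_fit <- function(data, covariates, ties = c("efron", "breslow"),
                    time_col = "time", event_col = "event") {
  ties <- match.arg(ties)
  stopifnot(is.data.frame(data), nrow(data) >= 1)
  miss <- setdiff(c(time_col, event_col, covariates), names(data))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  for (v in covariates) {
    x <- data[[v]]
    if (length(unique(x[!is.na(x)])) < 2)
      stop("degenerate covariate (constant): ", v)
  }
  fml <- stats::as.formula(paste0(
    "survival::Surv(", time_col, ", ", event_col, ") ~ ",
    paste(covariates, collapse = " + ")))
  fit <- suppressWarnings(survival::coxph(fml, data = data, ties = ties))
  s <- summary(fit)
  coefs <- stats::coef(fit)
  se <- sqrt(diag(fit$var))
  z <- stats::qnorm(0.975)
  ci <- cbind(low = exp(coefs - z * se), high = exp(coefs + z * se))
  score_df <- length(coefs)
  structure(list(
    coefficients = coefs, se = se, hr = exp(coefs), ci95 = ci,
    wald_p = 2 * stats::pnorm(-abs(coefs / se)),
    score_stat = unname(fit$score), score_df = score_df,
    score_p = stats::pchisq(unname(fit$score), score_df, lower.tail = FALSE),
    converged = is.null(fit$info) && fit$iter < 20 && !any(is.na(coefs)),
    n = s$n, n_events = s$nevent, ties = ties, fit = fit),
    class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Cox proportional-hazards fit (%s ties): n = %d, events = %d\n",
              x$ties, x$n, x$n_events))
  tab <- data.frame(coef = x$coefficients, HR = x$hr,
                    lower95 = x$ci95[, "low"], upper95 = x$ci95[, "high"],
                    wald_p = x$wald_p)
  print(round(tab, digits))
  cat(sprintf("Score test: chisq = %.4g on %d df, p = %.4g\n",
              x$score_stat, x$score_df, x$score_p))
  invisible(x)
}

# Candidate binary partitions of a variable.
#  - binary / few distinct values (<= 12): every threshold between adjacent
#    observed values (covers relapse counts {1..4} and the EDSS half grid);
#  - continuous with many values: inner decile grid of the observed values;
#  - categorical: all one-level-vs-rest partitions.
split_candidates <- function(x, kind) {
  if (kind == "categorical") {
    lv <- sort(unique(as.character(x)))
    return(lapply(lv, function(l) list(type = "levels", levels = l)))
  }
  u <- sort(unique(x))
  if (length(u) < 2) return(list())
  if (kind == "binary" || length(u) <= 12) {
    thr <- (u[-length(u)] + u[-1]) / 2
  } else {
    qs <- stats::quantile(x, probs = seq(0.1, 0.9, by = 0.1),
                          names = FALSE, type = 7)
    thr <- unique(qs)
    thr <- thr[thr > u[1] & thr < u[length(u)]]
  }
  lapply(thr, function(t) list(type = "threshold", threshold = t))
}

split_indicator <- function(x, cand) {
  if (cand$type == "levels") as.integer(as.character(x) %in% cand$levels)
  else as.integer(x > cand$threshold)
}

split_label <- function(variable, cand) {
  if (cand$type == "levels")
    sprintf("%s in {%s}", variable, paste(cand$levels, collapse = ","))
  else
    sprintf("%s > %g", variable, cand$threshold)
}

#' Strongest binary split of one variable
#'
#' Enumerates candidate binary partitions of `variable` (thresholds between
#' observed values for ordinal/low-cardinality variables, the decile grid
#' for continuous ones, one-vs-rest for categorical ones), keeps those where
#' both sides have at least `min_size` subjects, scores each by the Cox
#' score test of the split indicator, and returns the candidate with the
#' smallest score-test p-value together with its log-rank p-value. No
#' multiplicity correction is applied across candidates; the two p-values
#' are the raw per-test values used by the dual gate of [dgcart()].
#'
#' @param data Data frame with `time`, `event` and the variable.
#' @param variable Column name.
#' @param kind `"auto"` (default), `"binary"`, `"ordinal"`, `"continuous"`
#'   or `"categorical"`.
#' @param min_size Minimum subjects on each side of the split (default 5).
#' @param ties Tie handling for the score test.
#' @return `NULL` if no admissible candidate exists, else a list with
#'   `variable`, `split` (candidate description), `label`, `score_p`,
#'   `score_stat`, `logrank_p`, `n_left`, `n_right`.
#' @export
best_binary_split <- function(data, variable, kind = "auto", min_size = 5,
                              ties = "efron") {
  stopifnot(is.data.frame(data), variable %in% names(data))
  x <- data[[variable]]
  if (kind == "auto")
    kind <- if (is.character(x) || is.factor(x)) "categorical"
            else if (length(unique(x)) <= 2) "binary"
            else "continuous"
  cands <- split_candidates(x, kind)
  best <- NULL
  for (cand in cands) {
    ind <- split_indicator(x, cand)
    if (sum(ind == 1) < min_size || sum(ind == 0) < min_size) next
    if (sum(data$event) < 1) next
    d2 <- data.frame(time = data$time, event = data$event, .split = ind)
    sc <- tryCatch({
      f <- cox_fit(d2, ".split", ties = ties)
      list(p = f$score_p, stat = f$score_stat)
    }, error = function(e) list(p = NA_real_, stat = NA_real_))
    if (is.na(sc$p)) next
    if (is.null(best) || sc$p < best$score_p) {
      best <- list(variable = variable, split = cand,
                   label = split_label(variable, cand),
                   score_p = sc$p, score_stat = sc$stat, indicator = ind,
                   n_left = sum(ind == 0), n_right = sum(ind == 1))
    }
  }
  if (is.null(best)) return(NULL)
  lr <- logrank_test(data$time, data$event, best$indicator)
  best$logrank_p <- lr$p.value
  best
}
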