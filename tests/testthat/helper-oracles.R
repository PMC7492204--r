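# Independent oracles used across the suite. These deliberately avoid the
# package's own survival wrappers (and the survival package) so that they
# can serve as cross-checks.

# Two-group log-rank chi-square by direct per-event-time hypergeometric
# O-E / V tabulation.
logrank_oracle <- function(time, event, group) {
  stopifnot(length(unique(group)) == 2)
  g1 <- group == sort(unique(group))[2]
  O <- E <- V <- 0
  for (t in sort(unique(time[event == 1]))) {
    at_risk <- time >= t
    n <- sum(at_risk)
    n1 <- sum(at_risk & g1)
    d <- sum(event == 1 & time == t)
    d1 <- sum(event == 1 & time == t & g1)
    O <- O + d1
    E <- E + d * n1 / n
    if (n > 1) V <- V + d * (n1 / n) * (1 - n1 / n) * (n - d) / (n - 1)
  }
  (O - E)^2 / V
}

# Hand product-limit estimator (events-first at ties).
km_oracle <- function(time, event) {
  ts <- sort(unique(time[event == 1]))
  s <- 1
  out <- numeric(length(ts))
  for (i in seq_along(ts)) {
    t <- ts[i]
    n <- sum(time >= t)
    d <- sum(time == t & event == 1)
    s <- s * (1 - d / n)
    out[i] <- s
  }
  data.frame(time = ts, surv = out)
}

# Exhaustive rank-sum permutation distribution for tiny two-sample data:
# returns the two-sided p-value of the observed rank sum of x.
ranksum_permutation_oracle <- function(x, y) {
  pooled <- c(x, y)
  r <- rank(pooled)
  n <- length(x)
  idx <- utils::combn(length(pooled), n)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  obs <- sum(r[seq_len(n)])
  centre <- n * (length(pooled) + 1) / 2
  mean(abs(sums - centre) >= abs(obs - centre) - 1e-9)
}

# Standard candidate formula (model variant B) used by tree tests.
cdaf_formula_B <- survival::Surv(time, event) ~ poly + relapse_count_2y +
  sex + dominant_symptom + baseline_edss + most_affected_kfs + prior_dmt +
  age_at_baseline + age_at_first_symptom
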