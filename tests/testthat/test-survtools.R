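# Kaplan-Meier, log-rank, Cox and split-search utilities, checked against
# hand oracles and closed forms.

test_that("KM matches the hand product-limit example {2e, 4c, 6e}", {
  cv <- km_estimate(c(2, 4, 6), c(1, 0, 1))
  expect_equal(km_prob_at(cv, 2), 2 / 3)
  expect_equal(km_prob_at(cv, 3), 2 / 3)
  expect_equal(km_prob_at(cv, 6), 0)
  expect_equal(km_prob_at(cv, 1), 1)
})

test_that("KM with all subjects censored stays at 1", {
  cv <- km_estimate(c(3, 7, 11), c(0, 0, 0))
  expect_true(all(km_prob_at(cv, c(0, 5, 12)) == 1))
})

test_that("KM without censoring equals 1 - ECDF exactly", {
  set.seed(5)
  t <- round(rexp(400, 0.1), 3)
  cv <- km_estimate(t, rep(1, 400))
  for (q in quantile(t, c(0.1, 0.35, 0.6, 0.9)))
    expect_equal(km_prob_at(cv, q), mean(t > q))
})

test_that("KM converges to the exponential survival function", {
  set.seed(8)
  h <- 0.07
  t <- rexp(10000, h)
  cv <- km_estimate(t, rep(1, 10000))
  grid <- seq(1, 30, by = 1)
  expect_lt(max(abs(km_prob_at(cv, grid) - exp(-h * grid))), 0.02)
})

test_that("KM agrees with the independent product-limit oracle under censoring", {
  set.seed(21)
  t <- round(rexp(200, 0.08), 2)
  e <- rbinom(200, 1, 0.7)
  cv <- km_estimate(t, e)
  or <- km_oracle(t, e)
  expect_equal(km_prob_at(cv, or$time), or$surv, tolerance = 1e-12)
})

test_that("log-rank matches the per-event-time hypergeometric oracle", {
  # tiny all-events example
  lr <- logrank_test(c(1, 2, 3, 4), c(1, 1, 1, 1), c(0, 0, 1, 1))
  expect_equal(unname(lr$statistic),
               logrank_oracle(c(1, 2, 3, 4), c(1, 1, 1, 1), c(0, 0, 1, 1)),
               tolerance = 1e-12)
  # randomised datasets with censoring and ties
  set.seed(14)
  for (i in 1:25) {
    n <- sample(10:40, 1)
    t <- sample(1:12, n, replace = TRUE)
    e <- rbinom(n, 1, 0.75)
    g <- rbinom(n, 1, 0.5)
    if (sum(e) == 0 || length(unique(g)) < 2) next
    lr <- logrank_test(t, e, g)
    expect_equal(unname(lr$statistic), logrank_oracle(t, e, g),
                 tolerance = 1e-8)
  }
})

test_that("log-rank is symmetric in group labels and zero for identical groups", {
  set.seed(3)
  t <- rexp(60, 0.1); e <- rbinom(60, 1, 0.8); g <- rep(0:1, 30)
  a <- logrank_test(t, e, g)
  b <- logrank_test(t, e, 1 - g)
  expect_equal(a$statistic, b$statistic)
  # two copies of the same data as the two groups
  lr0 <- logrank_test(c(t, t), c(e, e), rep(0:1, each = 60))
  expect_lt(unname(lr0$statistic), 1e-12)
  # invariant under strictly monotone time transforms
  a2 <- logrank_test(log(t + 1), e, g)
  expect_equal(a$statistic, a2$statistic, tolerance = 1e-12)
})

test_that("Cox on balanced identical groups estimates a null coefficient", {
  d <- data.frame(time = rep(c(2, 5, 9, 14), 2),
                  event = rep(c(1, 1, 0, 1), 2),
                  g = rep(0:1, each = 4))
  f <- cox_fit(d, "g")
  expect_lt(abs(unname(f$coefficients)), 1e-6)
  expect_error(cox_fit(data.frame(time = 1:4, event = c(1, 1, 0, 1),
                                  g = rep(1, 4)), "g"),
               "degenerate")
})

test_that("Cox recovers a true hazard ratio of 2 from exponential data", {
  set.seed(77)
  n <- 5000
  g <- rep(0:1, each = n / 2)
  t <- rexp(n, 0.05 * 2^g)
  cens <- rexp(n, 0.012)  # roughly 20% censoring
  d <- data.frame(time = pmin(t, cens), event = as.integer(t <= cens), g = g)
  f <- cox_fit(d, "g")
  expect_gt(f$hr, 1.8); expect_lt(f$hr, 2.2)
})

test_that("score test equals the log-rank chi-square for a binary covariate", {
  set.seed(19)
  for (i in 1:30) {
    n <- sample(12:40, 1)
    t <- round(rexp(n, 0.1) + runif(n) * 1e-4, 8)  # continuous, no ties
    e <- rbinom(n, 1, 0.8)
    g <- rbinom(n, 1, 0.5)
    if (sum(e) < 2 || length(unique(g)) < 2) next
    f <- cox_fit(data.frame(time = t, event = e, g = g), "g",
                 ties = "breslow")
    lr <- logrank_test(t, e, g)
    expect_equal(f$score_stat, unname(lr$statistic), tolerance = 1e-8)
  }
})

test_that("with sparse ties, Breslow score and log-rank agree to 1e-3 relative", {
  set.seed(23)
  n <- 300
  t <- rexp(n, 0.1)
  t[1:5] <- t[6:10]  # a handful of tied pairs in large risk sets
  e <- rbinom(n, 1, 0.8); e[1:10] <- 1
  g <- rbinom(n, 1, 0.5)
  f <- cox_fit(data.frame(time = t, event = e, g = g), "g", ties = "breslow")
  lr <- logrank_test(t, e, g)
  expect_equal(f$score_stat, unname(lr$statistic), tolerance = 1e-3)
})

test_that("split candidates for relapse counts are the three thresholds", {
  set.seed(2)
  d <- data.frame(time = rexp(120, 0.1), event = rbinom(120, 1, 0.8),
                  count = sample(1:4, 120, replace = TRUE))
  cands <- msdaf:::split_candidates(d$count, "ordinal")
  expect_equal(vapply(cands, `[[`, numeric(1), "threshold"),
               c(1.5, 2.5, 3.5))
  bs <- best_binary_split(d, "count")
  expect_true(bs$split$threshold %in% c(1.5, 2.5, 3.5))
  expect_true(bs$n_left >= 5 && bs$n_right >= 5)
})

test_that("constant variables and undersized sides yield no split", {
  d <- data.frame(time = rexp(40, 0.1), event = rbinom(40, 1, 0.8),
                  k = rep(2, 40), j = c(rep(0, 2), rep(1, 38)))
  expect_null(best_binary_split(d, "k"))
  # both sides must satisfy the minimum size
  expect_null(best_binary_split(d, "j", min_size = 5))
})

test_that("categorical candidates are one-vs-rest partitions", {
  set.seed(4)
  d <- data.frame(time = rexp(90, 0.1), event = rbinom(90, 1, 0.8),
                  sym = sample(c("a", "b", "c"), 90, replace = TRUE))
  cands <- msdaf:::split_candidates(d$sym, "categorical")
  expect_equal(vapply(cands, function(x) x$levels, character(1)),
               c("a", "b", "c"))
})

test_that("split search finds a planted change-point at the right threshold", {
  set.seed(41)
  n <- 1500
  x <- runif(n)
  thr <- quantile(x, 0.4, names = FALSE)
  h <- ifelse(x > thr, 0.10, 0.05)  # hazard doubles above the threshold
  t <- rexp(n, h)
  d <- data.frame(time = pmin(t, 24), event = as.integer(t <= 24), x = x)
  bs <- best_binary_split(d, "x", kind = "continuous")
  # selected decile threshold sits at (or next to) the planted 40% quantile
  sel_q <- mean(x <= bs$split$threshold)
  expect_lt(abs(sel_q - 0.4), 0.11)
  expect_lt(bs$score_p, 1e-6)
  expect_lt(bs$logrank_p, 1e-6)
})
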