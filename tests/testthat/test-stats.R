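test_that("rank-sum test matches exact enumeration and identities", {
  # fully separated 3 vs 3: U = 0, exact two-sided p = 2 * 1/C(6,3) = 0.1
  cmp <- rank_sum_test(c(1, 2, 3), c(4, 5, 6))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 0.1)
  expect_match(cmp$method, "exact")

  # identical tied groups: U = n_a n_b / 2 by symmetry of midranks
  cmp2 <- rank_sum_test(c(1, 1, 2, 2), c(1, 1, 2, 2))
  expect_equal(cmp2$statistic, 8)

  # U_a + U_b = n_a n_b on arbitrary data
  set.seed(3)
  for (i in 1:20) {
    a <- rnorm(sample(3:15, 1)); b <- rnorm(sample(3:15, 1))
    ua <- rank_sum_test(a, b)$statistic
    ub <- rank_sum_test(b, a)$statistic
    expect_equal(ua + ub, length(a) * length(b))
  }
  expect_error(rank_sum_test(numeric(0), 1), "nonempty")
})

test_that("rank-sum p-values are approximately uniform under the null", {
  set.seed(11)
  p <- replicate(500, {
    x <- rnorm(10); y <- rnorm(10)
    rank_sum_test(x, y)$p_value
  })
  frac <- mean(p < 0.05)
  expect_gte(frac, 0.02)
  expect_lte(frac, 0.09)
})

test_that("rank-based AUC handles separation, inversion and ties", {
  expect_equal(roc_auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(roc_auc(c(1, 2, 3, 4), c(1, 1, 0, 0)), 0)
  expect_equal(roc_auc(c(1, 1, 2), c(0, 1, 1)), 0.75)  # tie counts 1/2
  expect_error(roc_auc(1:4, c(1, 1, 1, 1)), "both classes")
  # complement identity on random data
  set.seed(4)
  s <- rnorm(40); l <- rbinom(40, 1, 0.3); l[1] <- 1; l[2] <- 0
  expect_equal(roc_auc(s, l) + roc_auc(s, 1 - l), 1)
})

test_that("separation diagnostic flags disjoint and near-disjoint classes", {
  sep <- detect_complete_separation(c(1, 2, 3, 4, 5, 6), c(0, 0, 0, 1, 1, 1))
  expect_true(sep$flag)
  expect_equal(sep$overlap, 0)

  inter <- detect_complete_separation(c(1, 2, 3, 4, 5, 6), c(0, 1, 0, 1, 0, 1))
  expect_false(inter$flag)
  expect_gt(inter$overlap, 0.5)

  # a single event dipping below one non-event -> near-complete separation
  scores <- c(1:80, 79.5, 82:101)
  labels <- c(rep(0, 80), rep(1, 21))
  near <- detect_complete_separation(scores, labels)
  expect_true(near$flag)
  expect_equal(near$overlap, 2 / 101, tolerance = 1e-9)
})

test_that("Kaplan-Meier reproduces hand-computed product limits", {
  # all censored: survival stays at 1
  km0 <- kaplan_meier(c(2, 3, 5), c(0, 0, 0))
  expect_true(all(km0$survival == 1))

  # n = 2, events at 1 and 2: S(1) = 1/2, S(2) = 0
  km1 <- kaplan_meier(c(1, 2), c(1, 1))
  expect_equal(km1$survival[km1$time == 1], 0.5)
  expect_equal(km1$survival[km1$time == 2], 0)

  # n = 3: event at 1, censored at 2, event at 3: S(1) = 2/3, S(3) = 0
  km2 <- kaplan_meier(c(1, 2, 3), c(1, 0, 1))
  expect_equal(km2$survival[km2$time == 1], 2 / 3)
  expect_equal(km2$survival[km2$time == 3], 0)

  expect_error(kaplan_meier(c(-1, 2), c(1, 1)), "nonnegative")
})

test_that("Kaplan-Meier without censoring equals the empirical survival", {
  set.seed(8)
  t <- sample(1:50, 30, replace = TRUE)
  km <- kaplan_meier(t, rep(1, 30))
  for (i in seq_len(nrow(km)))
    expect_equal(km$survival[i], mean(t > km$time[i]))
})

test_that("log-rank is zero on identical groups and matches hand-computed O/E", {
  g <- list(times = c(1, 3, 5, 7), observed = c(1, 0, 1, 1))
  cmp <- log_rank(list(g, g))
  expect_equal(cmp$statistic, 0)
  expect_equal(cmp$p_value, 1)

  # events only in one group of a 4-subject cohort:
  # A events at 1, 2; B censored at 3, 3.
  # t=1: O_A=1 E_A=1/2 V=1/4; t=2: O_A=1 E_A=1/3 V=2/9
  # chi-square = (2 - 5/6)^2 / (1/4 + 2/9) = 2.882353
  cmp2 <- log_rank(list(list(times = c(1, 2), observed = c(1, 1)),
                        list(times = c(3, 3), observed = c(0, 0))))
  expect_equal(cmp2$statistic, (2 - 5 / 6)^2 / (1 / 4 + 2 / 9),
               tolerance = 1e-9)
  expect_equal(cmp2$p_value,
               pchisq(cmp2$statistic, df = 1, lower.tail = FALSE))

  expect_error(log_rank(list(list(times = 1:2, observed = c(0, 0)),
                             list(times = 1:2, observed = c(0, 0)))),
               "degenerate")
  expect_error(log_rank(list(g)), "two groups")
})

test_that("tertile split places boundary values in the lower tertile", {
  expect_identical(tertile_split(1:9), rep(1:3, each = 3L))
  expect_warning(t1 <- tertile_split(rep(4, 6)), "identical")
  expect_true(all(t1 == 1L))
  # permutation invariance
  set.seed(5)
  v <- rnorm(30)
  perm <- sample(30)
  expect_identical(tertile_split(v)[perm], tertile_split(v[perm]))
})

test_that("delay-tertile survival stratification follows the event labels", {
  co <- base_cohort(1)
  km <- km_by_delay_tertiles(co)
  expect_named(km$curves, c("T1", "T2", "T3"))
  expect_equal(as.integer(table(km$tertile)), c(34, 33, 33))
  # event fraction rises toward the slowest tertile on the calibrated cohort
  expect_true(all(diff(km$event_fraction) >= 0))
  expect_lt(km$comparison$p_value, 0.001)

  # zero events: flat curves, no comparison
  co0 <- co
  co0$metrics$event_cv <- 0L
  km0 <- km_by_delay_tertiles(co0)
  expect_true(all(vapply(km0$curves, function(cv) all(cv$survival == 1),
                         logical(1))))
  expect_null(km0$comparison)

  # six distinct delays split 2/2/2
  co6 <- co
  co6$metrics <- co$metrics[1:6, ]
  co6$metrics$time_to_peak_y <- c(5, 10, 15, 20, 25, 30)
  km6 <- km_by_delay_tertiles(co6)
  expect_equal(as.integer(table(km6$tertile)), c(2, 2, 2))

  co2 <- co
  co2$metrics <- co$metrics[1:4, ]
  co2$metrics$time_to_peak_y <- c(1, 1, 2, 2)
  expect_error(km_by_delay_tertiles(co2), "distinct")
})
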