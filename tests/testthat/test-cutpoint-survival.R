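# Log-rank statistic, KM estimator, cutpoint scan and the permutation
# correction. survival:: is used only as an independent oracle.

test_that("log-rank is zero for identical group profiles and symmetric", {
  co <- data.frame(time = rep(c(1, 3, 5, 7), 2),
                   event = rep(c(1, 1, 0, 1), 2),
                   marker = 0)
  g <- rep(c(TRUE, FALSE), each = 4)
  r <- logrank_statistic(co, g)
  expect_equal(r$statistic, 0, tolerance = 1e-12)
  expect_equal(r$p_value, 1, tolerance = 1e-12)
  # label swap leaves the statistic unchanged
  set.seed(51)
  co2 <- random_cohort(51)
  g2 <- co2$marker > median(co2$marker)
  expect_equal(logrank_statistic(co2, g2)$statistic,
               logrank_statistic(co2, !g2)$statistic, tolerance = 1e-12)
})

test_that("log-rank equals the hand oracle and survival::survdiff", {
  skip_if_not_installed("survival")
  # worked 6-patient cohort: all events, groups by time thirds
  co <- data.frame(time = 1:6, event = 1L, marker = 0)
  g <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE)
  r <- logrank_statistic(co, g)
  expect_equal(r$statistic, oracle_logrank(co$time, co$event, g),
               tolerance = 1e-10)
  sd6 <- survival::survdiff(survival::Surv(time, event) ~ g, data = co)
  expect_equal(r$statistic, unname(sd6$chisq), tolerance = 1e-8)

  for (seed in 52:66) {
    co <- random_cohort(seed, n = sample(4:8, 1))
    if (sum(co$event) == 0) next
    g <- co$marker > median(co$marker)
    if (!any(g) || all(g)) next
    r <- logrank_statistic(co, g)
    expect_equal(r$statistic, oracle_logrank(co$time, co$event, g),
                 tolerance = 1e-10)
    sd <- survival::survdiff(survival::Surv(time, event) ~ g, data = co)
    expect_equal(r$statistic, unname(sd$chisq), tolerance = 1e-8)
    # internal identity: chi-square is the squared standardized O - E
    expect_equal(r$statistic, r$observed_minus_expected^2 / r$variance,
                 tolerance = 1e-12)
  }
})

test_that("log-rank input validation and zero-event convention", {
  co <- data.frame(time = 1:4, event = c(0L, 0L, 0L, 0L), marker = 0)
  expect_warning(r <- logrank_statistic(co, c(TRUE, TRUE, FALSE, FALSE)),
                 "no events")
  expect_equal(r$p_value, 1)
  co$event <- 1L
  expect_error(logrank_statistic(co, rep(TRUE, 4)), "non-empty")
  expect_error(logrank_statistic(transform(co, event = 2L),
                                 c(TRUE, FALSE, TRUE, FALSE)), "event")
})

test_that("KM estimator matches hand calculations and survival::survfit", {
  skip_if_not_installed("survival")
  # no events: S(t) = 1 throughout
  co <- data.frame(time = 1:4, event = 0L, marker = 0)
  expect_true(all(km_estimate(co)$survival == 1))
  # single event among 4 at t = 2, everyone at risk there: single factor 3/4
  co <- data.frame(time = c(2, 3, 4, 5), event = c(1L, 0L, 0L, 0L), marker = 0)
  km <- km_estimate(co)
  expect_equal(km$survival[km$time == 2], 0.75)
  expect_equal(km$survival[km$time == 5], 0.75)
  # censoring shrinks later risk sets without a drop:
  # times 1(ev) 2(cens) 3(ev) 4(ev) 5: S = 4/5, 4/5, 4/5*2/3, 4/5*2/3*1/2
  co <- data.frame(time = 1:5, event = c(1L, 0L, 1L, 1L, 0L), marker = 0)
  km <- km_estimate(co)
  expect_equal(km$survival, c(4/5, 4/5, 4/5 * 2/3, 4/5 * 2/3 * 1/2,
                              4/5 * 2/3 * 1/2), tolerance = 1e-12)

  for (seed in 61:70) {
    co <- random_cohort(seed, n = 30)
    km <- km_estimate(co)
    # bounded, non-increasing step function
    expect_true(all(km$survival >= 0 & km$survival <= 1))
    expect_true(all(diff(km$survival) <= 1e-12))
    sf <- survival::survfit(survival::Surv(time, event) ~ 1, data = co)
    expect_equal(km$survival, unname(sf$surv), tolerance = 1e-10)
    expect_equal(km$n_risk, sf$n.risk, ignore_attr = TRUE)
  }

  # with no censoring KM equals the empirical survival function
  co <- random_cohort(71, n = 20, censor = FALSE)
  km <- km_estimate(co)
  emp <- vapply(km$time, function(t) mean(co$time > t), numeric(1))
  expect_equal(km$survival, emp, tolerance = 1e-12)
})

test_that("best_cutpoint honors candidates, constraints and tie-breaks", {
  # exactly 2 distinct marker values: single forced candidate
  co <- data.frame(time = c(1, 2, 3, 4, 5, 6), event = 1L,
                   marker = rep(c(0, 1), each = 3))
  r <- best_cutpoint(co, min_prop = 0.3)
  expect_equal(nrow(r$selection_trace), 1L)
  expect_equal(r$cutoff, 0.5)
  expect_equal(r$n_high + r$n_low, 6L)

  expect_error(best_cutpoint(transform(co, marker = 1)), "constant")

  # all stats tie at 0 (no events): the median-proximity rule decides
  co0 <- data.frame(time = 1:10, event = 0L, marker = 1:10)
  suppressWarnings(r0 <- best_cutpoint(co0, min_prop = 0.2))
  med <- median(co0$marker)
  expect_equal(r0$cutoff,
               r0$selection_trace$candidate[
                 which.min(abs(r0$selection_trace$candidate - med))])

  # group-proportion constraint bounds both arms
  co2 <- simulate_survival_cohort(surv_sim_config(n_patients = 100, seed = 52))
  r2 <- best_cutpoint(co2, min_prop = 0.25)
  expect_gte(r2$n_high / 100, 0.25)
  expect_gte(r2$n_low / 100, 0.25)
  # the selected stat is the maximum of the trace
  expect_equal(r2$logrank_stat, max(r2$selection_trace$stat))
})

test_that("cutpoint recovery and monotone-transform invariance", {
  co <- simulate_survival_cohort(surv_sim_config(seed = 53))
  r <- best_cutpoint(co)
  band <- quantile(co$marker, c(0.45, 0.55))
  expect_gte(r$cutoff, band[[1]])
  expect_lte(r$cutoff, band[[2]])

  # strictly increasing marker transform: identical grouping
  co_t <- transform(co, marker = exp(marker))
  r_t <- best_cutpoint(co_t)
  expect_identical(co$marker > r$cutoff, co_t$marker > r_t$cutoff)
  expect_equal(r_t$logrank_stat, r$logrank_stat, tolerance = 1e-9)
})

test_that("naive best-cutoff p is anti-conservative under the null", {
  hits <- 0L
  n_rep <- 60L
  for (i in seq_len(n_rep)) {
    co <- simulate_survival_cohort(surv_sim_config(
      n_patients = 40, hazard_low = 0.1, hazard_high = 0.1, seed = 500 + i))
    hits <- hits + (best_cutpoint(co)$p_value <= 0.05)
  }
  # far above the nominal 0.05 (binomial sd at p=.05, n=60 is ~0.028)
  expect_gt(hits / n_rep, 0.12)
})

test_that("corrected p dominates the naive p and is seed-stable", {
  co <- simulate_survival_cohort(surv_sim_config(n_patients = 120, seed = 54))
  cp <- corrected_cutpoint_p(co, n_permutations = 200, seed = 9)
  expect_gte(cp$p_adjusted, cp$p_naive)
  expect_gte(cp$p_adjusted, 1 / 201)
  cp2 <- corrected_cutpoint_p(co, n_permutations = 200, seed = 9)
  expect_identical(cp$p_adjusted, cp2$p_adjusted)
  expect_warning(corrected_cutpoint_p(co, n_permutations = 50, seed = 1),
                 "fewer than 100")
})
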