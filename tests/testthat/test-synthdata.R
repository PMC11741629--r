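test_that("generation is reproducible and respects hazard limits", {
  cfg <- synth_config(n = 200, horizon = 6)
  g1 <- generate_survival_data(cfg, seed = 5)
  g2 <- generate_survival_data(cfg, seed = 5)
  expect_identical(as.data.frame(g1$data), as.data.frame(g2$data))
  expect_identical(g1$true_surv, g2$true_surv)
  g3 <- generate_survival_data(cfg, seed = 6)
  expect_false(identical(g1$data$time, g3$data$time))

  # hazard ~ 0: everyone is administratively censored
  none <- generate_survival_data(
    synth_config(n = 100, horizon = 5, baseline = -50, effects = 0), seed = 1)
  expect_true(all(none$data$event == 0))
  # hazard ~ 1: every event in period 1
  all1 <- generate_survival_data(
    synth_config(n = 100, horizon = 5, baseline = 50, effects = 0), seed = 1)
  expect_true(all(all1$data$event == 1))
  expect_true(all(all1$data$time > 0 & all1$data$time < 1))  # died in period 1
})

test_that("constant-hazard survival matches the geometric closed form", {
  # hazard 0.1 every period, no censoring inside the horizon
  h <- 0.1
  cfg <- synth_config(n = 50000, n_features = 1, horizon = 10,
                      baseline = qlogis(h), effects = 0,
                      max_periods = 40, followup_min = 40, followup_max = 41)
  g <- generate_survival_data(cfg, seed = 77)
  expect_equal(unique(as.vector(round(g$hazard, 12))), h)
  km <- km_baseline(g$data)
  for (tau in c(1, 3, 5, 10)) {
    # deaths in periods <= tau all have observed time < tau
    expect_equal(km$step(tau), (1 - h)^tau, tolerance = 0.01)
  }
  # true survival matrix agrees with the closed form exactly
  expect_equal(g$true_surv[1, ], (1 - h)^(1:10), ignore_attr = TRUE)
})

test_that("empirical event-time distribution converges to the configured hazard", {
  cfg <- synth_config(n = 50000, n_features = 2, horizon = 10,
                      baseline = -2, effects = 0.7,
                      max_periods = 30, followup_min = 30, followup_max = 31)
  g <- generate_survival_data(cfg, seed = 78)
  # with no censoring inside the mechanism, compare the empirical survival
  # to the mean true survival (marginal over covariates)
  emp <- vapply(1:10, function(tau) mean(g$data$time > tau), numeric(1))
  theor <- colMeans(g$true_surv)
  expect_lt(max(abs(emp - theor)), 0.02)
})

test_that("censoring fraction grows as the follow-up window shrinks", {
  frac <- sapply(c(20, 10, 5, 2), function(fu) {
    g <- generate_survival_data(
      synth_config(n = 3000, horizon = 10, baseline = -2.5,
                   followup_min = 1, followup_max = fu), seed = 79)
    mean(g$data$event == 0)
  })
  expect_true(all(diff(frac) > 0))
})

test_that("imbalance scenarios show the documented class-ratio behaviour over P", {
  mc <- generate_survival_data(imbalance_scenario("minimal_censoring"),
                               seed = 80)
  cd <- generate_survival_data(imbalance_scenario("censoring_dominance"),
                               seed = 80)
  # the scenarios realize the intended censoring regimes
  expect_lt(mean(mc$data$event == 0), 0.05)
  expect_gt(mean(cd$data$event == 0), 0.5)

  horizons <- c(5, 10, 20)
  r_mc <- sapply(horizons, function(P) case_class_ratio(mc$data, P))
  r_cd <- sapply(horizons, function(P) case_class_ratio(cd$data, P))
  # censoring dominance: the all-positive censored rows make the positive
  # class the majority, and lengthening the horizon moves the ratio toward
  # balance (the ratio itself is non-increasing in P)
  expect_true(all(r_cd > 0.5))
  expect_true(all(diff(abs(r_cd - 0.5)) < 0))
  # minimal censoring: the ratio is governed by the event-time distribution
  # alone — it matches the ground-truth oracle E[min(floor(T), P)] / P
  for (j in seq_along(horizons)) {
    P <- horizons[j]
    oracle <- mean(pmin(floor(mc$true_time), P), na.rm = TRUE) / P
    expect_equal(r_mc[j], oracle, tolerance = 0.02)
  }
  # deterministic configs
  expect_identical(imbalance_scenario("minimal_censoring"),
                   imbalance_scenario("minimal_censoring"))
})

test_that("a bimodal hazard configuration yields a non-monotone survival-time density", {
  # low mid-study hazard with a late spike reproduces a late bump in the
  # distribution of observed event times
  P <- 20
  alpha <- rep(-4, 2 * P)
  alpha[1:3] <- -1.2       # early mortality
  alpha[17:20] <- -1.2     # late bump
  cfg <- synth_config(n = 20000, n_features = 1, horizon = P,
                      baseline = alpha, effects = 0,
                      max_periods = 2 * P, followup_min = 2 * P,
                      followup_max = 2 * P + 1)
  g <- generate_survival_data(cfg, seed = 81)
  ev_times <- g$data$time[g$data$event == 1]
  dens <- tabulate(ceiling(ev_times), nbins = P)  # period of death
  mid <- mean(dens[8:14])
  late <- mean(dens[17:20])
  expect_gt(late, 2 * mid)
})
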