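test_that("ideal curve passes through 0.5 at the event time and decreases", {
  f <- ideal_curve(10, steepness = 2)
  expect_equal(f(10), 0.5)
  grid <- seq(0, 20, by = 0.5)
  expect_true(all(diff(f(grid)) < 0))
  # steep limit approaches the step function
  sharp <- ideal_curve(10, steepness = 200)
  expect_gt(sharp(9.9), 0.999)
  expect_lt(sharp(10.1), 0.001)
  expect_lt(f(10 + 50), 1e-10)  # tail limit
  expect_error(ideal_curve(5, steepness = 0))
})

test_that("the time weight is 1 at the event, exp(-1) at distance P, and caps T_i at P", {
  expect_equal(ausc_weight(10, 10, 20), 1)
  expect_equal(ausc_weight(0, 20, 20), exp(-1))
  expect_equal(ausc_weight(15, 30, 20), exp(-abs(15 - 20) / 20))  # T capped
})

test_that("iAUSC closed forms: perfect step scores 1, constant half scores exactly 0.5", {
  step_pred <- function(t) as.numeric(t <= 10)
  s <- iausc(step_pred, event_time = 10, horizon = 20)
  expect_equal(as.numeric(s), 1, tolerance = 1e-3)
  const <- iausc(function(t) rep(0.5, length(t)), event_time = 10,
                 horizon = 20)
  expect_equal(as.numeric(const), 0.5)
  expect_equal(attr(const, "error"), 0.5)
  expect_error(iausc(step_pred, event_time = NA, horizon = 20), "censored")
})

test_that("flip symmetry: score(S) + score(1-S) = 1 for any predictor", {
  set.seed(61)
  for (rep in 1:5) {
    curve <- runif(12)
    f <- function(t) interpolate_curve(curve, t)
    g <- function(t) 1 - f(t)
    Ti <- runif(1, 0, 12)
    s1 <- as.numeric(iausc(f, Ti, horizon = 12))
    s2 <- as.numeric(iausc(g, Ti, horizon = 12))
    expect_equal(s1 + s2, 1, tolerance = 1e-10)
  }
})

test_that("iAUSC matches an independent fine-grid quadrature oracle", {
  # oracle: plain trapezoid of the full integrand at 10x finer resolution,
  # written independently of the implementation's segment splitting
  oracle <- function(shat, Ti, P, h) {
    g <- sort(unique(c(seq(0, P, by = h), Ti)))
    w <- exp(-abs(g - min(Ti, P)) / P)
    dev <- abs(shat(g) - as.numeric(g <= Ti)) * w
    tr <- function(y) sum(diff(g) * (y[-1] + y[-length(y)])) / 2
    1 - tr(dev) / tr(w)
  }
  shat <- ideal_curve(10, steepness = 1)
  got <- as.numeric(iausc(shat, event_time = 10, horizon = 20))
  expect_equal(got, oracle(shat, 10, 20, 0.001), tolerance = 1e-3)

  smooth2 <- function(t) 0.9 * exp(-t / 8)
  got2 <- as.numeric(iausc(smooth2, event_time = 6.5, horizon = 15))
  expect_equal(got2, oracle(smooth2, 6.5, 15, 0.001), tolerance = 1e-3)
})

test_that("iAUSC is stable under grid refinement and rises with sigmoid steepness", {
  shat <- ideal_curve(10, steepness = 2)
  s1 <- as.numeric(iausc(shat, 10, horizon = 20, grid_step = 0.01))
  s2 <- as.numeric(iausc(shat, 10, horizon = 20, grid_step = 0.005))
  expect_lt(abs(s1 - s2), 1e-4)

  scores <- sapply(c(1, 10, 100), function(ms) {
    as.numeric(iausc(ideal_curve(10, ms), 10, horizon = 20))
  })
  expect_true(all(diff(scores) > 0))
})

test_that("mAUSC averages per-subject scores over events only", {
  d <- as_survival_data(data.frame(id = c("e1", "c1", "e2"),
                                   time = c(3, 5, 7), event = c(1, 0, 1),
                                   x = 0))
  P <- 10
  curves <- survival_curves(rbind(as.numeric(1:P <= 3),
                                  rep(0.5, P),
                                  as.numeric(1:P <= 7)), ids = d$id)
  m <- mausc(curves, d)
  per <- attr(m, "iausc")
  expect_equal(names(per), c("e1", "e2"))       # censored subject excluded
  expect_equal(as.numeric(m), mean(per))
  expect_gt(as.numeric(m), 0.9)  # near-step curves (linear knot-to-knot fall)

  single <- subset(as.data.frame(d), id == "e1")
  ds <- as_survival_data(single)
  expect_equal(as.numeric(mausc(curves, ds)), unname(per["e1"]))
  cens_only <- as_survival_data(data.frame(id = "c", time = 2, event = 0, x = 0))
  expect_error(mausc(curves, cens_only), "event")
})

test_that("ECE closed forms and a hand-computed two-bin fixture", {
  # predictor that outputs each bin's empirical rate -> ECE 0
  p <- c(rep(0.25, 4), rep(0.75, 4))
  y <- c(1, 0, 0, 0, 1, 1, 1, 0)
  expect_equal(ece(p, y, bins = 2), 0)
  # all predictions 1, all outcomes 0 -> ECE 1
  expect_equal(ece(rep(1, 10), rep(0, 10)), 1)
  # hand-computed: bin1 has p=(0.1,0.3), y=(0,1): gap |0.2-0.5| = 0.3
  #                bin2 has p=(0.8,0.9), y=(1,1): gap |0.85-1| = 0.15
  expect_equal(ece(c(0.1, 0.3, 0.8, 0.9), c(0, 1, 1, 1), bins = 2),
               0.5 * 0.3 + 0.5 * 0.15)
})

test_that("ECE of a perfectly calibrated simulator vanishes at large n", {
  set.seed(62)
  n <- 1e5
  p <- runif(n)
  y <- rbinom(n, 1, p)
  expect_lt(ece(p, y), 0.01)
})
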