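test_that("worked examples: censored and event records replicate as specified", {
  d <- as_survival_data(data.frame(id = c("cens", "evt"), time = c(6, 6),
                                   event = c(0, 1), x = c(1, 2)))
  a <- case_augment(d, horizon = 20)

  cens <- a[a$source_id == "cens", ]
  expect_equal(nrow(cens), 6)
  expect_equal(cens$period, 1:6)
  expect_true(all(cens$label == 1))

  evt <- a[a$source_id == "evt", ]
  expect_equal(nrow(evt), 20)
  expect_equal(evt$label, as.integer(evt$period <= 6))
  expect_equal(sum(evt$label), 6)

  # features copied unchanged to every replicate
  expect_true(all(cens$x == 1) && all(evt$x == 2))
})

test_that("edge cases: horizon capping, sub-period censoring, empty input", {
  d <- as_survival_data(data.frame(id = c("long", "short"),
                                   time = c(25, 0.5), event = c(0, 0),
                                   x = 0))
  a <- case_augment(d, horizon = 20)
  expect_equal(nrow(a[a$source_id == "long", ]), 20)   # capped at P
  expect_true(all(a$label == 1))
  expect_equal(nrow(a[a$source_id == "short", ]), 0)   # no complete period

  empty <- as_survival_data(data.frame(id = character(), time = numeric(),
                                       event = integer(), x = numeric()))
  expect_equal(nrow(case_augment(empty, 10)), 0)

  # an event before one complete period still yields P all-negative rows
  d2 <- as_survival_data(data.frame(id = "e0", time = 0.4, event = 1, x = 0))
  a2 <- case_augment(d2, 5)
  expect_equal(nrow(a2), 5)
  expect_true(all(a2$label == 0))
})

test_that("fractional times are reduced to completed periods", {
  d <- as_survival_data(data.frame(id = c("a", "b"), time = c(6.4, 6.9),
                                   event = c(0, 1), x = 0))
  a <- case_augment(d, 10)
  expect_equal(nrow(a[a$source_id == "a", ]), 6)
  expect_equal(sum(a[a$source_id == "b", "label"]), 6)
})

test_that("validation rejects malformed records by name", {
  expect_error(as_survival_data(data.frame(id = "bad", time = -1, event = 1)),
               "bad")
  expect_error(as_survival_data(data.frame(id = "odd", time = 1, event = 2)),
               "odd")
  expect_error(as_survival_data(data.frame(id = c("d", "d"), time = 1:2,
                                           event = 0)),
               "not unique")
})

test_that("cardinality and labels match the brute-force oracle on random data", {
  set.seed(101)
  for (rep in 1:25) {
    n <- sample(1:50, 1)
    P <- sample(1:25, 1)
    d <- random_survival_data(n, max_time = 30)
    a <- case_augment(d, P)
    o <- brute_force_augment(d, P)
    expect_equal(nrow(a), nrow(o))
    expect_equal(a$source_id, o$source_id)
    expect_equal(a$period, o$period)
    expect_equal(a$label, o$label)
    # closed-form cardinality identity
    fp <- pmin(floor(d$time), P)
    expect_equal(nrow(a), sum(ifelse(d$event == 1, P, fp)))
  }
})

test_that("class ratio equals the empirical positive fraction and has closed-form values", {
  one_event <- as_survival_data(data.frame(id = "e", time = 6, event = 1, x = 0))
  expect_equal(case_class_ratio(one_event, 20), 6 / 20)
  one_cens <- as_survival_data(data.frame(id = "c", time = 6, event = 0, x = 0))
  expect_equal(case_class_ratio(one_cens, 20), 1.0)

  set.seed(7)
  for (rep in 1:25) {
    d <- random_survival_data(sample(2:40, 1), max_time = 25)
    P <- sample(1:25, 1)
    a <- case_augment(d, P)
    if (nrow(a) == 0) {
      expect_error(case_class_ratio(d, P), "undefined")
    } else {
      expect_equal(case_class_ratio(d, P), mean(a$label))
    }
  }
})

test_that("adding a censored record never decreases the positive-row count", {
  set.seed(11)
  d <- random_survival_data(20, max_time = 15)
  P <- 10
  base_pos <- sum(case_augment(d, P)$label)
  extra <- as_survival_data(data.frame(id = "new", time = runif(1, 0, 20),
                                       event = 0, x = 0))
  d2 <- as_survival_data(rbind(as.data.frame(d), as.data.frame(extra)))
  expect_gte(sum(case_augment(d2, P)$label), base_pos)
})

test_that("expand_for_prediction yields P unlabeled rows per record", {
  d <- make_small_data()
  e <- expand_for_prediction(d, 20)
  expect_equal(nrow(e), 20 * nrow(d))
  expect_false("label" %in% names(e))
  for (id in d$id) {
    rows <- e[e$source_id == id, ]
    expect_equal(rows$period, 1:20)
    expect_equal(length(unique(rows$age)), 1)  # features replicated
  }
  e1 <- expand_for_prediction(d, 1)
  expect_equal(e1$period, rep(1, nrow(d)))
})

test_that("attach_survival_features joins curves onto the original table", {
  d <- make_small_data()
  P <- 10
  probs <- matrix(runif(nrow(d) * P), nrow = nrow(d))
  cv <- survival_curves(probs, ids = d$id)
  tab <- attach_survival_features(d, cv)
  expect_equal(dim(tab), c(nrow(d), 1 + 2 + P))  # id + F features + P probs
  expect_equal(tab$id, d$id)
  for (k in seq_len(P)) {
    expect_equal(tab[[paste0("prob_", k)]], unname(probs[, k]))
  }
  # manual 3-subject join as an independent check
  sub <- d[1:3, ]
  manual <- cbind(as.data.frame(sub)[c("id", "age", "sex")],
                  probs[1:3, , drop = FALSE])
  tab3 <- attach_survival_features(
    structure(as.data.frame(d)[1:3, ], features = attr(d, "features"),
              class = c("survival_data", "data.frame")), cv)
  expect_equal(unname(as.matrix(tab3[paste0("prob_", 1:P)])),
               unname(probs[1:3, , drop = FALSE]))

  bad <- survival_curves(probs[1:3, , drop = FALSE], ids = d$id[1:3])
  expect_error(attach_survival_features(d, bad), "p4")
})

test_that("augmented CSV round-trips with the documented column layout", {
  a <- case_augment(make_small_data(), 8)
  path <- withr::local_tempfile(fileext = ".csv")
  write_augmented_csv(a, path)
  back <- utils::read.csv(path)
  expect_equal(names(back)[1:3], c("source_id", "period", "label"))
  expect_equal(nrow(back), nrow(a))
})
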