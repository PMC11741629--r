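# Shared fixtures, built in code.

# Small survival dataset with a mix of events and censorings.
make_small_data <- function() {
  as_survival_data(data.frame(
    id = paste0("p", 1:6),
    time = c(6, 6, 0.5, 25, 3.2, 10),
    event = c(0, 1, 0, 0, 1, 1),
    age = c(50, 61, 45, 70, 38, 55),
    sex = c(0, 1, 1, 0, 0, 1)
  ))
}

# Random survival dataset for property-style loops.
random_survival_data <- function(n, max_time = 30, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  as_survival_data(data.frame(
    id = sprintf("r%04d", seq_len(n)),
    time = stats::runif(n, 0, max_time),
    event = stats::rbinom(n, 1, 0.5),
    x = stats::rnorm(n)
  ))
}

# Independent brute-force oracle for the augmentation operator: enumerates
# rows record by record, period by period, straight from the label rule.
brute_force_augment <- function(data, P) {
  rows <- list()
  for (i in seq_len(nrow(data))) {
    fp <- min(floor(data$time[i]), P)
    n_rep <- if (data$event[i] == 1) P else fp
    if (n_rep == 0) next
    for (tau in seq_len(n_rep)) {
      rows[[length(rows) + 1L]] <- data.frame(
        source_id = data$id[i], period = tau,
        label = as.integer(tau <= fp))
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(source_id = character(), period = integer(),
                      label = integer()))
  }
  do.call(rbind, rows)
}

# Fit a small classifier + calibration on generated data; cached per session
# so several tests can share one fit.
fitted_toy_pipeline <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gen <- generate_survival_data(
      synth_config(n = 400, n_features = 3, horizon = 8,
                   baseline = -2, effects = c(1, 0.5, 0),
                   followup_min = 8, followup_max = 16),
      seed = 42)
    aug <- case_augment(gen$data, 8)
    model <- fit_classifier(case_classifier(nrounds = 60), aug, seed = 42)
    raw <- score_classifier(model, aug)
    map <- fit_abbq(raw, aug$label, bins = 10)
    cache <<- list(gen = gen, aug = aug, model = model, map = map)
    cache
  }
})

# Shared fitted model with one relevant, one irrelevant and one
# switch-on covariate (effect active only after period 5).
importance_fixture <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    P <- 10
    beta <- rbind(x1 = rep(0.9, 2 * P),
                  x2 = rep(0, 2 * P),                      # pure noise
                  x3 = c(rep(0, 5), rep(1.5, 2 * P - 5)))  # activates after 5
    cfg <- synth_config(n = 2400, n_features = 3, horizon = P,
                        baseline = -2.6, effects = beta,
                        followup_min = 2 * P, followup_max = 2 * P + 1)
    gen <- generate_survival_data(cfg, seed = 71)
    # fit on one half, attribute on the held-out half so the survivor-set
    # means are not inflated by training-set memorization
    train <- gen$data[1:1200, ]
    attr(train, "features") <- attr(gen$data, "features")
    class(train) <- c("survival_data", "data.frame")
    test <- gen$data[1201:2400, ]
    attr(test, "features") <- attr(gen$data, "features")
    class(test) <- c("survival_data", "data.frame")
    aug <- case_augment(train, P)
    model <- fit_classifier(case_classifier(nrounds = 120), aug, seed = 71)
    prof <- temporal_importance(model, test, P, seed = 71)
    cache <<- list(gen = gen, data = test, model = model, prof = prof, P = P)
    cache
  }
})

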