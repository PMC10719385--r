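# Trial splitting, window sampling and z-scoring: leakage guards, interval
# arithmetic and train-only moments.

test_that("stratified trial folds have the documented arithmetic", {
  trials <- data.frame(trial = 1:90,
                       label = rep(c("DII", "DV"), each = 45))
  plan <- split_trials(trials, k = 5, seed = 3L)
  for (f in plan$folds) {
    te <- trials[trials$trial %in% f$test, ]
    expect_equal(sum(te$label == "DII"), 9)
    expect_equal(sum(te$label == "DV"), 9)
    expect_length(intersect(f$train, f$test), 0)
    expect_setequal(c(f$train, f$test), 1:90)
  }
  # each trial tests exactly once
  all_test <- unlist(lapply(plan$folds, `[[`, "test"))
  expect_setequal(all_test, 1:90)
  expect_equal(anyDuplicated(all_test), 0L)
  # determinism and degenerate k
  expect_identical(split_trials(trials, 5, seed = 3L)$folds, plan$folds)
  expect_error(split_trials(trials, 1, seed = 3L), "cannot cross-validate")
  expect_error(split_trials(trials[c(1:3, 46:48), ], 5, seed = 1L),
               "fewer trials")
})

test_that("movement windows stay in the 0-300 ms interval with 20 samples", {
  envexp <- get_small_envexp("EMG")
  pos <- sample_window_positions(envexp, "DII", 200,
                                 trials = envexp$trials$trial, seed = 4L)
  expect_true(all(pos$win == 20))
  # window start offset relative to the owning trial's onset in {0..200} ms
  on <- envexp$trials$onset[match(pos$owner_trial, envexp$trials$trial)]
  off_ms <- (pos$start / envexp$fs - on) * 1000
  expect_true(all(off_ms >= 0 - 1e-9))
  expect_true(all(off_ms <= 200 + 1e-9))
  X <- extract_windows(envexp, pos)
  expect_equal(dim(X), c(200L, 20L, 4L))
})

test_that("no-movement windows avoid movement intervals and trial boundaries", {
  envexp <- get_small_envexp("EMG")
  pos <- sample_window_positions(envexp, "NoMove", 400,
                                 trials = envexp$trials$trial, seed = 5L)
  fs <- envexp$fs
  tl <- envexp$trial_len
  for (i in seq_len(nrow(pos))) {
    t0 <- pos$start[i] / fs
    t1 <- (pos$start[i] + pos$win[i]) / fs
    ev <- envexp$events[[pos$session[i]]]
    # no overlap with any movement interval
    expect_true(all(t1 <= ev$onset | t0 >= ev$onset + ev$duration))
    # fully inside one physical trial
    expect_equal(floor(t0 / tl), floor((t1 - 1 / fs) / tl))
  }
  # drawn from trials of both labels in (near) equal proportion
  owner_lab <- envexp$trials$label[match(pos$owner_trial,
                                         envexp$trials$trial)]
  expect_equal(as.vector(abs(diff(as.vector(table(owner_lab))))), 0)
})

test_that("fold datasets have the nested 500/100 sampling sizes and no trial leakage", {
  envexp <- get_small_envexp("MMG")
  plan <- split_trials(envexp$trials, k = 5, seed = 7L)
  ds <- build_fold_dataset(envexp, plan$folds[[1]], n_train = 500,
                           n_test = 100, seed = 8L)
  expect_equal(dim(ds$train$X), c(1500L, 20L, 8L))
  expect_equal(dim(ds$test$X), c(300L, 20L, 8L))
  expect_equal(as.vector(table(ds$train$y)), rep(500L, 3))
  expect_equal(as.vector(table(ds$test$y)), rep(100L, 3))
  expect_length(intersect(ds$train$positions$owner_trial,
                          ds$test$positions$owner_trial), 0)
  expect_true(all(ds$train$positions$owner_trial %in% plan$folds[[1]]$train))
  expect_true(all(ds$test$positions$owner_trial %in% plan$folds[[1]]$test))
})

test_that("z-scoring moments come from the train split only", {
  set.seed(10)
  Xtr <- array(stats::rnorm(200 * 5 * 3, mean = 2, sd = 3), c(200, 5, 3))
  mo <- zscore_fit(Xtr)
  Z <- zscore_apply(Xtr, mo)
  expect_lt(max(abs(apply(Z, c(2, 3), mean))), 1e-10)
  expect_equal(apply(Z, c(2, 3), stats::sd),
               matrix(1, 5, 3), tolerance = 1e-10)
  # a shifted test set must NOT come out centred (no refitting)
  Xte <- Xtr + 5
  Zte <- zscore_apply(Xte, mo)
  expect_gt(min(apply(Zte, c(2, 3), mean)), 1)
  # constant feature -> informative error
  Xbad <- Xtr; Xbad[, 2, 3] <- 7
  expect_error(zscore_fit(Xbad), "t = 2, channel = 3")
})

test_that("window sampling validates intervals and eligibility", {
  envexp <- get_small_envexp("EMG")
  expect_error(sample_window_positions(envexp, "DII", 10,
                                       trials = envexp$trials$trial,
                                       interval = c(0, 50), seed = 1L),
               "interval")
  expect_error(sample_window_positions(envexp, "DII", 10, trials = integer(0),
                                       seed = 1L),
               "no eligible trials")
  # determinism
  p1 <- sample_window_positions(envexp, "DV", 50,
                                trials = envexp$trials$trial, seed = 2L)
  p2 <- sample_window_positions(envexp, "DV", 50,
                                trials = envexp$trials$trial, seed = 2L)
  expect_identical(p1, p2)
})
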