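# Synthetic generator: protocol structure, determinism, spectral content
# and ground-truth gain recovery.

test_that("event tables follow the cued-trial protocol", {
  cfg <- generator_config()
  sess <- generate_session(cfg, rep("DII", 30), seed = 2L)
  ev <- sess$events
  expect_equal(nrow(ev), 30)
  expect_equal(ev$onset, seq(0, by = 5, length.out = 30) + cfg$cue_offset)
  expect_true(all(ev$label == "DII"))
  expect_true(all(ev$duration == 1))
  expect_equal(nrow(sess$emg$data), 4)
  expect_equal(nrow(sess$mmg$data), 8)
  expect_equal(ncol(sess$emg$data), round(30 * 5 * cfg$fs_raw))
  expect_false(any(!is.finite(sess$emg$data)))
})

test_that("session plan: all-DII, all-DV, alternating; seeds separate structure from noise", {
  cfg <- small_generator_config()
  e1 <- generate_experiment(cfg, seed = 5L)
  labs <- lapply(e1$sessions, function(s) s$events$label)
  expect_true(all(labs[[1]] == "DII"))
  expect_true(all(labs[[2]] == "DV"))
  expect_equal(labs[[3]], rep(c("DII", "DV"), 5))
  # same seed -> bit-identical; different seed -> same events, new noise
  e2 <- generate_experiment(cfg, seed = 5L)
  expect_identical(e1$sessions[[1]]$mmg$data, e2$sessions[[1]]$mmg$data)
  e3 <- generate_experiment(cfg, seed = 6L)
  expect_identical(e1$sessions[[3]]$events, e3$sessions[[3]]$events)
  expect_false(identical(e1$sessions[[1]]$mmg$data,
                         e3$sessions[[1]]$mmg$data))
})

test_that("generator validates labels, SNR and plan", {
  cfg <- small_generator_config()
  expect_error(generate_session(cfg, rep("DIII", 10), seed = 1L), "unknown label")
  expect_error(generate_session(cfg, rep("DII", 3), seed = 1L), "entries")
  expect_error(generator_config(snr_emg = 0), "positive")
  expect_error(generator_config(gain_emg = -default_gain_matrix("EMG")),
               "non-negative")
  bad <- small_generator_config()
  bad$session_plan <- bad$session_plan[1:2]
  expect_error(generate_experiment(bad, seed = 1L), "3 entries")
})

test_that("zero gain leaves pure background with a flat movement-locked envelope", {
  cfg <- small_generator_config(gain_emg = matrix(0, 4, 2,
                                                  dimnames = list(NULL, c("DII", "DV"))),
                                gain_mmg = matrix(0, 8, 2,
                                                  dimnames = list(NULL, c("DII", "DV"))))
  sess <- generate_session(cfg, rep("DII", 10), seed = 31L)
  env <- preprocess_recording(sess$emg)
  on <- round(sess$events$onset * 200)
  move <- unlist(lapply(on, function(i) env$data[1, (i + 1):(i + 200)]))
  rest <- unlist(lapply(on, function(i) env$data[1, (i + 401):(i + 800)]))
  expect_equal(mean(move) / mean(rest), 1, tolerance = 0.1)
})

test_that("movement bursts are band-limited to 25-100 Hz", {
  # same seed with zero vs default gain isolates the burst component
  zero <- small_generator_config(
    gain_emg = matrix(0, 4, 2, dimnames = list(NULL, c("DII", "DV"))),
    gain_mmg = matrix(0, 8, 2, dimnames = list(NULL, c("DII", "DV"))))
  full <- small_generator_config()
  s0 <- generate_session(zero, rep("DV", 10), seed = 13L)
  s1 <- generate_session(full, rep("DV", 10), seed = 13L)
  burst <- s1$emg$data[2, ] - s0$emg$data[2, ]
  spec <- stats::spec.pgram(stats::ts(burst, frequency = full$fs_raw),
                            taper = 0.1, plot = FALSE)
  inband <- spec$freq >= 15 & spec$freq <= 120
  expect_lt(sum(spec$spec[!inband]) / sum(spec$spec), 0.05)
})

test_that("envelope transient peaks within the movement window and subsides", {
  envexp <- get_small_envexp("EMG")
  env <- envexp$sessions[[1]]  # all-DII session
  on <- round(envexp$events[[1]]$onset * envexp$fs)
  for (ch in 1:4) {
    seg <- sapply(on, function(i) env$data[ch, (i - 59):(i + 400)])
    m <- rowMeans(seg)
    base <- mean(m[1:50])
    expect_gt(max(m[61:260]), 1.5 * base)          # peak inside 0-1 s
    expect_equal(which.max(m) >= 61 && which.max(m) <= 260, TRUE)
    expect_lt(abs(mean(m[441:460]) - base) / base, 0.35)  # back near baseline by +2 s
  }
})

test_that("EMG/MMG SNR ordering shows up in movement-to-rest envelope ratios", {
  cfg <- small_generator_config(snr_emg = 5, snr_mmg = 0.5)
  exp1 <- generate_experiment(cfg, seed = 41L)
  ratio <- function(modality) {
    envexp <- preprocess_modality(exp1, modality)
    r <- c()
    for (s in 1:3) {
      env <- envexp$sessions[[s]]$data
      on <- round(envexp$events[[s]]$onset * 200)
      move <- unlist(lapply(on, function(i) env[, (i + 1):(i + 200)]))
      rest <- unlist(lapply(on, function(i) env[, (i + 501):(i + 800)]))
      r <- c(r, sqrt(mean(move^2)) / sqrt(mean(rest^2)))
    }
    mean(r)
  }
  expect_gt(ratio("EMG"), ratio("MMG"))
})

test_that("ground-truth gain ordering is recoverable from movement envelopes", {
  envexp <- get_small_envexp("MMG")
  cfg <- get_small_experiment()$config
  for (lab in c("DII", "DV")) {
    gains <- cfg$gain_mmg[, lab]
    contrast <- numeric(8)
    for (s in 1:3) {
      ev <- envexp$events[[s]]
      on <- round(ev$onset[ev$label == lab] * envexp$fs)
      if (!length(on)) next
      env <- envexp$sessions[[s]]$data
      move <- do.call(cbind, lapply(on, function(i) env[, (i + 1):(i + 200)]))
      rest <- do.call(cbind, lapply(on, function(i) env[, (i + 501):(i + 800)]))
      contrast <- contrast + rowMeans(move) / rowMeans(rest)
    }
    expect_gte(stats::cor(gains, contrast, method = "spearman"), 0.9)
  }
})
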