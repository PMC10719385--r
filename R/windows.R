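# Window sampling and dataset construction.
#
# Movement-class windows (100 ms) are drawn 0-300 ms after each movement
# onset; no-movement windows from -1500-0 ms relative to onset. Splits are
# made at the trial level (stratified), never at the window level, so that
# within-trial autocorrelation cannot leak between train and test. A window
# is owned by the physical trial that contains it and must lie entirely
# inside that trial; the first and last 0.5 s of each session are excluded.

#' Stratified k-fold split over trials
#'
#' Partitions trials into k folds preserving class proportions; each trial
#' appears in exactly one test fold. Deterministic given the seed.
#'
#' @param trials trial table (columns `trial`, `label`), e.g.
#'   `envexp$trials`.
#' @param k number of folds (>= 2).
#' @param seed integer seed.
#' @return object of class `fold_plan`: list with `k`, `seed` and `folds`,
#'   each fold a list of `train` and `test` global trial ids.
#' @export
split_trials <- function(trials, k = 5L, seed = 1L) {
  k <- as.integer(k)
  if (k < 2L) stopf("k must be >= 2 (cannot cross-validate with k = %d)", k)
  labs <- unique(trials$label)
  counts <- table(trials$label)
  if (any(counts < k))
    stopf("fewer trials than folds for class %s",
          names(counts)[which.min(counts)])
  assign_fold <- integer(nrow(trials))
  with_seed(derive_seed(seed, 202L), {
    for (lb in labs) {
      idx <- which(trials$label == lb)
      idx <- sample(idx)
      assign_fold[idx] <- rep_len(seq_len(k), length(idx))
    }
  })
  folds <- lapply(seq_len(k), function(i) {
    list(train = trials$trial[assign_fold != i],
         test = trials$trial[assign_fold == i])
  })
  structure(list(k = k, seed = seed, folds = folds), class = "fold_plan")
}

# Enumerate admissible window start samples (0-based, in envelope samples)
# for a class. Movement classes draw from their own events; NoMove draws
# relative to every onset. Constraints: the window lies inside
# [onset+interval[1], onset+interval[2]], inside a single physical trial,
# and clear of the session-edge guard.
window_candidates <- function(envexp, label,
                              interval = NULL, win_ms = 100,
                              edge_guard_s = 0.5) {
  fs <- envexp$fs
  tw <- round(win_ms / 1000 * fs)
  if (is.null(interval))
    interval <- if (label == "NoMove") c(-1500, 0) else c(0, 300)
  a <- interval[1] / 1000
  b <- interval[2] / 1000
  if ((b - a) * 1000 < win_ms) stopf("interval shorter than the window")
  trial_len <- envexp$trial_len
  samp_per_trial <- round(trial_len * fs)
  out <- list()
  for (s in seq_along(envexp$events)) {
    ev <- envexp$events[[s]]
    rows <- if (label == "NoMove") seq_len(nrow(ev)) else which(ev$label == label)
    if (!length(rows)) next
    n_samp <- ncol(envexp$sessions[[s]]$data)
    guard_lo <- ceiling(edge_guard_s * fs)
    guard_hi <- n_samp - ceiling(edge_guard_s * fs) - tw
    sess_trials <- envexp$trials[envexp$trials$session == s, ]
    for (r in rows) {
      onset <- ev$onset[r]
      i_min <- max(ceiling((onset + a) * fs), guard_lo)
      i_max <- min(floor((onset + b) * fs) - tw, guard_hi)
      if (i_max < i_min) next
      starts <- i_min:i_max
      # window must not straddle a trial boundary
      ok <- (starts %/% samp_per_trial) == ((starts + tw - 1L) %/% samp_per_trial)
      starts <- starts[ok]
      if (!length(starts)) next
      owner_in_session <- starts %/% samp_per_trial + 1L
      keep <- owner_in_session >= 1L & owner_in_session <= nrow(sess_trials)
      starts <- starts[keep]
      owner_in_session <- owner_in_session[keep]
      if (!length(starts)) next
      out[[length(out) + 1L]] <- data.frame(
        session = s,
        start = starts,
        owner_trial = sess_trials$trial[owner_in_session],
        owner_label = sess_trials$label[owner_in_session],
        event_label = ev$label[r],
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(out))
    stopf("no admissible windows for class %s", label)
  res <- do.call(rbind, out)
  res$label <- label
  res$win <- tw
  res
}

#' Sample window positions for one class
#'
#' Start positions are drawn uniformly with replacement over all admissible
#' (trial, offset) pairs whose owner trial is in `trials`. No-movement
#' draws are stratified equally over owner trials labelled DII and DV.
#'
#' @param envexp an `envelope_experiment`.
#' @param label class to sample (`"DII"`, `"DV"`, `"NoMove"`).
#' @param n number of windows.
#' @param trials global trial ids the windows may come from.
#' @param interval `(start_ms, end_ms)` relative to movement onset; default
#'   `(0, 300)` for movement classes, `(-1500, 0)` for no-movement.
#' @param win_ms window length in ms.
#' @param seed integer seed.
#' @return data.frame of sampled positions (`session`, `start`,
#'   `owner_trial`, `label`, `win`).
#' @export
sample_window_positions <- function(envexp, label, n, trials,
                                    interval = NULL, win_ms = 100,
                                    seed = 1L) {
  if (n < 1) stopf("n must be >= 1")
  cand <- window_candidates(envexp, label, interval, win_ms)
  cand <- cand[cand$owner_trial %in% trials, ]
  if (!nrow(cand)) stopf("no eligible trials for class %s", label)
  with_seed(derive_seed(seed, 303L), {
    if (label == "NoMove") {
      pools <- split(seq_len(nrow(cand)), cand$owner_label)
      if (length(pools) < 2L) {
        pick <- sample(seq_len(nrow(cand)), n, replace = TRUE)
      } else {
        n_half <- c(ceiling(n / 2), floor(n / 2))
        pick <- c(sample(pools[[1]], n_half[1], replace = TRUE),
                  sample(pools[[2]], n_half[2], replace = TRUE))
      }
    } else {
      pick <- sample(seq_len(nrow(cand)), n, replace = TRUE)
    }
    cand[pick, c("session", "start", "owner_trial", "label", "win")]
  })
}

#' Extract window tensors from an envelope experiment
#'
#' @param envexp an `envelope_experiment`.
#' @param positions data.frame from [sample_window_positions()]. Positions
#'   sampled on one modality can be extracted from the other, giving
#'   time-aligned datasets for both sensor types.
#' @return array `N x T x C`.
#' @export
extract_windows <- function(envexp, positions) {
  tw <- positions$win[1]
  n_ch <- nrow(envexp$channels)
  X <- array(0, c(nrow(positions), tw, n_ch))
  for (i in seq_len(nrow(positions))) {
    env <- envexp$sessions[[positions$session[i]]]$data
    idx <- (positions$start[i] + 1L):(positions$start[i] + tw)
    X[i, , ] <- t(env[, idx, drop = FALSE])
  }
  X
}

#' Fit z-scoring moments on a training tensor
#'
#' Moments are computed over the window (first) dimension only, one mean
#' and standard deviation per `(time, channel)` feature, on the train split
#' alone; they are then applied unchanged to any other split.
#'
#' @param X array `N x T x C`.
#' @return list with `mean` and `sd` matrices (`T x C`).
#' @export
zscore_fit <- function(X) {
  if (length(dim(X)) != 3 || dim(X)[1] < 2) stopf("need an N x T x C tensor with N >= 2")
  mu <- apply(X, c(2, 3), mean)
  sd_ <- apply(X, c(2, 3), stats::sd)
  if (any(sd_ == 0)) {
    bad <- which(sd_ == 0, arr.ind = TRUE)[1, ]
    stopf("zero standard deviation in feature (t = %d, channel = %d)",
          bad[1], bad[2])
  }
  list(mean = mu, sd = sd_)
}

#' Apply fitted z-scoring moments
#'
#' @param X array `N x T x C`.
#' @param moments list from [zscore_fit()].
#' @return standardized array, same shape.
#' @export
zscore_apply <- function(X, moments) {
  d <- dim(X)
  mu <- aperm(array(moments$mean, c(d[2], d[3], d[1])), c(3, 1, 2))
  sd_ <- aperm(array(moments$sd, c(d[2], d[3], d[1])), c(3, 1, 2))
  (X - mu) / sd_
}

#' Build the z-scored train/test dataset for one fold
#'
#' Samples `n_train` windows per class from the fold's training trials and
#' `n_test` per class from its test trials (defaults 500/100, the nested
#' sampling scheme), extracts the envelope tensors, and z-scores both
#' splits with moments fitted on the train split only.
#'
#' @param envexp an `envelope_experiment`.
#' @param fold one element of a [split_trials()] plan.
#' @param n_train,n_test windows per class and split.
#' @param classes label set; the last entry is conventionally `"NoMove"`.
#' @param win_ms window length in ms.
#' @param seed integer seed.
#' @param positions optional precomputed positions (list with `train`,
#'   `test` data.frames) to reuse across modalities.
#' @return list `train`/`test` (each `X`, `y`, `positions`), `moments`,
#'   `classes`.
#' @export
build_fold_dataset <- function(envexp, fold, n_train = 500L, n_test = 100L,
                               classes = ALL_CLASSES, win_ms = 100,
                               seed = 1L, positions = NULL) {
  if (is.null(positions)) {
    positions <- list(
      train = do.call(rbind, lapply(seq_along(classes), function(ci)
        sample_window_positions(envexp, classes[ci], n_train, fold$train,
                                win_ms = win_ms,
                                seed = derive_seed(seed, 11L, ci)))),
      test = do.call(rbind, lapply(seq_along(classes), function(ci)
        sample_window_positions(envexp, classes[ci], n_test, fold$test,
                                win_ms = win_ms,
                                seed = derive_seed(seed, 12L, ci))))
    )
  }
  X_tr <- extract_windows(envexp, positions$train)
  X_te <- extract_windows(envexp, positions$test)
  y_tr <- factor(positions$train$label, levels = classes)
  y_te <- factor(positions$test$label, levels = classes)
  moments <- zscore_fit(X_tr)
  list(
    train = list(X = zscore_apply(X_tr, moments), y = y_tr,
                 positions = positions$train),
    test = list(X = zscore_apply(X_te, moments), y = y_te,
                positions = positions$test),
    moments = moments,
    classes = classes
  )
}
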