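# Synthetic paired MMG/EMG experiment generator.
#
# Emulates a cued finger-flexion protocol: 3 sessions x 30 trials of 5 s,
# one 1 s movement-evoked burst of 25-100 Hz activity per trial, with
# class-dependent spatial gains (radial-side channels stronger for index
# finger DII, ulnar-side channels stronger for little finger DV), 1/f
# background, 50 Hz line interference, white sensor noise, and a lower
# in-band SNR for MMG than for EMG.

MOVE_CLASSES <- c("DII", "DV")
ALL_CLASSES <- c("DII", "DV", "NoMove")

#' Default per-channel, per-class burst gain matrix
#'
#' Encodes the spatial prior used as ground truth for importance-recovery
#' tests: ulnar-side channels (channels 2 and 4 of each modality; OPM
#' sensors 2 and 4) respond preferentially to little-finger (DV) flexion,
#' radial-side channels (1 and 3) to index-finger (DII) flexion. For the
#' biaxial magnetometers the skin-perpendicular Z axis is weighted above the
#' Y axis.
#'
#' @param modality `"EMG"` (4 bipolar channels) or `"MMG"` (4 sensors x
#'   axes Y, Z = 8 channels).
#' @return numeric matrix `channels x 2` with columns `DII`, `DV`, row
#'   names matching the channel table of [channel_table()].
#' @export
default_gain_matrix <- function(modality = c("EMG", "MMG")) {
  modality <- match.arg(modality)
  pref <- 1.0    # gain toward the side's preferred class
  nonpref <- 0.35
  if (modality == "EMG") {
    # channels 1,3 radial; 2,4 ulnar
    g <- rbind(
      c(pref, nonpref),     # EMG-1 radial
      c(nonpref, pref),     # EMG-2 ulnar
      c(pref, nonpref),     # EMG-3 radial
      c(nonpref, pref)      # EMG-4 ulnar
    )
    rownames(g) <- paste0("EMG-", 1:4)
  } else {
    axis_w <- c(Y = 0.6, Z = 1.0)
    rows <- list()
    for (s in 1:4) {
      side_pref <- if (s %% 2 == 0) c(nonpref, pref) else c(pref, nonpref)
      for (ax in c("Y", "Z")) {
        rows[[paste0("OPM-", s, ax)]] <- side_pref * axis_w[[ax]]
      }
    }
    g <- do.call(rbind, rows)
  }
  colnames(g) <- MOVE_CLASSES
  g
}

#' Channel metadata table for one modality
#'
#' @param modality `"EMG"` or `"MMG"`.
#' @param n number of channels (4 EMG, 8 MMG by default).
#' @return data.frame with columns `name`, `modality`, `axis` (`Y`/`Z` for
#'   MMG, `none` for EMG), `side` (`radial`/`ulnar`).
#' @export
channel_table <- function(modality = c("EMG", "MMG"), n = NULL) {
  modality <- match.arg(modality)
  if (modality == "EMG") {
    n <- n %||% 4L
    data.frame(
      name = paste0("EMG-", seq_len(n)),
      modality = "EMG",
      axis = "none",
      side = ifelse(seq_len(n) %% 2 == 0, "ulnar", "radial"),
      stringsAsFactors = FALSE
    )
  } else {
    n <- n %||% 8L
    stopifnot(n %% 2 == 0)
    sensor <- rep(seq_len(n %/% 2), each = 2)
    axis <- rep(c("Y", "Z"), n %/% 2)
    data.frame(
      name = paste0("OPM-", sensor, axis),
      modality = "MMG",
      axis = axis,
      side = ifelse(sensor %% 2 == 0, "ulnar", "radial"),
      stringsAsFactors = FALSE
    )
  }
}

#' Configuration for the synthetic MMG/EMG generator
#'
#' Defaults reproduce the emulated acquisition protocol: 2343.8 Hz sampling,
#' 5 s trials, 1 s movements, 30 trials per session, three sessions
#' (all-DII, all-DV, alternating), 4 EMG + 8 MMG channels.
#'
#' @param fs_raw sampling rate in Hz.
#' @param trial_len trial length in seconds.
#' @param move_len movement duration in seconds.
#' @param n_trials_per_session trials per session.
#' @param session_plan list of per-session class sequences; default is
#'   all-DII, all-DV, alternating DII/DV.
#' @param cue_offset cue-to-movement-onset latency in seconds (reaction
#'   time; movement onset of trial t is at `(t-1)*trial_len + cue_offset`).
#' @param emg_channels,mmg_channels channel counts per modality.
#' @param gain_emg,gain_mmg non-negative `channels x 2` burst gain matrices
#'   (columns DII, DV); see [default_gain_matrix()].
#' @param burst_taper Tukey taper fraction of the movement burst envelope
#'   (cosine on/offset ramps of `taper/2 * move_len` each).
#' @param snr_emg,snr_mmg burst RMS relative to the background RMS in the
#'   25-100 Hz band, for a unit-gain channel.
#' @param line_amp amplitude of the 50 Hz line component.
#' @param pink_exponent spectral exponent of the 1/f background.
#' @param pink_amp,white_amp RMS of the 1/f and white background components.
#' @param seed default generator seed (can be overridden per call).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(fs_raw = 2343.8,
                             trial_len = 5,
                             move_len = 1,
                             n_trials_per_session = 30L,
                             session_plan = NULL,
                             cue_offset = 0.3,
                             emg_channels = 4L,
                             mmg_channels = 8L,
                             gain_emg = default_gain_matrix("EMG"),
                             gain_mmg = default_gain_matrix("MMG"),
                             burst_taper = 0.3,
                             snr_emg = 1.0,
                             snr_mmg = 0.6,
                             line_amp = 1.0,
                             pink_exponent = 1.0,
                             pink_amp = 1.0,
                             white_amp = 0.3,
                             seed = 1L) {
  n <- as.integer(n_trials_per_session)
  if (is.null(session_plan)) {
    session_plan <- list(
      rep("DII", n),
      rep("DV", n),
      rep(MOVE_CLASSES, length.out = n)
    )
  }
  cfg <- list(
    fs_raw = fs_raw, trial_len = trial_len, move_len = move_len,
    n_trials_per_session = n, session_plan = session_plan,
    cue_offset = cue_offset, burst_taper = burst_taper,
    emg_channels = as.integer(emg_channels),
    mmg_channels = as.integer(mmg_channels),
    gain_emg = gain_emg, gain_mmg = gain_mmg,
    snr_emg = snr_emg, snr_mmg = snr_mmg,
    line_amp = line_amp, pink_exponent = pink_exponent,
    pink_amp = pink_amp, white_amp = white_amp,
    seed = as.integer(seed)
  )
  class(cfg) <- "generator_config"
  validate_generator_config(cfg)
  cfg
}

validate_generator_config <- function(cfg) {
  if (cfg$fs_raw <= 200) stopf("fs_raw must exceed 2 x 100 Hz")
  if (cfg$move_len >= cfg$trial_len) stopf("move_len must be < trial_len")
  if (cfg$snr_emg <= 0 || cfg$snr_mmg <= 0) stopf("SNR values must be positive")
  if (any(cfg$gain_emg < 0) || any(cfg$gain_mmg < 0))
    stopf("gain matrices must be non-negative")
  if (cfg$n_trials_per_session < 1L || cfg$emg_channels < 1L ||
      cfg$mmg_channels < 1L)
    stopf("all counts must be >= 1")
  if (nrow(cfg$gain_emg) != cfg$emg_channels ||
      nrow(cfg$gain_mmg) != cfg$mmg_channels)
    stopf("gain matrix rows must match channel counts")
  if (cfg$cue_offset < 0 ||
      cfg$cue_offset + cfg$move_len > cfg$trial_len)
    stopf("movement must fit inside the trial")
  invisible(cfg)
}

# 1/f^expo Gaussian noise with unit RMS, synthesized in the frequency
# domain at a 5-smooth padded length and truncated.
pink_noise <- function(n, exponent = 1) {
  nf <- next_fast_len(n)
  half <- nf %/% 2
  f <- seq_len(half)  # bin index; absolute frequency scale is irrelevant
  amp <- f^(-exponent / 2)
  ph <- stats::runif(half, 0, 2 * pi)
  spec <- complex(real = amp * cos(ph), imaginary = amp * sin(ph))
  full <- complex(length.out = nf)
  full[2:(half + 1)] <- spec
  full[nf:(nf - half + 2)] <- Conj(spec[1:(half - 1)])
  x <- Re(stats::fft(full, inverse = TRUE)) / nf
  x <- x[seq_len(n)]
  x / rms(x)
}

hann_window <- function(n) {
  k <- seq_len(n) - 1
  0.5 * (1 - cos(2 * pi * k / (n - 1)))
}

# Tapered-cosine (Tukey) window: cosine ramps over `taper/2` of the length
# at each end, flat in between. Muscle bursts switch on over tens of
# milliseconds, much faster than the movement itself; the taper keeps the
# on/offset smooth while the burst is at full strength during the
# post-onset sampling interval.
tukey_window <- function(n, taper = 0.3) {
  if (taper <= 0) return(rep(1, n))
  if (taper >= 1) return(hann_window(n))
  k <- (seq_len(n) - 1) / (n - 1)
  w <- rep(1, n)
  lo <- k < taper / 2
  hi <- k > 1 - taper / 2
  w[lo] <- 0.5 * (1 + cos(pi * (2 * k[lo] / taper - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - k[hi]) / taper - 1)))
  w
}

new_recording <- function(data, fs, channels, session_id) {
  stopifnot(nrow(data) == nrow(channels))
  structure(
    list(data = data, fs = fs, channels = channels, session_id = session_id),
    class = "recording"
  )
}

#' @export
print.recording <- function(x, ...) {
  cat(sprintf("<recording> session %s: %d channels (%s) x %d samples @ %.1f Hz\n",
              x$session_id, nrow(x$data), x$channels$modality[1],
              ncol(x$data), x$fs))
  invisible(x)
}

new_event_table <- function(onset, duration, label, rec_len_s) {
  stopifnot(all(diff(onset) > 0), all(onset + duration <= rec_len_s + 1e-9),
            all(label %in% MOVE_CLASSES))
  data.frame(onset = onset, duration = duration, label = label,
             stringsAsFactors = FALSE)
}

# Simulate the background process for one modality: unit-scale 1/f + white
# noise + 50 Hz line with a random phase per channel.
simulate_background <- function(n_ch, n, fs, cfg) {
  bg <- matrix(0, n_ch, n)
  tt <- (seq_len(n) - 1) / fs
  for (ch in seq_len(n_ch)) {
    bg[ch, ] <- cfg$pink_amp * pink_noise(n, cfg$pink_exponent) +
      cfg$white_amp * stats::rnorm(n) +
      cfg$line_amp * sin(2 * pi * 50 * tt + stats::runif(1, 0, 2 * pi))
  }
  bg
}

# Add one movement burst per trial: band-limited (25-100 Hz) Gaussian noise
# under a raised-cosine (Hann) 1 s envelope, scaled so that the burst RMS
# at gain 1 equals `snr` times the channel's background RMS in the same
# band.
add_bursts <- function(data, fs, cfg, onsets, labels, gain, snr) {
  n_ch <- nrow(data)
  n_mv <- round(cfg$move_len * fs)
  env <- tukey_window(n_mv, cfg$burst_taper)
  band_rms <- apply(bandpass_filter(data, fs, 25, 100), 1, rms)
  for (i in seq_along(onsets)) {
    i0 <- round(onsets[i] * fs) + 1L
    idx <- i0:(i0 + n_mv - 1L)
    carrier <- bandpass_filter(matrix(stats::rnorm(n_ch * n_mv), n_ch, n_mv),
                               fs, 25, 100)
    carrier <- carrier / apply(carrier, 1, rms)
    amp <- gain[, labels[i]] * snr * band_rms
    data[, idx] <- data[, idx] + (amp * carrier) *
      matrix(env, n_ch, n_mv, byrow = TRUE)
  }
  data
}

#' Generate one synthetic recording session
#'
#' Produces time-aligned EMG and MMG recordings plus the event table for a
#' single cued session. Each trial carries one movement burst starting
#' `cue_offset` seconds after the trial's cue, superposed on 1/f background,
#' 50 Hz line interference and white sensor noise. Identical seeds give
#' bit-identical output.
#'
#' @param config a [generator_config()].
#' @param class_sequence character vector of per-trial labels
#'   (`"DII"`/`"DV"`), length `n_trials_per_session`.
#' @param seed integer seed.
#' @param session_id identifier stored in the recordings.
#' @return list with elements `emg`, `mmg` (class `recording`) and `events`
#'   (data.frame `onset`, `duration`, `label`).
#' @export
generate_session <- function(config, class_sequence,
                             seed = config$seed, session_id = 1L) {
  validate_generator_config(config)
  if (length(class_sequence) != config$n_trials_per_session)
    stopf("class_sequence must have %d entries", config$n_trials_per_session)
  if (!all(class_sequence %in% MOVE_CLASSES))
    stopf("unknown label(s) in class_sequence: %s",
          paste(setdiff(class_sequence, MOVE_CLASSES), collapse = ", "))
  fs <- config$fs_raw
  n_trial <- round(config$trial_len * fs)
  n <- n_trial * config$n_trials_per_session
  onsets <- (seq_along(class_sequence) - 1) * config$trial_len +
    config$cue_offset
  with_seed(seed, {
    emg <- simulate_background(config$emg_channels, n, fs, config)
    emg <- add_bursts(emg, fs, config, onsets, class_sequence,
                      config$gain_emg, config$snr_emg)
    mmg <- simulate_background(config$mmg_channels, n, fs, config)
    mmg <- add_bursts(mmg, fs, config, onsets, class_sequence,
                      config$gain_mmg, config$snr_mmg)
    list(
      emg = new_recording(emg, fs, channel_table("EMG", config$emg_channels),
                          session_id),
      mmg = new_recording(mmg, fs, channel_table("MMG", config$mmg_channels),
                          session_id),
      events = new_event_table(onsets, rep(config$move_len,
                                           length(onsets)),
                               class_sequence,
                               n / fs)
    )
  })
}

#' Generate the full three-session experiment
#'
#' Sessions follow `config$session_plan` (default: all-DII, all-DV,
#' alternating). Per-session seeds are derived deterministically from the
#' master seed, so the same seed reproduces the experiment exactly while
#' the event structure depends only on the plan.
#'
#' @param config a [generator_config()].
#' @param seed master seed.
#' @return object of class `mmg_experiment`: list of session triples.
#' @export
generate_experiment <- function(config, seed = config$seed) {
  if (length(config$session_plan) != 3L)
    stopf("session_plan must have 3 entries")
  sessions <- lapply(seq_along(config$session_plan), function(s) {
    generate_session(config, config$session_plan[[s]],
                     seed = derive_seed(seed, 101L, s), session_id = s)
  })
  structure(list(sessions = sessions, config = config, seed = seed),
            class = "mmg_experiment")
}

#' @export
print.mmg_experiment <- function(x, ...) {
  cat(sprintf("<mmg_experiment> %d sessions x %d trials, %d EMG + %d MMG channels @ %.1f Hz\n",
              length(x$sessions), x$config$n_trials_per_session,
              x$config$emg_channels, x$config$mmg_channels,
              x$config$fs_raw))
  invisible(x)
}
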