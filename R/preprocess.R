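# Signal preprocessing: zero-phase Butterworth filtering, Hilbert envelope,
# anti-aliased resampling. Pipeline: demean -> 25-100 Hz band-pass ->
# 49-51 Hz band-stop -> |analytic signal| -> resample at 200 Hz.

as_signal_matrix <- function(x) {
  if (is.vector(x)) x <- matrix(x, nrow = 1)
  if (!is.matrix(x) || !is.numeric(x)) stopf("signal must be a numeric matrix (channels x samples)")
  if (ncol(x) < 2) stopf("signal is empty or too short")
  if (!all(is.finite(x))) stopf("signal contains non-finite values")
  x
}

# Zero-phase IIR filtering: odd-reflection padding at both ends (so the
# filter transients decay inside the padding), then the average of the
# forward-backward and backward-forward passes. The symmetrization keeps
# the squared magnitude response, cancels the residual direction-dependent
# rounding of the recursions, and makes the operation exactly symmetric
# under time reversal.
filtfilt_refl <- function(b, a, x) {
  n <- length(x)
  padlen <- min(n - 1L, max(3L * (max(length(a), length(b)) - 1L), 2048L))
  left <- 2 * x[1] - x[(padlen + 1):2]
  right <- 2 * x[n] - x[(n - 1):(n - padlen)]
  ext <- c(left, x, right)
  fb <- function(z) {
    y <- as.numeric(signal::filter(b, a, z))
    rev(as.numeric(signal::filter(b, a, rev(y))))
  }
  y <- 0.5 * (fb(ext) + rev(fb(rev(ext))))
  y[(padlen + 1):(padlen + n)]
}

butter_design <- function(order, edges, fs, type) {
  nyq <- fs / 2
  if (any(edges <= 0) || any(edges >= nyq) || edges[1] >= edges[2])
    stopf("band edges must satisfy 0 < low < high < fs/2 (= %.1f Hz)", nyq)
  signal::butter(order, edges / nyq, type = type)
}

apply_zero_phase <- function(x, filt) {
  x <- as_signal_matrix(x)
  out <- x
  for (ch in seq_len(nrow(x)))
    out[ch, ] <- filtfilt_refl(filt$b, filt$a, x[ch, ])
  out
}

#' Zero-phase Butterworth band-pass filter
#'
#' Applies an order-`order` Butterworth band-pass forward and backward
#' (zero phase; the magnitude response is squared by the double pass).
#'
#' @param x numeric matrix `channels x samples` (a vector is treated as one
#'   channel).
#' @param fs sampling rate in Hz.
#' @param low,high band edges in Hz, `0 < low < high < fs/2`.
#' @param order design order of the one-way filter.
#' @return filtered matrix, same shape as the input.
#' @export
bandpass_filter <- function(x, fs, low = 25, high = 100, order = 4) {
  apply_zero_phase(x, butter_design(order, c(low, high), fs, "pass"))
}

#' Zero-phase Butterworth band-stop (notch) filter
#'
#' @inheritParams bandpass_filter
#' @param low,high stop-band edges in Hz (default 49-51, the 50 Hz line).
#' @return filtered matrix, same shape as the input.
#' @export
bandstop_filter <- function(x, fs, low = 49, high = 51, order = 4) {
  apply_zero_phase(x, butter_design(order, c(low, high), fs, "stop"))
}

#' Instantaneous amplitude via the analytic signal
#'
#' Magnitude of the Hilbert analytic signal per channel. The FFT is taken
#' at a zero-padded 5-smooth length for speed; padding artefacts are
#' confined to the signal edges.
#'
#' @param x numeric matrix `channels x samples`.
#' @return non-negative envelope matrix, same shape as input.
#' @export
hilbert_envelope <- function(x) {
  x <- as_signal_matrix(x)
  n <- ncol(x)
  nf <- next_fast_len(n)
  h <- numeric(nf)
  if (nf %% 2 == 0) {
    h[1] <- 1; h[nf / 2 + 1] <- 1; h[2:(nf / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((nf + 1) / 2)] <- 2
  }
  out <- x
  for (ch in seq_len(nrow(x))) {
    X <- stats::fft(c(x[ch, ], numeric(nf - n)))
    z <- stats::fft(X * h, inverse = TRUE) / nf
    out[ch, ] <- Mod(z[seq_len(n)])
  }
  out
}

#' Resample a signal to a lower rate
#'
#' Zero-phase anti-alias low-pass (windowed-sinc FIR, cutoff at 90% of the
#' output Nyquist) followed by interpolation onto the output sample grid.
#' Output length is `round(n_in * fs_out / fs_in)`; upsampling is not
#' supported.
#'
#' @param x numeric matrix `channels x samples`.
#' @param fs_in,fs_out input and output sampling rates in Hz.
#' @return resampled matrix `channels x round(n * fs_out / fs_in)`.
#' @export
resample_signal <- function(x, fs_in, fs_out = 200) {
  x <- as_signal_matrix(x)
  if (fs_out > fs_in) stopf("upsampling not supported (fs_out > fs_in)")
  n <- ncol(x)
  n_out <- round(n * fs_out / fs_in)
  if (fs_out == fs_in) return(x)
  # anti-alias FIR: Hamming-windowed sinc, order chosen for a transition
  # band comfortably inside the output Nyquist at typical rate ratios
  ntaps <- 513L
  if (ntaps >= n) ntaps <- (n %/% 2) * 2L - 1L
  fir <- signal::fir1(ntaps - 1L, 0.9 * fs_out / fs_in)
  half <- (ntaps - 1L) %/% 2L
  t_out <- (seq_len(n_out) - 1) / fs_out
  t_in <- (seq_len(n) - 1) / fs_in
  n_ext <- n + 2L * half
  nfft <- next_fast_len(n_ext + ntaps - 1L)
  FIR <- stats::fft(c(fir, numeric(nfft - ntaps)))
  out <- matrix(0, nrow(x), n_out)
  for (ch in seq_len(nrow(x))) {
    v <- x[ch, ]
    ext <- c(v[(half + 1):2], v, v[(n - 1):(n - half)])  # even reflection
    conv <- Re(stats::fft(stats::fft(c(ext, numeric(nfft - n_ext))) * FIR,
                          inverse = TRUE)) / nfft
    f <- conv[(2L * half + 1L):(2L * half + n)]  # centered, padding trimmed
    out[ch, ] <- stats::approx(t_in, f, xout = t_out, rule = 2)$y
  }
  out
}

new_envelope_series <- function(data, fs, channels, session_id) {
  structure(
    list(data = data, fs = fs, channels = channels, session_id = session_id),
    class = "envelope_series"
  )
}

#' Preprocess a raw recording into a 200 Hz band-power envelope
#'
#' Pipeline: per-channel demeaning over the whole session, 25-100 Hz
#' zero-phase Butterworth band-pass, 49-51 Hz band-stop, Hilbert envelope,
#' resampling at 200 Hz. Channel metadata and session id are carried over;
#' event times in seconds remain valid.
#'
#' @param rec a `recording`.
#' @param low,high band-pass edges in Hz.
#' @param notch band-stop edges in Hz.
#' @param fs_out output sampling rate in Hz.
#' @param order Butterworth design order.
#' @return object of class `envelope_series` with fields `data`
#'   (`channels x samples`, non-negative), `fs`, `channels`, `session_id`.
#' @export
preprocess_recording <- function(rec, low = 25, high = 100,
                                 notch = c(49, 51), fs_out = 200,
                                 order = 4) {
  stopifnot(inherits(rec, "recording"))
  x <- rec$data - rowMeans(rec$data)
  x <- bandpass_filter(x, rec$fs, low, high, order)
  x <- bandstop_filter(x, rec$fs, notch[1], notch[2], order)
  x <- hilbert_envelope(x)
  x <- resample_signal(x, rec$fs, fs_out)
  # the anti-alias/interpolation stage can undershoot slightly around sharp
  # envelope transients; the envelope is non-negative by definition
  x[x < 0] <- 0
  new_envelope_series(x, fs_out, rec$channels, rec$session_id)
}

#' Preprocess one modality of a synthetic experiment
#'
#' Runs [preprocess_recording()] on every session of the chosen modality
#' and attaches the global trial table used by the windowing and
#' cross-validation layers.
#'
#' @param experiment an `mmg_experiment` from [generate_experiment()].
#' @param modality `"EMG"` or `"MMG"`.
#' @param ... passed to [preprocess_recording()].
#' @return object of class `envelope_experiment`: `sessions` (list of
#'   `envelope_series`), `events` (list of event tables), `trials` (global
#'   trial table), `channels`, `fs`, `trial_len`.
#' @export
preprocess_modality <- function(experiment, modality = c("EMG", "MMG"), ...) {
  modality <- match.arg(modality)
  field <- if (modality == "EMG") "emg" else "mmg"
  envs <- lapply(experiment$sessions,
                 function(s) preprocess_recording(s[[field]], ...))
  events <- lapply(experiment$sessions, function(s) s$events)
  structure(
    list(
      sessions = envs,
      events = events,
      trials = build_trial_table(events, experiment$config$trial_len),
      channels = envs[[1]]$channels,
      fs = envs[[1]]$fs,
      trial_len = experiment$config$trial_len
    ),
    class = "envelope_experiment"
  )
}

# Global trial table: one row per cued movement across sessions.
build_trial_table <- function(events, trial_len) {
  out <- do.call(rbind, lapply(seq_along(events), function(s) {
    ev <- events[[s]]
    data.frame(
      session = s,
      trial_in_session = seq_len(nrow(ev)),
      onset = ev$onset,
      duration = ev$duration,
      label = ev$label,
      stringsAsFactors = FALSE
    )
  }))
  out$trial <- seq_len(nrow(out))
  out[, c("trial", "session", "trial_in_session", "onset", "duration", "label")]
}
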