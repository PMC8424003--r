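#' Preprocessing configuration
#'
#' Defaults implement the standard conditioning chain for ECM construction:
#' upsampling to 500 Hz, zero-phase 4th-order Butterworth highpass at 0.5 Hz
#' to remove baseline wander, and amplitude clipping to +/- 1 mV.
#'
#' @param target_fs resampling target in Hz.
#' @param highpass_cutoff highpass cutoff in Hz.
#' @param filter_order Butterworth order (of the single-pass prototype; the
#'   filter is applied forward-backward, squaring its magnitude response).
#' @param clip_mv clipping bound in mV.
#' @return list of class `preprocess_config`.
#' @export
preprocess_config <- function(target_fs = 500, highpass_cutoff = 0.5,
                              filter_order = 4, clip_mv = 1.0) {
  assert_that(target_fs > 2 * highpass_cutoff,
              "target_fs must exceed twice the highpass cutoff")
  assert_that(clip_mv > 0, "clip_mv must be positive")
  assert_that(is_count(filter_order) && filter_order >= 1,
              "filter_order must be a positive integer")
  structure(list(target_fs = target_fs, highpass_cutoff = highpass_cutoff,
                 filter_order = as.integer(filter_order), clip_mv = clip_mv),
            class = "preprocess_config")
}

# reduce p/q to smallest integers with p/q == ratio (rational approximation)
rational_ratio <- function(ratio, max_den = 4096L) {
  best <- c(round(ratio), 1L)
  err <- abs(ratio - best[1])
  for (q in seq_len(max_den)) {
    p <- round(ratio * q)
    e <- abs(ratio - p / q)
    if (e < err - 1e-12) {
      best <- c(p, q)
      err <- e
      if (e < 1e-9) break
    }
  }
  best
}

# Rational resampling by p/q: zero-stuff upsampling, windowed-sinc FIR
# lowpass (linear phase, delay compensated exactly), then decimation.
# Odd-reflection padding suppresses edge transients.
rational_resample <- function(x, p, q) {
  n <- length(x)
  half_zc <- 10L                                  # sinc zero-crossings per side
  L <- 2L * half_zc * max(p, q) + 1L
  pad <- ceiling(L / (2 * p)) + 2L
  pad <- min(pad, n - 1L)
  xe <- c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  up <- numeric(length(xe) * p)
  up[seq(1L, length(up), by = p)] <- xe
  i <- seq_len(L) - 1L - (L - 1L) / 2
  fc <- 0.5 / max(p, q)                           # cycles/sample at the high rate
  h <- 2 * fc * ifelse(i == 0, 1, sin(2 * pi * fc * i) / (2 * pi * fc * i))
  h <- p * h * (0.42 - 0.5 * cos(2 * pi * seq(0, 1, length.out = L)) +
                  0.08 * cos(4 * pi * seq(0, 1, length.out = L)))  # Blackman
  y <- stats::convolve(up, rev(h), type = "open")
  delay <- (L - 1L) / 2
  y <- y[(delay + 1L):(delay + length(up))]
  y <- y[(pad * p + 1L):(pad * p + n * p)]
  out_n <- as.integer(round(n * p / q))
  y[pmin((seq_len(out_n) - 1L) * q + 1L, n * p)]
}

#' Resample a record to a new sampling rate
#'
#' Rational resampling with anti-aliasing: the signal is upsampled by
#' zero-stuffing, filtered with a delay-compensated linear-phase windowed-sinc
#' lowpass, and decimated, so waveforms keep their exact timing. Beat indices
#' and rhythm interval bounds are rescaled by `target_fs/fs` and rounded to
#' the nearest sample (ties to even); record duration is preserved to within
#' one output sample.
#'
#' @param rec an [ecg_record()].
#' @param target_fs target sampling frequency in Hz.
#' @return the resampled [ecg_record()]; returned unchanged if already at
#'   `target_fs`.
#' @export
resample_record <- function(rec, target_fs) {
  assert_that(is.numeric(target_fs) && length(target_fs) == 1 && target_fs > 0,
              "target_fs must be a positive number")
  validate_ecg_record(rec)
  if (isTRUE(all.equal(rec$fs, target_fs))) return(rec)
  pq <- rational_ratio(target_fs / rec$fs)
  sig <- apply(rec$signal, 2L, rational_resample, p = pq[1], q = pq[2])
  scale <- target_fs / rec$fs
  rh <- rec$rhythm
  rh$onset <- as.integer(round(rh$onset * scale))
  rh$offset <- pmin(as.integer(round(rh$offset * scale)), nrow(sig))
  rh$offset[nrow(rh)] <- nrow(sig)
  ecg_record(sig, fs = target_fs, record_id = rec$record_id,
             beats = pmin(as.integer(round(rec$beats * scale)), nrow(sig) - 1L),
             rhythm = rh, channels = rec$channels, patient_id = rec$patient_id)
}

# zero-phase Butterworth filtering with odd-reflection padding and
# forward-backward application; pad long enough that the edge transient of a
# sub-hertz highpass decays below 1e-6
zero_phase_filter <- function(x, bf, pad) {
  n <- length(x)
  pad <- min(pad, n - 1L)
  pre <- 2 * x[1] - x[(pad + 1L):2]
  post <- 2 * x[n] - x[(n - 1L):(n - pad)]
  y <- signal::filtfilt(bf, c(pre, x, post))
  y[(pad + 1L):(pad + n)]
}

#' Remove baseline wander with a zero-phase Butterworth highpass
#'
#' Applies a 4th-order (by default) highpass Butterworth filter forward and
#' backward per channel, achieving exactly linear (zero) phase: output length
#' equals input length and mid-band peaks do not move. The effective magnitude
#' response is the square of the single-pass Butterworth response.
#'
#' @param rec an [ecg_record()] (intended post-resampling, fs >= 100 Hz).
#' @param cfg a [preprocess_config()].
#' @return the filtered [ecg_record()].
#' @export
highpass_baseline <- function(rec, cfg = preprocess_config()) {
  validate_ecg_record(rec)
  assert_that(rec$fs >= 100, "highpass_baseline expects fs >= 100 Hz")
  n <- nrow(rec$signal)
  min_len <- as.integer(ceiling(rec$fs))
  if (n <= min_len) {
    abort(sprintf(
      "record too short for baseline filtering: %d samples; need more than %d (1 s at %g Hz)",
      n, min_len, rec$fs))
  }
  bf <- signal::butter(cfg$filter_order, cfg$highpass_cutoff / (rec$fs / 2),
                       type = "high")
  pad <- as.integer(round(10 * rec$fs))
  rec$signal <- apply(rec$signal, 2L, zero_phase_filter, bf = bf, pad = pad)
  colnames(rec$signal) <- rec$channels
  rec
}

#' Clip signal amplitude
#'
#' Confines every sample to `[-clip_mv, +clip_mv]`.
#'
#' @param rec an [ecg_record()].
#' @param clip_mv clipping bound in mV (> 0).
#' @return the clipped [ecg_record()].
#' @export
clip_amplitude <- function(rec, clip_mv = 1.0) {
  assert_that(is.numeric(clip_mv) && length(clip_mv) == 1 && clip_mv > 0,
              "clip_mv must be positive")
  rec$signal <- pmin(pmax(rec$signal, -clip_mv), clip_mv)
  rec
}

#' Full preprocessing chain
#'
#' Resample to `cfg$target_fs`, remove baseline wander, clip amplitude — the
#' conditioning every record passes through before ECM construction.
#'
#' @param rec an [ecg_record()].
#' @param cfg a [preprocess_config()].
#' @return the preprocessed [ecg_record()].
#' @export
preprocess_record <- function(rec, cfg = preprocess_config()) {
  rec |>
    resample_record(cfg$target_fs) |>
    highpass_baseline(cfg) |>
    clip_amplitude(cfg$clip_mv)
}
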