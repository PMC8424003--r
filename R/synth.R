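#' Morphology and noise parameters for the synthetic ECG generator
#'
#' Defaults encode the two clinical signatures that separate normal sinus
#' rhythm (NSR) from atrial fibrillation (AF): RR-interval regularity and
#' P-wave presence. NSR beats are near-periodic (coefficient of variation
#' 0.03) and carry a P wave ~160 ms before the R peak; AF beats are drawn
#' i.i.d. with a much larger spread (CV 0.20), the P wave is absent, and a
#' low-amplitude fibrillatory (f) wave oscillation is added to the baseline.
#'
#' Beat morphology is a sum of Gaussian bumps (P, Q, R, S, T), each given as
#' `(amplitude mV, center s relative to the R peak, width s)`.
#'
#' @param nsr_rr_mean mean NSR RR interval, seconds.
#' @param nsr_rr_cv coefficient of variation of NSR RR intervals.
#' @param af_rr_mean mean AF RR interval, seconds.
#' @param af_rr_cv coefficient of variation of AF RR intervals (i.i.d. draws,
#'   serially uncorrelated). Must exceed `nsr_rr_cv`.
#' @param p_amp,p_center,p_width P wave amplitude (mV), center (s) and
#'   Gaussian width (s); the P wave is suppressed entirely during AF.
#' @param qrs description of the Q, R and S bumps: 3x3 matrix with columns
#'   amplitude, center, width.
#' @param t_amp,t_center,t_width T wave parameters.
#' @param fwave_freq fibrillatory wave frequency, Hz (4-10 Hz physiologically).
#' @param fwave_amp fibrillatory wave amplitude, mV.
#' @param wander_amp,wander_freq baseline-wander amplitude (mV) and frequency
#'   (Hz, below the 0.5 Hz highpass cutoff so preprocessing removes it).
#' @param noise_sd white measurement-noise standard deviation, mV.
#'
#' @return a list of class `morphology_params`.
#' @export
morphology_params <- function(nsr_rr_mean = 0.8, nsr_rr_cv = 0.03,
                              af_rr_mean = 0.6, af_rr_cv = 0.20,
                              p_amp = 0.15, p_center = -0.16, p_width = 0.025,
                              qrs = rbind(q = c(-0.10, -0.028, 0.010),
                                          r = c(1.00, 0.000, 0.012),
                                          s = c(-0.18, 0.030, 0.010)),
                              t_amp = 0.28, t_center = 0.30, t_width = 0.055,
                              fwave_freq = 6, fwave_amp = 0.08,
                              wander_amp = 0.03, wander_freq = 0.25,
                              noise_sd = 0.01) {
  m <- list(
    nsr_rr_mean = nsr_rr_mean, nsr_rr_cv = nsr_rr_cv,
    af_rr_mean = af_rr_mean, af_rr_cv = af_rr_cv,
    p_amp = p_amp, p_center = p_center, p_width = p_width,
    qrs = qrs,
    t_amp = t_amp, t_center = t_center, t_width = t_width,
    fwave_freq = fwave_freq, fwave_amp = fwave_amp,
    wander_amp = wander_amp, wander_freq = wander_freq,
    noise_sd = noise_sd
  )
  assert_that(af_rr_cv > nsr_rr_cv, "AF RR variability must exceed NSR variability")
  assert_that(fwave_freq >= 4 && fwave_freq <= 10,
              "f-wave frequency must lie in [4, 10] Hz")
  assert_that(all(c(p_width, qrs[, 3], t_width) > 0) && all(is.finite(unlist(m[1:4]))),
              "widths must be positive and RR parameters finite")
  assert_that(min(nsr_rr_mean, af_rr_mean) > 0, "RR means must be positive")
  structure(m, class = "morphology_params")
}

#' Rhythm plan for a synthetic record
#'
#' An ordered schedule of rhythm phases from which a record is generated.
#'
#' @param durations_s numeric vector of phase durations in seconds (all > 0).
#' @param rhythms character vector of the same length, each `"NSR"` or `"AF"`.
#' @param patient_id patient identifier attached to records generated from the
#'   plan.
#'
#' @return a tibble of class `rhythm_plan` with columns `duration_s`, `rhythm`.
#' @export
rhythm_plan <- function(durations_s, rhythms, patient_id = "p1") {
  assert_that(length(durations_s) == length(rhythms) && length(rhythms) >= 1L,
              "durations and rhythms must be non-empty and match in length")
  assert_that(all(durations_s > 0), "phase durations must be positive")
  assert_that(all(rhythms %in% c("NSR", "AF")), "rhythms must be NSR or AF")
  out <- tibble::tibble(duration_s = as.numeric(durations_s),
                        rhythm = as.character(rhythms))
  attr(out, "patient_id") <- patient_id
  class(out) <- c("rhythm_plan", class(out))
  out
}

#' Rhythm plan with brief AF episodes of exact durations
#'
#' Builds an NSR background with AF insertions of exactly the requested
#' durations, separated (and flanked) by at least `gap_s` of NSR — the
#' standard layout for probing episode sensitivity as a function of episode
#' duration.
#'
#' @param durations_s AF episode durations in seconds (possibly empty).
#' @param gap_s minimum NSR gap before, between and after episodes.
#' @param patient_id patient identifier.
#' @return a [rhythm_plan()].
#' @export
generate_brief_af_plan <- function(durations_s, gap_s = 30, patient_id = "p1") {
  assert_that(all(durations_s > 0), "AF durations must be positive")
  if (!length(durations_s)) {
    return(rhythm_plan(max(gap_s * 2, 60), "NSR", patient_id = patient_id))
  }
  durs <- as.numeric(durations_s)
  d <- c(gap_s, as.vector(rbind(durs, rep(gap_s, length(durs)))))
  r <- c("NSR", as.vector(rbind(rep("AF", length(durs)), rep("NSR", length(durs)))))
  rhythm_plan(d, r, patient_id = patient_id)
}

gauss_bump <- function(t, amp, center, width) {
  amp * exp(-((t - center)^2) / (2 * width^2))
}

#' Generate a synthetic ECG record from a rhythm plan
#'
#' Beats are placed by drawing RR intervals from a log-normal distribution
#' whose mean and coefficient of variation depend on the rhythm active at the
#' R-peak time. Each beat renders a sum-of-Gaussians P-QRS-T template; during
#' AF the P wave is removed and a frequency/amplitude-jittered fibrillatory
#' sinusoid is added (with short cosine tapers at rhythm boundaries). Baseline
#' wander and white noise are superimposed. The returned record carries exact
#' ground-truth beats and rhythm intervals snapped to the nearest sample.
#'
#' @param plan a [rhythm_plan()].
#' @param morph a [morphology_params()].
#' @param fs sampling frequency in Hz (>= 250).
#' @param seed integer seed; the same (plan, morph, seed) always yields an
#'   identical record.
#' @param n_channels number of channels; further channels are scaled copies
#'   with independent noise.
#' @param record_id record identifier.
#' @return an [ecg_record()].
#' @export
generate_record <- function(plan, morph = morphology_params(), fs = 500,
                            seed = 1L, n_channels = 1L, record_id = NULL) {
  assert_that(inherits(plan, "rhythm_plan"), "plan must be a rhythm_plan")
  assert_that(fs >= 250, "fs must be at least 250 Hz")
  patient_id <- attr(plan, "patient_id") %||% "p1"
  if (is.null(record_id)) record_id <- paste0(patient_id, "_rec")
  total_s <- sum(plan$duration_s)
  n <- round(total_s * fs)
  bounds <- c(0, cumsum(plan$duration_s))
  rhythm <- tibble::tibble(
    onset = as.integer(round(bounds[-length(bounds)] * fs)),
    offset = as.integer(round(bounds[-1L] * fs)),
    label = ifelse(plan$rhythm == "AF", "AF", "NONAF")
  )
  rhythm$offset[nrow(rhythm)] <- n

  with_seed(seed, {
    active <- function(t_s) {
      i <- findInterval(t_s, bounds, rightmost.closed = TRUE)
      plan$rhythm[max(1L, min(i, nrow(plan)))]
    }
    draw_rr <- function(rh) {
      mu <- if (rh == "AF") morph$af_rr_mean else morph$nsr_rr_mean
      cv <- if (rh == "AF") morph$af_rr_cv else morph$nsr_rr_cv
      sdlog <- sqrt(log(1 + cv^2))
      rr <- rlnorm(1L, meanlog = log(mu) - sdlog^2 / 2, sdlog = sdlog)
      min(max(rr, 0.25), 2.5)
    }
    beat_t <- numeric(0)
    t_cur <- 0.4 + runif(1L, 0, 0.1)
    while (t_cur < total_s - 0.05) {
      beat_t <- c(beat_t, t_cur)
      t_cur <- t_cur + draw_rr(active(t_cur))
    }
    beat_rh <- vapply(beat_t, active, character(1))

    tgrid <- (seq_len(n) - 1L) / fs
    af_ind <- logical(n)
    for (i in which(rhythm$label == "AF")) {
      af_ind[(rhythm$onset[i] + 1L):rhythm$offset[i]] <- TRUE
    }
    # cosine taper of the AF indicator over 100 ms to avoid hard edges
    taper <- round(0.1 * fs)
    af_w <- stats::filter(as.numeric(af_ind), rep(1 / (2 * taper + 1), 2 * taper + 1),
                          sides = 2)
    af_w[is.na(af_w)] <- as.numeric(af_ind[is.na(af_w)])
    af_w <- as.numeric(af_w)

    sig <- matrix(0, n, n_channels)
    for (ch in seq_len(n_channels)) {
      ch_gain <- if (ch == 1L) 1 else runif(1L, 0.6, 0.9)
      x <- numeric(n)
      for (b in seq_along(beat_t)) {
        tb <- beat_t[b]
        lo <- max(1L, floor((tb - 0.45) * fs))
        hi <- min(n, ceiling((tb + 0.55) * fs))
        tt <- tgrid[lo:hi] - tb
        # T-wave latency adapts to rate (Bazett-style sqrt scaling of QT
        # with the preceding RR interval)
        rr_prev <- if (b > 1L) tb - beat_t[b - 1L] else morph$nsr_rr_mean
        qt_scale <- min(max(sqrt(rr_prev / 0.8), 0.6), 1.2)
        w <- gauss_bump(tt, morph$qrs[1, 1], morph$qrs[1, 2], morph$qrs[1, 3]) +
          gauss_bump(tt, morph$qrs[2, 1], morph$qrs[2, 2], morph$qrs[2, 3]) +
          gauss_bump(tt, morph$qrs[3, 1], morph$qrs[3, 2], morph$qrs[3, 3]) +
          gauss_bump(tt, morph$t_amp, morph$t_center * qt_scale,
                     morph$t_width * qt_scale)
        if (beat_rh[b] == "NSR") {
          w <- w + gauss_bump(tt, morph$p_amp, morph$p_center, morph$p_width)
        }
        x[lo:hi] <- x[lo:hi] + w
      }
      fjit <- morph$fwave_freq * (1 + 0.1 * sin(2 * pi * 0.11 * tgrid + runif(1L, 0, 2 * pi)))
      fphase <- cumsum(2 * pi * fjit / fs)
      fwave <- morph$fwave_amp * (1 + 0.25 * sin(2 * pi * 0.07 * tgrid)) * sin(fphase)
      wander <- morph$wander_amp * sin(2 * pi * morph$wander_freq * tgrid +
                                         runif(1L, 0, 2 * pi))
      x <- x + af_w * fwave + wander + rnorm(n, sd = morph$noise_sd)
      sig[, ch] <- ch_gain * x
    }
    beats <- as.integer(round(beat_t * fs))
    beats <- beats[beats >= 0 & beats < n]
    ecg_record(sig, fs = fs, record_id = record_id, beats = beats,
               rhythm = rhythm, patient_id = patient_id)
  })
}

#' Generate a cohort of synthetic patients
#'
#' Each patient receives a seeded jitter of the template morphology (amplitude
#' scaling, RR means, f-wave frequency) so patients genuinely differ — the
#' prerequisite for meaningful patient-wise train/validation splits.
#'
#' @param n_patients number of patients (>= 2).
#' @param plan_template a [rhythm_plan()] reused for every patient, or a
#'   function `(patient_id) -> rhythm_plan`.
#' @param seed master seed; each patient derives a child seed.
#' @param morph base [morphology_params()].
#' @param fs sampling frequency in Hz.
#' @param n_channels channels per record.
#' @return list of [ecg_record()], one per patient, with distinct patient ids.
#' @export
generate_cohort <- function(n_patients, plan_template, seed = 1L,
                            morph = morphology_params(), fs = 500,
                            n_channels = 1L) {
  assert_that(is_count(n_patients) && n_patients >= 2, "need at least 2 patients")
  lapply(seq_len(n_patients), function(i) {
    pid <- sprintf("p%02d", i)
    ps <- child_seed(seed, pid)
    jit <- with_seed(ps, {
      list(amp = runif(1L, 0.85, 1.15), rr = runif(1L, 0.9, 1.1),
           afrr = runif(1L, 0.9, 1.1), fw = runif(1L, morph$fwave_freq - 1,
                                                  morph$fwave_freq + 1))
    })
    m <- morph
    m$qrs[, 1] <- m$qrs[, 1] * jit$amp
    m$p_amp <- m$p_amp * jit$amp
    m$t_amp <- m$t_amp * jit$amp
    m$nsr_rr_mean <- m$nsr_rr_mean * jit$rr
    m$af_rr_mean <- m$af_rr_mean * jit$afrr
    m$fwave_freq <- min(10, max(4, jit$fw))
    plan <- if (is.function(plan_template)) plan_template(pid) else plan_template
    attr(plan, "patient_id") <- pid
    generate_record(plan, m, fs = fs, seed = child_seed(ps, "rec"),
                    n_channels = n_channels, record_id = paste0(pid, "_rec"))
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a
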