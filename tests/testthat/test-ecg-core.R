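test_that("ecg_record enforces its invariants", {
  sig <- matrix(rnorm(1000), ncol = 2)
  rec <- ecg_record(sig, fs = 100, beats = c(10L, 50L, 200L))
  expect_s3_class(rec, "ecg_record")
  expect_equal(rec$rhythm$label, "NONAF")   # default covers the record
  expect_equal(rec$rhythm$offset, 500L)

  expect_error(ecg_record(sig, fs = 100, beats = c(50L, 10L)), "increasing")
  expect_error(ecg_record(sig, fs = 100, beats = c(10L, 600L)), "inside")
  expect_error(
    ecg_record(sig, fs = 100,
               rhythm = tibble::tibble(onset = c(0L, 100L),
                                       offset = c(200L, 300L),
                                       label = c("AF", "NONAF"))),
    "non-overlapping")
  expect_error(
    ecg_record(sig, fs = 100,
               rhythm = tibble::tibble(onset = 0L, offset = 100L,
                                       label = "AFIB")),
    "labels")
})

test_that("CSV record I/O round-trips exactly and rejects bad input", {
  rec <- generate_record(rhythm_plan(c(10, 8, 12), c("NSR", "AF", "NSR")),
                         seed = 3L, n_channels = 2L)
  sp <- withr::local_tempfile(fileext = ".csv")
  ap <- withr::local_tempfile(fileext = ".csv")
  bp <- withr::local_tempfile(fileext = ".csv")
  write_csv_record(rec, sp, ap, bp)
  back <- read_csv_record(sp, ap, bp)
  expect_identical(back$signal, rec$signal)
  expect_identical(back$beats, rec$beats)
  expect_equal(back$rhythm, rec$rhythm)
  expect_identical(back$fs, rec$fs)
  expect_identical(back$record_id, rec$record_id)

  # one-interval miniature
  mini <- ecg_record(seq(0, 0.9, by = 0.1), fs = 10,
                     rhythm = tibble::tibble(onset = 0L, offset = 10L,
                                             label = "AF"))
  write_csv_record(mini, sp, ap)
  expect_equal(read_csv_record(sp, ap)$rhythm$label, "AF")

  # overlapping intervals rejected with offender listing
  readr::write_csv(tibble::tibble(onset = c(0L, 3L), offset = c(5L, 8L),
                                  label = c("AF", "NONAF")), ap)
  expect_error(read_csv_record(sp, ap), "overlapping")

  # non-numeric signal cell names the row
  writeLines(c("# fs=10 record_id=x patient_id=x", "ch1", "0.1", "oops", "0.3"),
             sp)
  expect_error(read_csv_record(sp), "row 4")
})

test_that("WFDB writer/reader round-trips signal, beats and rhythm", {
  rec <- generate_record(rhythm_plan(c(6, 5, 6), c("NSR", "AF", "NSR"),
                                     patient_id = "w1"),
                         seed = 9L, n_channels = 2L, record_id = "w1rec")
  dir <- withr::local_tempdir()
  write_wfdb_record(rec, dir)
  back <- read_wfdb_record(file.path(dir, "w1rec"))
  expect_equal(ncol(back$signal), 2L)
  expect_equal(back$fs, rec$fs)
  expect_equal(nrow(back$signal), nrow(rec$signal))
  # gain-quantized signal: within half an ADC step of 1/200 mV
  expect_lt(max(abs(back$signal - rec$signal)), 1 / 200)
  expect_identical(back$beats, rec$beats)
  expect_equal(back$rhythm$label, rec$rhythm$label)
  expect_equal(back$rhythm$onset, rec$rhythm$onset)
})

test_that("WFDB rhythm aux labels open intervals closed by the next label", {
  # annotation stream (N @0, (AFIB @1000, (N @3000 on a 5000-sample record
  rec <- ecg_record(matrix(rnorm(5000, sd = 0.1), ncol = 1), fs = 128,
                    record_id = "annx",
                    rhythm = tibble::tibble(onset = c(0L, 1000L, 3000L),
                                            offset = c(1000L, 3000L, 5000L),
                                            label = c("NONAF", "AF", "NONAF")))
  dir <- withr::local_tempdir()
  write_wfdb_record(rec, dir)
  back <- read_wfdb_record(file.path(dir, "annx.hea"))
  expect_equal(back$rhythm$onset, c(0L, 1000L, 3000L))
  expect_equal(back$rhythm$offset, c(1000L, 3000L, 5000L))
  expect_equal(back$rhythm$label, c("NONAF", "AF", "NONAF"))
  expect_equal(back$fs, 128)

  # no annotation file: single NONAF interval, no beats
  rec2 <- ecg_record(matrix(rnorm(640), ncol = 1), fs = 128, record_id = "noann")
  write_wfdb_record(rec2, dir)
  file.remove(file.path(dir, "noann.atr"))
  back2 <- read_wfdb_record(file.path(dir, "noann"))
  expect_equal(nrow(back2$rhythm), 1L)
  expect_equal(back2$rhythm$label, "NONAF")
  expect_length(back2$beats, 0L)

  expect_error(read_wfdb_record(file.path(dir, "missing")), "not found")
})

test_that("resampling preserves duration and waveform shape", {
  # 1280 samples at 128 Hz -> exactly 5000 at 500 Hz
  rec <- ecg_record(matrix(rnorm(1280), ncol = 1), fs = 128,
                    beats = c(100L, 500L, 900L))
  up <- resample_record(rec, 500)
  expect_equal(nrow(up$signal), 5000L)
  expect_equal(up$fs, 500)
  expect_equal(up$beats, as.integer(round(rec$beats * 500 / 128)))
  expect_equal(up$rhythm$offset, 5000L)

  # identity at target rate
  rec500 <- ecg_record(matrix(rnorm(1000), ncol = 1), fs = 500)
  expect_identical(resample_record(rec500, 500), rec500)

  # closed-form sinusoid oracle: 5 Hz sine at 250 Hz up to 500 Hz
  t1 <- (0:2499) / 250
  rec_s <- ecg_record(sin(2 * pi * 5 * t1), fs = 250)
  up_s <- resample_record(rec_s, 500)
  n <- nrow(up_s$signal)
  ref <- sin(2 * pi * 5 * (seq_len(n) - 1) / 500)
  core <- seq(round(n * 0.1), round(n * 0.9))
  expect_gt(cor(up_s$signal[core, 1], ref[core]), 0.999)

  # there-and-back on a 1 Hz sine
  t2 <- (0:4999) / 500
  rec1 <- ecg_record(sin(2 * pi * 1 * t2), fs = 500)
  back <- resample_record(resample_record(rec1, 128), 500)
  m <- min(nrow(back$signal), 5000)
  core2 <- seq(round(m * 0.1), round(m * 0.9))
  expect_gt(cor(back$signal[core2, 1], rec1$signal[core2, 1]), 0.999)

  expect_error(resample_record(rec, -10), "positive")
})

test_that("zero-phase highpass removes baseline without moving peaks", {
  n <- 5000
  # DC rejection
  recc <- ecg_record(rep(0.3, n), fs = 500)
  expect_lt(max(abs(highpass_baseline(recc)$signal)), 1e-6)

  # 0.05 Hz sinusoid: squared single-pass magnitude ~1e-8, well under 0.01
  t <- (0:9999) / 500
  rec_lo <- ecg_record(sin(2 * pi * 0.05 * t), fs = 500)
  expect_lt(max(abs(highpass_baseline(rec_lo)$signal[2000:8000, 1])), 0.01)

  # 5 Hz sine: first positive peak position unchanged within 1 sample
  rec5 <- ecg_record(sin(2 * pi * 5 * (0:4999) / 500), fs = 500)
  out5 <- highpass_baseline(rec5)
  expect_lte(abs(which.max(out5$signal[1:150, 1]) -
                   which.max(rec5$signal[1:150, 1])), 1)

  expect_error(highpass_baseline(ecg_record(rnorm(100), fs = 500)), "short")
})

test_that("amplitude clipping maps samples into the bound", {
  rec <- ecg_record(c(1.5, -2.0, 0.4, 0.99, -1.0), fs = 500)
  out <- clip_amplitude(rec, 1.0)
  expect_equal(out$signal[, 1], c(1.0, -1.0, 0.4, 0.99, -1.0))
  expect_error(clip_amplitude(rec, -1), "positive")
})

test_that("preprocessing pipeline output respects the clip bound and rhythm validity", {
  rec <- generate_record(rhythm_plan(c(20, 15, 20), c("NSR", "AF", "NSR")),
                         fs = 250, seed = 12L)
  out <- preprocess_record(rec)
  expect_true(all(abs(out$signal) <= 1))
  expect_equal(out$fs, 500)
  expect_s3_class(validate_ecg_record(out), "ecg_record")
})

test_that("the stand-in QRS detector recovers ground-truth beats", {
  rec <- fix_nsr_record()
  det <- detect_beats(rec)
  expect_true(all(diff(det) >= 0.2 * rec$fs))   # refractory period
  # every true beat matched within 10 ms, count agrees on a clean record
  tol <- round(0.010 * rec$fs)
  miss <- vapply(rec$beats, function(b) min(abs(det - b)) > tol, logical(1))
  expect_equal(sum(miss), 0L)
  expect_equal(length(det), length(rec$beats))

  # determinism
  expect_identical(det, detect_beats(rec))

  # all-zero record yields nothing; too-short record errors
  expect_length(detect_beats(ecg_record(rep(0, 5000), fs = 500)), 0L)
  expect_error(detect_beats(ecg_record(rnorm(1000), fs = 500)), "3 s")
})
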