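# Independent oracle: rebuild truth/prediction label vectors from the
# confusion counts and recompute every metric from first principles —
# proportions over the vectors and, for Mcc, the Pearson correlation of the
# binary vectors (the phi coefficient), a different computational route than
# the closed-form expression under test.
oracle_metrics <- function(tp, tn, fp, fn) {
  truth <- rep(c(1, 1, 0, 0), c(tp, fn, tn, fp))
  pred <- rep(c(1, 0, 0, 1), c(tp, fn, tn, fp))
  prop <- function(x) if (length(x)) mean(x) else NA_real_
  se <- prop(pred[truth == 1] == 1)
  ppv <- prop(truth[pred == 1] == 1)
  f1 <- if (tp + fp + fn > 0) 2 * tp / (2 * tp + fp + fn) else NA_real_
  mcc <- if (isTRUE(sd(truth) > 0) && isTRUE(sd(pred) > 0)) {
    cor(truth, pred)
  } else {
    NA_real_
  }
  list(acc = prop(truth == pred), se = se,
       sp = prop(pred[truth == 0] == 0), ppv = ppv, f1 = f1,
       mcc_norm = if (is.na(mcc)) NA_real_ else (mcc + 1) / 2)
}

test_that("classification metrics match the brute-force oracle exhaustively", {
  for (tp in 0:6) for (fp in 0:6) for (tn in 0:6) for (fn in 0:6) {
    if (tp + tn + fp + fn == 0) next
    got <- classification_metrics(tp, tn, fp, fn)
    want <- oracle_metrics(tp, tn, fp, fn)
    for (mname in names(want)) {
      expect_equal(got[[mname]], want[[mname]], tolerance = 1e-12,
                   info = sprintf("%s at tp=%d tn=%d fp=%d fn=%d",
                                  mname, tp, tn, fp, fn))
    }
  }
})

test_that("specific confusion tables evaluate to the known values", {
  perfect <- classification_metrics(50, 50, 0, 0)
  expect_equal(unlist(perfect[, c("acc", "se", "sp", "ppv", "f1", "mcc_norm")]),
               c(acc = 1, se = 1, sp = 1, ppv = 1, f1 = 1, mcc_norm = 1))

  m <- classification_metrics(tp = 3, tn = 4, fp = 1, fn = 2)
  expect_equal(m$acc, 0.7)
  expect_equal(m$se, 0.6)
  expect_equal(m$sp, 0.8)
  expect_equal(m$ppv, 0.75)
  expect_equal(m$f1, 2 / 3, tolerance = 1e-4)
  expect_equal(m$mcc_norm, (0.4082483 + 1) / 2, tolerance = 1e-6)

  # class swap changes F1, leaves Acc and Mcc_norm unchanged
  sw <- classification_metrics(tp = 4, tn = 3, fp = 2, fn = 1)
  expect_equal(sw$acc, m$acc)
  expect_equal(sw$mcc_norm, m$mcc_norm, tolerance = 1e-12)
  expect_false(isTRUE(all.equal(sw$f1, m$f1)))

  # undefined metrics are NA, never 0
  allneg <- classification_metrics(0, 10, 0, 0)
  expect_true(is.na(allneg$se))
  expect_true(is.na(allneg$ppv))
  expect_true(is.na(allneg$mcc_norm))
  expect_equal(allneg$acc, 1)
  expect_error(classification_metrics(0, 0, 0, 0), "empty")
})

test_that("F1 equals the harmonic mean of PPV and Se where defined", {
  set.seed(42)
  for (i in 1:200) {
    cts <- rpois(4, lambda = 4)
    if (sum(cts) == 0) next
    m <- classification_metrics(cts[1], cts[2], cts[3], cts[4])
    if (!is.na(m$ppv) && !is.na(m$se) && (m$ppv + m$se) > 0) {
      expect_equal(m$f1, 2 * m$ppv * m$se / (m$ppv + m$se), tolerance = 1e-12)
    }
  }
})

test_that("window decisions remap to samples with AF-priority overlap", {
  dec <- tibble::tibble(segment_start = 100L, segment_end = 5100L, label = "AF")
  s <- remap_to_samples(dec, 10000L)
  expect_true(all(s[101:5100]))
  expect_false(any(s[c(1:100, 5101:10000)]))

  both <- tibble::tibble(segment_start = c(0L, 50L), segment_end = c(100L, 150L),
                         label = c("AF", "NONAF"))
  s2 <- remap_to_samples(both, 200L)
  expect_true(all(s2[51:100]))    # overlap region stays AF

  expect_false(any(remap_to_samples(dec[0, ], 100L)))
})

test_that("episode extraction finds maximal runs", {
  e <- episodes_from_labels(c(0, 0, 0, 1, 1, 1, 1, 0, 0))
  expect_equal(e$onset, 3L)
  expect_equal(e$offset, 7L)
  expect_equal(nrow(episodes_from_labels(rep(0, 10))), 0L)
  e2 <- episodes_from_labels(c(1, 0, 1))
  expect_equal(e2$onset, c(0L, 2L))
  expect_equal(e2$offset, c(1L, 3L))
  # runs are maximal: never adjacent
  set.seed(1)
  for (i in 1:20) {
    s <- runif(200) > 0.6
    ep <- episodes_from_labels(s)
    if (nrow(ep) > 1L) expect_true(all(ep$onset[-1] > ep$offset[-nrow(ep)]))
    # reconstruction identity
    back <- logical(200)
    for (j in seq_len(nrow(ep))) back[(ep$onset[j] + 1):ep$offset[j]] <- TRUE
    expect_identical(back, as.logical(s))
  }
})

test_that("EC57 metrics evaluate the worked interval examples", {
  fs <- 100
  truth <- tibble::tibble(onset = c(10L, 30L) * fs, offset = c(20L, 40L) * fs)
  det <- tibble::tibble(onset = 12L * fs, offset = 18L * fs)
  m <- ec57_metrics(truth, det, fs = fs)
  expect_equal(m$se_epi, 0.5)
  expect_equal(m$ppv_epi, 1.0)
  expect_equal(m$se_dur, 0.30)
  expect_equal(m$ppv_dur, 1.0)
  expect_equal(m$tp_epi, 1L)
  expect_equal(m$fn_epi, 1L)

  ident <- ec57_metrics(truth, truth, fs = fs)
  expect_equal(unlist(ident[, c("se_epi", "ppv_epi", "se_dur", "ppv_dur")]),
               c(se_epi = 1, ppv_epi = 1, se_dur = 1, ppv_dur = 1))

  disj <- ec57_metrics(truth, tibble::tibble(onset = 50L * fs, offset = 60L * fs),
                       fs = fs)
  expect_equal(unlist(disj[, c("se_epi", "ppv_epi", "se_dur", "ppv_dur")]),
               c(se_epi = 0, ppv_epi = 0, se_dur = 0, ppv_dur = 0))

  # undefined-marker cases
  none <- tibble::tibble(onset = integer(), offset = integer())
  expect_true(is.na(ec57_metrics(none, det, fs)$se_epi))
  expect_true(is.na(ec57_metrics(truth, none, fs)$ppv_dur))
  expect_equal(ec57_metrics(truth, none, fs)$se_dur, 0)
})

# per-sample stream oracle for the EC57 quantities
oracle_ec57 <- function(truth, det, n) {
  tv <- remap_to_samples(dplyr::rename(truth, segment_start = onset,
                                       segment_end = offset) |>
                           dplyr::mutate(label = "AF"), n)
  dv <- remap_to_samples(dplyr::rename(det, segment_start = onset,
                                       segment_end = offset) |>
                           dplyr::mutate(label = "AF"), n)
  tru_runs <- episodes_from_labels(tv)
  det_runs <- episodes_from_labels(dv)
  hit <- vapply(seq_len(nrow(tru_runs)), function(i) {
    any(dv[(tru_runs$onset[i] + 1):tru_runs$offset[i]])
  }, logical(1))
  fp <- vapply(seq_len(nrow(det_runs)), function(i) {
    !any(tv[(det_runs$onset[i] + 1):det_runs$offset[i]])
  }, logical(1))
  list(tp = sum(hit), fn = sum(!hit), fp = sum(fp),
       overlap = sum(tv & dv), t_af = sum(tv), t_hat = sum(dv))
}

test_that("EC57 metrics agree with a per-sample oracle on 1000 random layouts", {
  set.seed(123)
  n <- 600L
  for (case in 1:1000) {
    mk <- function() {
      k <- sample(0:4, 1)
      if (k == 0) return(tibble::tibble(onset = integer(), offset = integer()))
      on <- sort(sample(0:(n - 10L), k))
      len <- sample(1:80, k, replace = TRUE)
      off <- pmin(on + len, n)
      # merge overlaps through the label-stream route to keep sets maximal
      episodes_from_labels(remap_to_samples(
        tibble::tibble(segment_start = on, segment_end = off, label = "AF"), n))
    }
    truth <- mk()
    det <- mk()
    got <- ec57_metrics(truth, det, fs = 10)
    want <- oracle_ec57(truth, det, n)
    expect_equal(got$tp_epi, want$tp)
    expect_equal(got$fn_epi, want$fn)
    expect_equal(got$fp_epi, want$fp)
    expect_equal(got$overlap_s * 10, want$overlap)
    if (want$t_af > 0) expect_equal(got$se_dur, want$overlap / want$t_af)
    if (want$t_hat > 0) expect_equal(got$ppv_dur, want$overlap / want$t_hat)
  }
})

test_that("duration sensitivity equals window Se for covering non-overlapping windows", {
  # windows tile the record; per-sample truth equals window labels
  n <- 10000L
  set.seed(7)
  edges <- c(seq(0L, n, by = 500L))
  labs_t <- sample(c("AF", "NONAF"), length(edges) - 1L, replace = TRUE)
  labs_p <- ifelse(runif(length(labs_t)) < 0.8, labs_t,
                   ifelse(labs_t == "AF", "NONAF", "AF"))
  win <- tibble::tibble(segment_start = edges[-length(edges)],
                        segment_end = edges[-1L])
  tv <- remap_to_samples(dplyr::mutate(win, label = labs_t), n)
  dv <- remap_to_samples(dplyr::mutate(win, label = labs_p), n)
  m <- ec57_metrics(episodes_from_labels(tv), episodes_from_labels(dv), fs = 500)
  cm <- confusion_from_labels(labs_t, labs_p)
  expect_equal(m$se_dur, cm$se, tolerance = 1e-12)
  expect_equal(m$ppv_dur, cm$ppv, tolerance = 1e-12)
})

test_that("brief-episode sensitivity stratifies by duration with cumulative bins", {
  fs <- 10
  # episodes of 5 s (detected) and 25 s (missed)
  truth <- tibble::tibble(onset = c(0L, 100L), offset = c(50L, 350L))
  det <- tibble::tibble(onset = 10L, offset = 30L)
  b <- brief_episode_sensitivity(truth, det, fs = fs)
  expect_equal(b$se_epi[b$threshold_s == 10], 1.0)
  expect_equal(b$se_epi[b$threshold_s == 30], 0.5)
  expect_equal(b$threshold_s, c(10, 15, 20, 30, 60, 90, 120, Inf))
  # cumulative counts
  expect_true(all(diff(b$n_episodes) >= 0))
  expect_equal(b$n_episodes[b$threshold_s == Inf], 2L)
  # empty bin -> NA
  long <- tibble::tibble(onset = 0L, offset = 2000L)
  b2 <- brief_episode_sensitivity(long, det, fs = fs)
  expect_true(is.na(b2$se_epi[b2$threshold_s == 10]))
})
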