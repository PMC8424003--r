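#' Confusion-based classification metrics
#'
#' Computes accuracy, sensitivity, specificity, positive predictive value,
#' F1 and the Matthews correlation coefficient from a 2x2 confusion table,
#' with Mcc rescaled from `[-1, 1]` to `[0, 1]` as `(Mcc + 1) / 2`. A metric
#' whose denominator is zero is reported as `NA` (undefined), never silently
#' coerced to 0.
#'
#' @param tp,tn,fp,fn non-negative confusion counts (AF is the positive
#'   class).
#' @return one-row tibble with columns `tp`, `tn`, `fp`, `fn`, `acc`, `se`,
#'   `sp`, `ppv`, `f1`, `mcc_norm`.
#' @export
classification_metrics <- function(tp, tn, fp, fn) {
  assert_that(all(c(tp, tn, fp, fn) >= 0), "confusion counts must be >= 0")
  assert_that(tp + tn + fp + fn > 0, "confusion table is empty")
  div <- function(num, den) if (den > 0) num / den else NA_real_
  acc <- div(tp + tn, tp + tn + fp + fn)
  se <- div(tp, tp + fn)
  sp <- div(tn, tn + fp)
  ppv <- div(tp, tp + fp)
  f1 <- div(2 * tp, 2 * tp + fp + fn)
  mden <- sqrt(prod(c(tp + fp, tp + fn, tn + fp, tn + fn)))
  mcc <- if (mden > 0) (tp * tn - fp * fn) / mden else NA_real_
  tibble::tibble(tp = tp, tn = tn, fp = fp, fn = fn,
                 acc = acc, se = se, sp = sp, ppv = ppv, f1 = f1,
                 mcc_norm = if (is.na(mcc)) NA_real_ else (mcc + 1) / 2)
}

#' Confusion table of window-level decisions
#'
#' @param truth,predicted character vectors of `"AF"`/`"NONAF"` labels.
#' @return one-row tibble of metrics (see [classification_metrics()]).
#' @export
confusion_from_labels <- function(truth, predicted) {
  assert_that(length(truth) == length(predicted), "label vectors must match")
  classification_metrics(
    tp = sum(truth == "AF" & predicted == "AF"),
    tn = sum(truth == "NONAF" & predicted == "NONAF"),
    fp = sum(truth == "NONAF" & predicted == "AF"),
    fn = sum(truth == "AF" & predicted == "NONAF")
  )
}

#' Remap window decisions to a per-sample label stream
#'
#' Every sample inside a classified window receives the window's label; where
#' windows overlap, a sample is AF if any covering window voted AF; samples
#' covered by no window are non-AF.
#'
#' @param decisions tibble with `segment_start`, `segment_end` (0-based,
#'   half-open) and `label` columns.
#' @param record_len record length in samples.
#' @return logical vector of length `record_len`, `TRUE` = AF.
#' @export
remap_to_samples <- function(decisions, record_len) {
  out <- logical(record_len)
  af <- decisions[decisions$label == "AF", , drop = FALSE]
  for (i in seq_len(nrow(af))) {
    lo <- max(af$segment_start[i], 0L)
    hi <- min(af$segment_end[i], record_len)
    if (hi > lo) out[(lo + 1L):hi] <- TRUE
  }
  out
}

#' Extract maximal AF episodes from a per-sample label stream
#'
#' @param stream logical (or 0/1) vector, `TRUE` = AF sample.
#' @return tibble of class `episode_set` with half-open 0-based `onset`,
#'   `offset` columns — maximal runs, so never adjacent or overlapping.
#' @export
episodes_from_labels <- function(stream) {
  stream <- as.logical(stream)
  n <- length(stream)
  d <- diff(c(FALSE, stream, FALSE))
  onsets <- which(d == 1) - 1L
  offsets <- which(d == -1) - 1L
  structure(tibble::tibble(onset = onsets, offset = offsets),
            class = c("episode_set", class(tibble::tibble())))
}

episode_overlap_samples <- function(truth, detected) {
  ov <- 0
  for (i in seq_len(nrow(truth))) {
    if (nrow(detected)) {
      ov <- ov + sum(pmax(0, pmin(detected$offset, truth$offset[i]) -
                            pmax(detected$onset, truth$onset[i])))
    }
  }
  ov
}

#' EC57-style episode and duration metrics
#'
#' Episode matching uses the permissive any-overlap rule: an annotated
#' episode counts as detected (TP) if at least one of its samples is marked
#' AF by the detector, and a detected episode counts as false (FP) if it
#' overlaps no annotated AF sample. Duration metrics compare total
#' intersected AF time with annotated (`Se_Dur`) and detected (`PPV_Dur`)
#' AF time. Metrics with no annotated (or no detected) AF are `NA`.
#'
#' @param truth,detected `episode_set` tibbles (`onset`, `offset`, samples).
#' @param fs sampling rate in Hz (for the reported second-valued totals).
#' @return one-row tibble: `tp_epi`, `fn_epi`, `fp_epi`, `t_af_s`,
#'   `t_af_hat_s`, `overlap_s`, `se_epi`, `ppv_epi`, `se_dur`, `ppv_dur`.
#' @export
ec57_metrics <- function(truth, detected, fs = 500) {
  overlaps_any <- function(a, b) {
    if (!nrow(b)) return(rep(FALSE, nrow(a)))
    vapply(seq_len(nrow(a)), function(i) {
      any(pmin(b$offset, a$offset[i]) > pmax(b$onset, a$onset[i]))
    }, logical(1))
  }
  tp_epi <- sum(overlaps_any(truth, detected))
  fn_epi <- nrow(truth) - tp_epi
  fp_epi <- sum(!overlaps_any(detected, truth))
  t_af <- sum(truth$offset - truth$onset)
  t_af_hat <- sum(detected$offset - detected$onset)
  ov <- episode_overlap_samples(truth, detected)
  div <- function(num, den) if (den > 0) num / den else NA_real_
  tibble::tibble(
    tp_epi = tp_epi, fn_epi = fn_epi, fp_epi = fp_epi,
    t_af_s = t_af / fs, t_af_hat_s = t_af_hat / fs, overlap_s = ov / fs,
    se_epi = div(tp_epi, tp_epi + fn_epi),
    ppv_epi = div(tp_epi, tp_epi + fp_epi),
    se_dur = div(ov, t_af),
    ppv_dur = div(ov, t_af_hat)
  )
}

#' Episode sensitivity stratified by episode duration
#'
#' For each duration threshold `d`, recomputes `Se_Epi` restricted to the
#' annotated episodes shorter than `d` seconds (the `Inf` bin covers all
#' episodes) and reports the episode count per bin. Bins are cumulative:
#' every episode shorter than 10 s is also shorter than 15 s.
#'
#' @param truth,detected `episode_set` tibbles.
#' @param fs sampling rate in Hz.
#' @param thresholds_s duration thresholds in seconds.
#' @return tibble with one row per threshold: `threshold_s`, `n_episodes`,
#'   `n_detected`, `se_epi` (`NA` when a bin holds no episodes).
#' @export
brief_episode_sensitivity <- function(truth, detected, fs = 500,
                                      thresholds_s = c(10, 15, 20, 30, 60,
                                                       90, 120, Inf)) {
  dur_s <- (truth$offset - truth$onset) / fs
  detected_flag <- if (nrow(truth)) {
    vapply(seq_len(nrow(truth)), function(i) {
      nrow(detected) > 0 &&
        any(pmin(detected$offset, truth$offset[i]) >
              pmax(detected$onset, truth$onset[i]))
    }, logical(1))
  } else {
    logical(0)
  }
  purrr::map_dfr(thresholds_s, function(d) {
    sel <- dur_s < d
    n <- sum(sel)
    tibble::tibble(
      threshold_s = d,
      n_episodes = n,
      n_detected = sum(detected_flag[sel]),
      se_epi = if (n > 0) sum(detected_flag[sel]) / n else NA_real_
    )
  })
}

#' End-to-end AF detection report for one record
#'
#' Classifies the record's non-overlapping ECM-images with the ensemble,
#' remaps decisions to samples, extracts detected episodes and scores them
#' against the annotation: window-level confusion metrics, EC57 episode and
#' duration metrics, and the brief-episode sensitivity table.
#'
#' @param ens trained `ecm_ensemble`.
#' @param rec preprocessed, beat-annotated [ecg_record()] at 500 Hz.
#' @param channel channel to evaluate.
#' @param hop_beats window hop (10 = non-overlapping, the testing layout).
#' @param thresholds_s duration thresholds for the sensitivity table.
#' @return list with `windows` (per-window predictions), `confusion`,
#'   `ec57`, `brief`, `detected` and `truth` episode sets.
#' @export
evaluate_record <- function(ens, rec, channel = 1L, hop_beats = 10L,
                            thresholds_s = c(10, 15, 20, 30, 60, 90, 120,
                                             Inf)) {
  ds <- build_ecm_dataset(rec, channel = channel, hop_beats = hop_beats)
  n <- dim(ds$pixels)[3]
  if (n == 0L) {
    abort("record produced no ECM windows; too few beats or margins")
  }
  pred <- mov_classify(ens, ds$pixels)
  windows <- dplyr::bind_cols(ds$meta, pred[, c(paste0("p_AF_net", 1:3),
                                                paste0("vote_net", 1:3))])
  windows$predicted <- pred$label
  stream <- remap_to_samples(
    tibble::tibble(segment_start = ds$meta$segment_start,
                   segment_end = ds$meta$segment_end,
                   label = pred$label),
    nrow(rec$signal))
  detected <- episodes_from_labels(stream)
  truth <- record_af_episodes(rec)
  list(
    windows = windows,
    confusion = confusion_from_labels(ds$meta$label, pred$label),
    ec57 = ec57_metrics(truth, detected, fs = rec$fs),
    brief = brief_episode_sensitivity(truth, detected, fs = rec$fs,
                                      thresholds_s = thresholds_s),
    detected = detected,
    truth = truth
  )
}

#' Pool evaluation reports into gross statistics
#'
#' Sums confusion counts and episode/duration tallies over per-record
#' reports (the EC57 "gross" statistics) and recomputes all metrics from the
#' pooled counts.
#'
#' @param reports list of [evaluate_record()] results.
#' @param fs sampling rate in Hz.
#' @param thresholds_s duration thresholds for the pooled sensitivity table.
#' @return list with `confusion`, `ec57` and `brief` pooled tables.
#' @export
pool_evaluations <- function(reports, fs = 500,
                             thresholds_s = c(10, 15, 20, 30, 60, 90, 120,
                                              Inf)) {
  cm <- purrr::map_dfr(reports, "confusion")
  confusion <- classification_metrics(sum(cm$tp), sum(cm$tn), sum(cm$fp),
                                      sum(cm$fn))
  # offset each record's sample axis so pooled episodes never collide
  shift <- 0L
  tr_all <- list()
  dt_all <- list()
  for (r in reports) {
    span <- max(c(r$truth$offset, r$detected$offset, 0L)) + as.integer(fs)
    tr_all[[length(tr_all) + 1L]] <-
      dplyr::mutate(r$truth, onset = .data$onset + shift,
                    offset = .data$offset + shift)
    dt_all[[length(dt_all) + 1L]] <-
      dplyr::mutate(r$detected, onset = .data$onset + shift,
                    offset = .data$offset + shift)
    shift <- shift + span
  }
  truth <- dplyr::bind_rows(tr_all)
  detected <- dplyr::bind_rows(dt_all)
  list(
    confusion = confusion,
    ec57 = ec57_metrics(truth, detected, fs = fs),
    brief = brief_episode_sensitivity(truth, detected, fs = fs,
                                      thresholds_s = thresholds_s)
  )
}
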