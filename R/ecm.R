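#' Two-section downsampling map of the ECM geometry
#'
#' Each 3.0 s, 1500-sample (500 Hz) beat-aligned subsegment is reduced to 219
#' columns in two sections: the 0.5 s before the R peak is kept at high rate
#' (decimate-by-4: 63 columns at 125 Hz, preserving P-wave morphology) and the
#' remaining 2.496 s at low rate (decimate-by-8: 156 columns, rhythm
#' information only). Offsets are 0-based positions within the subsegment.
#'
#' @return list of class `downsample_map` with `left_source_indices` (63
#'   offsets 0,4,...,248), `right_source_indices` (156 offsets 252,260,...,
#'   1492), `left_cols = 63`, `right_cols = 156`, and per-section decimation
#'   factors.
#' @export
downsample_map <- function() {
  m <- list(
    left_cols = 63L, right_cols = 156L,
    left_source_indices = seq(0L, 248L, by = 4L),
    right_source_indices = seq(252L, 1492L, by = 8L),
    left_factor = 4L, right_factor = 8L,
    subsegment_len = 1500L, fs = 500
  )
  stopifnot(length(m$left_source_indices) == 63L,
            length(m$right_source_indices) == 156L)
  structure(m, class = "downsample_map")
}

#' Enumerate 10-beat ECM windows over a record
#'
#' Windows start at beat positions `0, hop_beats, 2*hop_beats, ...` and span
#' 10 consecutive beats; the segment runs from 0.5 s before the first beat to
#' 2.5 s after the tenth. Windows whose segment would fall outside the record
#' are dropped (never padded). `hop_beats = 5` gives the overlapping windows
#' used for training augmentation, `hop_beats = 10` the non-overlapping
#' windows used for testing.
#'
#' @param beats sorted 0-based R-peak sample indices.
#' @param record_len record length in samples.
#' @param fs sampling frequency in Hz.
#' @param hop_beats window hop in beats, 5 or 10.
#' @param record_id,channel metadata carried into the windows.
#' @return tibble of windows (possibly 0 rows) with columns `window_id`,
#'   `record_id`, `channel`, `beat_indices` (list of 10 R-peak samples),
#'   `segment_start`, `segment_end` (0-based, half-open).
#' @export
segment_windows <- function(beats, record_len, fs, hop_beats,
                            record_id = "rec", channel = 1L) {
  assert_that(hop_beats %in% c(5L, 10L), "hop_beats must be 5 or 10")
  beats <- as.integer(beats)
  pre <- as.integer(round(0.5 * fs))
  post <- as.integer(round(2.5 * fs))
  nb <- length(beats)
  if (nb < 10L) {
    return(tibble::tibble(window_id = character(), record_id = character(),
                          channel = integer(), beat_indices = list(),
                          segment_start = integer(), segment_end = integer()))
  }
  starts <- seq(1L, nb - 9L, by = as.integer(hop_beats))
  rows <- purrr::map(starts, function(s) {
    b <- beats[s:(s + 9L)]
    seg0 <- b[1] - pre
    seg1 <- b[10] + post
    if (seg0 < 0L || seg1 > record_len) return(NULL)
    tibble::tibble(
      window_id = sprintf("%s_ch%d_b%05d", record_id, channel, s),
      record_id = record_id, channel = as.integer(channel),
      beat_indices = list(b),
      segment_start = seg0, segment_end = seg1
    )
  })
  dplyr::bind_rows(rows)
}

#' Extract the 10 beat-aligned subsegments of a window
#'
#' Row `i` holds the 1500 samples `[R_i - 250, R_i + 1250)` of the chosen
#' channel — 3.0 s at 500 Hz starting 0.5 s before the i:th R peak.
#'
#' @param rec a preprocessed [ecg_record()] at 500 Hz.
#' @param window one row of [segment_windows()] output (tibble or list).
#' @return 10 x 1500 numeric matrix.
#' @export
extract_subsegments <- function(rec, window) {
  assert_that(isTRUE(all.equal(rec$fs, 500)), "extract_subsegments expects fs = 500")
  b <- window$beat_indices[[1]]
  assert_that(length(b) == 10L, "a window must contain exactly 10 beats")
  ch <- window$channel[[1]]
  x <- rec$signal[, ch]
  n <- length(x)
  out <- matrix(0, 10L, 1500L)
  for (i in 1:10) {
    lo <- b[i] - 250L
    if (lo < 0L || lo + 1500L > n) {
      abort("subsegment out of record bounds; segment_windows should have dropped it")
    }
    out[i, ] <- x[(lo + 1L):(lo + 1500L)]
  }
  out
}

# 8th-order (effective, forward-backward) Butterworth anti-alias lowpass
anti_alias <- function(x, cutoff_hz, fs = 500) {
  bf <- signal::butter(4, cutoff_hz / (fs / 2), type = "low")
  zero_phase_filter(x, bf, pad = min(length(x) - 1L, as.integer(2 * fs)))
}

#' Two-section downsampling of a subsegment matrix
#'
#' Per row: anti-alias lowpass each section (cutoff 0.8 x the section's output
#' Nyquist), then keep the 63 left and 156 right source samples of the
#' [downsample_map()], concatenated into 219 columns.
#'
#' @param sub 10 x 1500 matrix at 500 Hz from [extract_subsegments()].
#' @param anti_alias_filter apply the anti-alias lowpass before subsampling;
#'   `FALSE` gives pure index-map subsampling (used by exactness tests and the
#'   inverse-mapping property).
#' @return 10 x 219 pixel matrix.
#' @export
downsample_two_section <- function(sub, anti_alias_filter = TRUE) {
  assert_that(is.matrix(sub) && all(dim(sub) == c(10L, 1500L)),
              "expected a 10 x 1500 subsegment matrix")
  dmap <- downsample_map()
  li <- dmap$left_source_indices + 1L
  ri <- dmap$right_source_indices + 1L
  if (!anti_alias_filter) {
    return(cbind(sub[, li, drop = FALSE], sub[, ri, drop = FALSE]))
  }
  out <- matrix(0, 10L, 219L)
  for (i in 1:10) {
    xl <- anti_alias(sub[i, ], cutoff_hz = 0.8 * (500 / dmap$left_factor) / 2)
    xr <- anti_alias(sub[i, ], cutoff_hz = 0.8 * (500 / dmap$right_factor) / 2)
    out[i, ] <- c(xl[li], xr[ri])
  }
  out
}

#' Label a window from the rhythm annotation
#'
#' The window is labeled AF when 50% or more of the samples of its segment
#' (margins included) are annotated AF; samples not covered by any rhythm
#' interval count as non-AF.
#'
#' @param window a window row (needs `segment_start`, `segment_end`).
#' @param rhythm rhythm tibble (`onset`, `offset`, `label`).
#' @return list with `label` ("AF"/"NONAF") and `af_fraction`.
#' @export
label_window <- function(window, rhythm) {
  s0 <- window$segment_start[[1]]
  s1 <- window$segment_end[[1]]
  af <- rhythm[rhythm$label == "AF", , drop = FALSE]
  ov <- 0
  for (i in seq_len(nrow(af))) {
    ov <- ov + max(0, min(af$offset[i], s1) - max(af$onset[i], s0))
  }
  frac <- ov / (s1 - s0)
  list(label = if (frac >= 0.5) "AF" else "NONAF", af_fraction = frac)
}

#' Build the ECM-image dataset of a record channel
#'
#' Chains window enumeration, beat-aligned subsegment extraction, two-section
#' downsampling and 50%-rule labeling. For efficiency the anti-alias lowpass
#' of each section is applied once to the whole channel (equivalent in-band to
#' per-row filtering, and free of per-window edge transients); pixels are
#' gathered from the two filtered signals by the downsample-map indices.
#'
#' @param rec preprocessed [ecg_record()] at 500 Hz with beats.
#' @param channel channel index (1-based).
#' @param hop_beats 5 (overlapping, training) or 10 (non-overlapping, testing).
#' @param anti_alias_filter disable for raw index-map subsampling.
#' @return an `ecm_dataset`: list with `pixels` (10 x 219 x N array) and
#'   `meta` (tibble with window metadata, `label`, `af_fraction`,
#'   `patient_id`).
#' @export
build_ecm_dataset <- function(rec, channel = 1L, hop_beats = 10L,
                              anti_alias_filter = TRUE) {
  validate_ecg_record(rec)
  assert_that(isTRUE(all.equal(rec$fs, 500)), "build_ecm_dataset expects fs = 500")
  wins <- segment_windows(rec$beats, nrow(rec$signal), rec$fs, hop_beats,
                          record_id = rec$record_id, channel = channel)
  dmap <- downsample_map()
  n <- nrow(wins)
  pixels <- array(0, dim = c(10L, 219L, n))
  if (n > 0L) {
    x <- rec$signal[, channel]
    if (anti_alias_filter) {
      xl <- anti_alias(x, 0.8 * (500 / dmap$left_factor) / 2)
      xr <- anti_alias(x, 0.8 * (500 / dmap$right_factor) / 2)
    } else {
      xl <- xr <- x
    }
    li <- dmap$left_source_indices
    ri <- dmap$right_source_indices
    for (w in seq_len(n)) {
      b <- wins$beat_indices[[w]]
      for (i in 1:10) {
        base <- b[i] - 250L
        pixels[i, , w] <- c(xl[base + li + 1L], xr[base + ri + 1L])
      }
    }
  }
  labs <- purrr::map(seq_len(n), function(w) label_window(wins[w, ], rec$rhythm))
  meta <- wins
  meta$label <- purrr::map_chr(labs, "label") %||na% character(0)
  meta$af_fraction <- purrr::map_dbl(labs, "af_fraction") %||na% numeric(0)
  meta$patient_id <- rep(rec$patient_id, n)
  structure(list(pixels = pixels, meta = meta, dmap = dmap),
            class = "ecm_dataset")
}

`%||na%` <- function(a, b) if (length(a)) a else b

#' Combine ECM datasets
#' @param ... `ecm_dataset` objects.
#' @return a single `ecm_dataset` with concatenated images and metadata.
#' @export
bind_ecm_datasets <- function(...) {
  ds <- list(...)
  if (length(ds) == 1L && is.list(ds[[1]]) && !inherits(ds[[1]], "ecm_dataset")) {
    ds <- ds[[1]]
  }
  ds <- ds[purrr::map_int(ds, ~ dim(.x$pixels)[3]) > 0]
  if (!length(ds)) {
    return(structure(list(pixels = array(0, c(10, 219, 0)),
                          meta = tibble::tibble(), dmap = downsample_map()),
                     class = "ecm_dataset"))
  }
  pixels <- array(0, c(10L, 219L, sum(purrr::map_int(ds, ~ dim(.x$pixels)[3]))))
  at <- 0L
  for (d in ds) {
    k <- dim(d$pixels)[3]
    if (k) pixels[, , (at + 1L):(at + k)] <- d$pixels
    at <- at + k
  }
  structure(list(pixels = pixels, meta = dplyr::bind_rows(purrr::map(ds, "meta")),
                 dmap = ds[[1]]$dmap),
            class = "ecm_dataset")
}

#' @export
print.ecm_dataset <- function(x, ...) {
  n <- dim(x$pixels)[3]
  naf <- if (n) sum(x$meta$label == "AF") else 0L
  cat(sprintf("<ecm_dataset> %d ECM-images (10 x 219), %d AF / %d non-AF\n",
              n, naf, n - naf))
  invisible(x)
}

#' Plot an ECM-image
#'
#' @param object an `ecm_dataset`.
#' @param index image index within the dataset.
#' @param ... unused.
#' @return a ggplot heatmap of the 10 x 219 intensity image.
#' @export
autoplot.ecm_dataset <- function(object, index = 1L, ...) {
  px <- object$pixels[, , index]
  df <- tidyr::expand_grid(row = 1:10, col = 1:219)
  df$mv <- as.vector(t(px))
  lab <- if (nrow(object$meta)) object$meta$label[index] else ""
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row, fill = .data$mv)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse(breaks = 1:10) +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white", high = "firebrick",
                                  midpoint = 0, name = "mV") +
    ggplot2::labs(x = "column", y = "beat row",
                  title = sprintf("ECM-image %s (%s)",
                                  if (nrow(object$meta)) object$meta$window_id[index] else index,
                                  lab)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
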