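#' ECG record container
#'
#' An `ecg_record` bundles a (possibly multichannel) sampled ECG signal in mV
#' with its sampling rate, R-peak positions, and ground-truth rhythm
#' annotation. All sample indices in the public interface are **0-based**, and
#' all intervals are half-open `[onset, offset)`, matching the convention of
#' annotation files where sample 0 is the first sample of the record.
#'
#' @param signal numeric matrix, samples x channels, amplitudes in mV. A plain
#'   vector is treated as a single channel.
#' @param fs sampling frequency in Hz.
#' @param record_id character scalar identifying the record.
#' @param beats integer vector of R-peak sample indices (0-based, strictly
#'   increasing, shared across channels).
#' @param rhythm tibble with columns `onset`, `offset` (0-based samples,
#'   half-open) and `label` (`"AF"` or `"NONAF"`), sorted and non-overlapping.
#'   Defaults to a single `NONAF` interval covering the record.
#' @param channels character vector of channel labels; defaults to
#'   `"ch1"`, `"ch2"`, ...
#' @param patient_id identifier of the patient the record belongs to; defaults
#'   to `record_id`. Patient-wise data splits key on this field.
#'
#' @return An object of class `ecg_record`.
#' @export
ecg_record <- function(signal, fs, record_id = "rec",
                       beats = integer(), rhythm = NULL,
                       channels = NULL, patient_id = record_id) {
  if (is.null(dim(signal))) signal <- matrix(as.numeric(signal), ncol = 1L)
  signal <- as.matrix(signal)
  storage.mode(signal) <- "double"
  n <- nrow(signal)
  if (is.null(channels)) channels <- paste0("ch", seq_len(ncol(signal)))
  colnames(signal) <- channels
  if (is.null(rhythm)) {
    rhythm <- tibble::tibble(onset = 0L, offset = n, label = "NONAF")
  }
  rec <- structure(
    list(
      record_id = as.character(record_id),
      patient_id = as.character(patient_id),
      channels = channels,
      signal = signal,
      fs = as.numeric(fs),
      beats = as.integer(round(beats)),
      rhythm = tibble::as_tibble(rhythm)
    ),
    class = "ecg_record"
  )
  validate_ecg_record(rec)
}

#' Validate the invariants of an ECG record
#'
#' Checks that beats are strictly increasing and inside the record, that
#' rhythm intervals are sorted, non-overlapping, half-open with known labels,
#' and that the sampling rate is positive.
#'
#' @param rec an `ecg_record`.
#' @return `rec`, invisibly usable, after passing all checks.
#' @export
validate_ecg_record <- function(rec) {
  assert_that(inherits(rec, "ecg_record"), "not an ecg_record")
  n <- nrow(rec$signal)
  assert_that(rec$fs > 0, "sampling frequency must be positive")
  if (length(rec$beats)) {
    assert_that(all(diff(rec$beats) > 0), "beats must be strictly increasing")
    assert_that(all(rec$beats >= 0 & rec$beats < n),
                "beat indices must lie inside the record")
  }
  rh <- rec$rhythm
  assert_that(all(c("onset", "offset", "label") %in% names(rh)),
              "rhythm needs columns onset, offset, label")
  if (nrow(rh)) {
    assert_that(all(rh$onset < rh$offset), "rhythm intervals need onset < offset")
    assert_that(all(rh$label %in% c("AF", "NONAF")),
                "rhythm labels must be AF or NONAF")
    if (nrow(rh) > 1L) {
      assert_that(all(rh$onset[-1L] >= rh$offset[-nrow(rh)]),
                  "rhythm intervals must be sorted and non-overlapping")
    }
  }
  rec
}

#' @export
print.ecg_record <- function(x, ...) {
  n <- nrow(x$signal)
  af <- sum(pmin(x$rhythm$offset, n)[x$rhythm$label == "AF"] -
              x$rhythm$onset[x$rhythm$label == "AF"])
  cat(sprintf(
    "<ecg_record '%s'> patient %s: %d ch x %d samples @ %g Hz (%.1f s), %d beats, %.1f s AF\n",
    x$record_id, x$patient_id, ncol(x$signal), n, x$fs, n / x$fs,
    length(x$beats), af / x$fs
  ))
  invisible(x)
}

#' Duration of a record in seconds
#' @param rec an `ecg_record`.
#' @return numeric scalar, seconds.
#' @export
record_duration <- function(rec) nrow(rec$signal) / rec$fs

#' Per-sample rhythm label stream
#'
#' Expands the rhythm annotation of a record into a logical vector with one
#' element per sample, `TRUE` where the sample is annotated AF. Samples not
#' covered by any interval count as non-AF.
#'
#' @param rec an `ecg_record`.
#' @return logical vector of length `nrow(rec$signal)`.
#' @export
rhythm_stream <- function(rec) {
  n <- nrow(rec$signal)
  out <- logical(n)
  af <- rec$rhythm[rec$rhythm$label == "AF", ]
  for (i in seq_len(nrow(af))) {
    lo <- max(af$onset[i], 0L)
    hi <- min(af$offset[i], n)
    if (hi > lo) out[(lo + 1L):hi] <- TRUE
  }
  out
}

#' True AF episodes of a record as an episode set
#'
#' @param rec an `ecg_record`.
#' @return a tibble of half-open AF intervals (see [episodes_from_labels()]).
#' @export
record_af_episodes <- function(rec) {
  episodes_from_labels(rhythm_stream(rec))
}
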