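#' Write an ECG record as CSV files
#'
#' The signal file starts with a `# fs=<Hz> record_id=<id> patient_id=<id>`
#' comment line followed by a header of channel labels and one mV value per
#' channel per row (full double precision, so a write/read round trip is
#' field-identical). The annotation file has columns `onset`, `offset`,
#' `label`; the optional beats file a single `beat` column. All indices are
#' 0-based; intervals half-open.
#'
#' @param rec an [ecg_record()].
#' @param signal_path,annotation_path,beats_path output file paths
#'   (`beats_path = NULL` skips beats).
#' @return invisibly, the record.
#' @export
write_csv_record <- function(rec, signal_path, annotation_path,
                             beats_path = NULL) {
  validate_ecg_record(rec)
  con <- file(signal_path, "w")
  writeLines(sprintf("# fs=%.10g record_id=%s patient_id=%s",
                     rec$fs, rec$record_id, rec$patient_id), con)
  writeLines(paste(rec$channels, collapse = ","), con)
  body <- apply(format(rec$signal, digits = 17, trim = TRUE, scientific = TRUE),
                1L, paste, collapse = ",")
  writeLines(body, con)
  close(con)
  readr::write_csv(rec$rhythm, annotation_path, progress = FALSE)
  if (!is.null(beats_path)) {
    readr::write_csv(tibble::tibble(beat = rec$beats), beats_path,
                     progress = FALSE)
  }
  invisible(rec)
}

#' Read an ECG record from CSV files
#'
#' Exact inverse of [write_csv_record()]. Overlapping annotation intervals
#' are rejected with a validation error listing the offending rows;
#' non-numeric signal cells raise a parse error with the row number.
#'
#' @param signal_path,annotation_path,beats_path input paths; `beats_path`
#'   and `annotation_path` may be `NULL` (no beats; whole record non-AF).
#' @return an [ecg_record()].
#' @export
read_csv_record <- function(signal_path, annotation_path = NULL,
                            beats_path = NULL) {
  lines <- readLines(signal_path)
  assert_that(length(lines) >= 2L && startsWith(lines[1], "#"),
              "signal CSV must start with a '# fs=...' metadata line")
  meta <- lines[1]
  getf <- function(key, default = NULL) {
    m <- regmatches(meta, regexec(paste0(key, "=([^ ]+)"), meta))[[1]]
    if (length(m) < 2L) default else m[2]
  }
  fs <- as.numeric(getf("fs"))
  assert_that(is.finite(fs) && fs > 0, "missing or invalid fs in signal CSV")
  channels <- strsplit(lines[2], ",", fixed = TRUE)[[1]]
  body <- lines[-(1:2)]
  cells <- strsplit(body, ",", fixed = TRUE)
  bad_len <- which(lengths(cells) != length(channels))
  if (length(bad_len)) {
    abort(sprintf("signal CSV row %d has %d cells; expected %d",
                  bad_len[1] + 2L, lengths(cells)[bad_len[1]], length(channels)))
  }
  vals <- suppressWarnings(as.numeric(unlist(cells)))
  if (anyNA(vals)) {
    bad <- which(is.na(vals))[1]
    abort(sprintf("non-numeric signal value at CSV row %d",
                  (bad - 1L) %/% length(channels) + 3L))
  }
  sig <- matrix(vals, ncol = length(channels), byrow = TRUE)
  rhythm <- NULL
  if (!is.null(annotation_path)) {
    rhythm <- readr::read_csv(annotation_path, show_col_types = FALSE,
                              progress = FALSE)
    if (nrow(rhythm) > 1L) {
      ord <- order(rhythm$onset)
      rhythm <- rhythm[ord, ]
      bad <- which(rhythm$onset[-1L] < rhythm$offset[-nrow(rhythm)])
      if (length(bad)) {
        abort(paste0("overlapping annotation intervals at rows: ",
                     paste(bad, bad + 1L, sep = "/", collapse = ", ")))
      }
    }
  }
  beats <- integer()
  if (!is.null(beats_path)) {
    beats <- readr::read_csv(beats_path, show_col_types = FALSE,
                             progress = FALSE)$beat
  }
  ecg_record(sig, fs = fs, record_id = getf("record_id", "rec"),
             beats = beats, rhythm = rhythm, channels = channels,
             patient_id = getf("patient_id", getf("record_id", "rec")))
}
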