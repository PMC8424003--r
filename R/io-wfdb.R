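# Minimal WFDB support: format-16 signals plus MIT-format annotations.
# Covers the subset of the format the AF databases use — multi-channel
# format-16 .dat, .hea headers with gain(baseline)/mV, and .atr annotation
# streams with beat marks and "(AFIB"/"(N"-style rhythm-change aux strings.

WFDB_NORMAL <- 1L
WFDB_RHYTHM <- 28L
WFDB_AUX <- 63L
WFDB_SKIP <- 59L

#' Write a record in WFDB format
#'
#' Emits `<record>.hea`, a format-16 interleaved `<record>.dat` (mV scaled by
#' the gain), and — when the record has beats or a rhythm annotation — an
#' MIT-format `<record>.atr` with beat marks and rhythm-change labels
#' (`"(AFIB"` for AF onsets, `"(N"` otherwise).
#'
#' @param rec an [ecg_record()].
#' @param dir output directory.
#' @param gain ADC gain in units per mV.
#' @return invisibly, the header path.
#' @export
write_wfdb_record <- function(rec, dir, gain = 200) {
  validate_ecg_record(rec)
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  name <- rec$record_id
  n <- nrow(rec$signal)
  nsig <- ncol(rec$signal)
  hea <- file.path(dir, paste0(name, ".hea"))
  lines <- sprintf("%s %d %.10g %d", name, nsig, rec$fs, n)
  for (ch in seq_len(nsig)) {
    lines <- c(lines, sprintf("%s.dat 16 %.10g(0)/mV 16 0 0 0 0 %s",
                              name, gain, rec$channels[ch]))
  }
  writeLines(lines, hea)
  dig <- round(rec$signal * gain)
  dig <- pmin(pmax(dig, -32768), 32767)
  inter <- as.integer(t(dig))            # sample-major interleaving
  writeBin(inter, file.path(dir, paste0(name, ".dat")), size = 2L,
           endian = "little")
  if (length(rec$beats) || nrow(rec$rhythm)) {
    anns <- tibble::tibble(time = rec$beats, code = WFDB_NORMAL,
                           aux = NA_character_)
    rh <- rec$rhythm
    if (nrow(rh)) {
      anns <- dplyr::bind_rows(anns, tibble::tibble(
        time = rh$onset, code = WFDB_RHYTHM,
        aux = ifelse(rh$label == "AF", "(AFIB", "(N")))
    }
    anns <- anns[order(anns$time, anns$code), ]
    write_wfdb_annotations(anns, file.path(dir, paste0(name, ".atr")))
  }
  invisible(hea)
}

write_wfdb_annotations <- function(anns, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  w16 <- function(v) writeBin(as.integer(v), con, size = 2L, endian = "little")
  prev <- 0L
  for (i in seq_len(nrow(anns))) {
    delta <- anns$time[i] - prev
    if (delta > 1023L || delta < 0L) {
      w16(bitwShiftL(WFDB_SKIP, 10L))
      hi <- delta %/% 65536L
      lo <- delta %% 65536L
      w16(hi)
      w16(lo)
      delta <- 0L
    }
    w16(bitwOr(bitwShiftL(anns$code[i], 10L), delta))
    if (!is.na(anns$aux[i])) {
      aux <- charToRaw(anns$aux[i])
      w16(bitwOr(bitwShiftL(WFDB_AUX, 10L), length(aux)))
      if (length(aux) %% 2L == 1L) aux <- c(aux, as.raw(0L))
      writeBin(aux, con)
    }
    prev <- anns$time[i]
  }
  w16(0L)
  invisible(path)
}

read_wfdb_annotations <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  words <- readBin(raw, "integer", n = length(raw) %/% 2L, size = 2L,
                   endian = "little", signed = FALSE)
  out <- list()
  t_cur <- 0L
  i <- 1L
  pend_skip <- 0L
  while (i <= length(words)) {
    w <- words[i]
    code <- bitwShiftR(w, 10L)
    delta <- bitwAnd(w, 1023L)
    if (w == 0L) break
    if (code == WFDB_SKIP) {
      hi <- words[i + 1L]
      lo <- words[i + 2L]
      pend_skip <- hi * 65536L + lo
      i <- i + 3L
      next
    }
    if (code == WFDB_AUX) {
      nbytes <- delta
      aux_raw <- raw[(2L * i + 1L):(2L * i + nbytes)]
      aux_raw <- aux_raw[aux_raw != as.raw(0L)]
      if (length(out)) out[[length(out)]]$aux <- rawToChar(aux_raw)
      i <- i + 1L + (nbytes + nbytes %% 2L) %/% 2L
      next
    }
    t_cur <- t_cur + delta + pend_skip
    pend_skip <- 0L
    out[[length(out) + 1L]] <- list(time = t_cur, code = code,
                                    aux = NA_character_)
    i <- i + 1L
  }
  dplyr::bind_rows(out)
}

#' Read a WFDB record
#'
#' Reads the header/signal pair (format 16) and, when present, the
#' annotation file: beat annotations become `beats`, and rhythm-change aux
#' labels open half-open rhythm intervals closed by the next label or the
#' record end (`"(AFIB"` maps to AF; `"(N"`, `"(SBR"` and all other labels to
#' NONAF — unknown labels with a warning). Without an annotation file the
#' whole record is one NONAF interval and beats are empty.
#'
#' @param path path to the `.hea` file (or record name without extension).
#' @param annotation_ext extension of the annotation file (default `"atr"`).
#' @return an [ecg_record()] with the signal in mV.
#' @export
read_wfdb_record <- function(path, annotation_ext = "atr") {
  hea <- if (grepl("\\.hea$", path)) path else paste0(path, ".hea")
  if (!file.exists(hea)) abort(sprintf("WFDB header not found: %s", hea))
  lines <- readLines(hea, warn = FALSE)
  lines <- lines[!startsWith(lines, "#") & nzchar(trimws(lines))]
  top <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  name <- sub("/.*$", "", top[1])
  nsig <- as.integer(top[2])
  fs <- if (length(top) >= 3L) as.numeric(sub("/.*", "", top[3])) else 250
  nsamp <- if (length(top) >= 4L) as.integer(top[4]) else NA_integer_
  assert_that(is.finite(fs) && nsig >= 1L, "malformed WFDB header")
  sig_lines <- lines[2:(1L + nsig)]
  parse_sig <- function(ln) {
    f <- strsplit(trimws(ln), "\\s+")[[1]]
    gm <- regmatches(f[3], regexec("^([-0-9.eE+]+)(\\(([-0-9]+)\\))?", f[3]))[[1]]
    gain <- as.numeric(gm[2])
    if (!is.finite(gain) || gain == 0) gain <- 200
    baseline <- if (nzchar(gm[4] %||% "")) as.numeric(gm[4]) else 0
    desc <- if (length(f) >= 9L) paste(f[9:length(f)], collapse = " ") else NA
    list(file = f[1], format = f[2], gain = gain, baseline = baseline,
         desc = desc)
  }
  sigs <- purrr::map(sig_lines, parse_sig)
  fmt <- unique(purrr::map_chr(sigs, "format"))
  if (!identical(fmt, "16")) {
    abort(sprintf("unsupported WFDB signal format '%s' (only 16 supported)",
                  paste(fmt, collapse = ",")))
  }
  dat <- file.path(dirname(hea), sigs[[1]]$file)
  if (!file.exists(dat)) abort(sprintf("WFDB signal file not found: %s", dat))
  nint <- file.size(dat) %/% 2L
  vals <- readBin(dat, "integer", n = nint, size = 2L, endian = "little")
  n <- length(vals) %/% nsig
  if (!is.na(nsamp) && nsamp < n) n <- nsamp
  dig <- matrix(vals[seq_len(n * nsig)], ncol = nsig, byrow = TRUE)
  sig <- sapply(seq_len(nsig), function(ch) {
    (dig[, ch] - sigs[[ch]]$baseline) / sigs[[ch]]$gain
  })
  channels <- purrr::imap_chr(sigs, function(s, i) {
    if (is.na(s$desc)) paste0("ch", i) else s$desc
  })
  atr <- file.path(dirname(hea), paste0(name, ".", annotation_ext))
  beats <- integer()
  rhythm <- NULL
  if (file.exists(atr)) {
    anns <- read_wfdb_annotations(atr)
    if (nrow(anns)) {
      beat_codes <- c(1L, 2L:13L, 34L, 35L, 38L)   # QRS annotation codes
      beats <- sort(unique(anns$time[anns$code %in% beat_codes]))
      rh <- anns[anns$code == WFDB_RHYTHM & !is.na(anns$aux), ]
      if (nrow(rh)) {
        lab <- vapply(rh$aux, function(a) {
          a <- trimws(a)
          if (a == "(AFIB") return("AF")
          if (!a %in% c("(N", "(SBR", "(AB", "(B", "(BII", "(SVTA", "(T",
                        "(VT", "(NOD", "(P", "(PREX", "(VFL", "(IVR", "(AFL")) {
            warn(sprintf("unknown rhythm label '%s' mapped to NONAF", a))
          }
          "NONAF"
        }, character(1), USE.NAMES = FALSE)
        rhythm <- tibble::tibble(
          onset = as.integer(rh$time),
          offset = c(as.integer(rh$time[-1L]), n),
          label = lab
        )
        rhythm <- rhythm[rhythm$onset < rhythm$offset, ]
        if (nrow(rhythm) && rhythm$onset[1] > 0L) {
          rhythm <- dplyr::bind_rows(
            tibble::tibble(onset = 0L, offset = rhythm$onset[1],
                           label = "NONAF"),
            rhythm)
        }
      }
    }
  }
  ecg_record(sig, fs = fs, record_id = name, beats = beats, rhythm = rhythm,
             channels = channels, patient_id = name)
}
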