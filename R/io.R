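#' Read an RR-interval series from delimited text
#'
#' The canonical on-disk dialect is two-column delimited text — beat time in
#' seconds, RR interval in milliseconds — comma- or tab-separated, with an
#' optional header line and `#` comment lines.
#'
#' @param path Path to the file.
#' @param record_id Identifier; defaults to the file name without extension.
#' @return An [rr_series()] with every beat flagged valid.
#' @export
read_rr <- function(path, record_id = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("empty RR file: %s", path))
  sep <- if (grepl(",", lines[1], fixed = TRUE)) "," else "\t| +"
  parts <- strsplit(lines, sep, perl = TRUE)
  first <- suppressWarnings(as.numeric(parts[[1]][1]))
  if (is.na(first)) { # header line
    lines <- lines[-1]
    parts <- parts[-1]
    if (length(lines) == 0) abort(sprintf("RR file has a header but no data: %s", path))
  }
  tm <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 1L)))
  iv <- suppressWarnings(as.numeric(vapply(parts, `[`, "", 2L)))
  bad <- which(is.na(tm) | is.na(iv))
  if (length(bad) > 0) {
    abort(sprintf("cannot parse RR file %s at data line %d: '%s'", path, bad[1], lines[bad[1]]))
  }
  mono <- which(diff(tm) <= 0)
  if (length(mono) > 0) {
    abort(sprintf(
      "beat times not strictly increasing in %s at data line %d: '%s'",
      path, mono[1] + 1L, lines[mono[1] + 1L]
    ))
  }
  rr_series(tm, iv,
    record_id = record_id %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' Write an RR-interval series as delimited text
#'
#' Writes the two-column dialect read by [read_rr()] at full double precision,
#' so a write/read round trip reproduces the series exactly. Validity flags are
#' not serialized; re-run [clean_rr()] after reading.
#'
#' @param rr An `rr_series`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rr <- function(rr, path) {
  writeLines(
    c(
      "beat_time,interval",
      paste(format(rr$beat_time, digits = 17, trim = TRUE, scientific = FALSE),
        format(rr$interval, digits = 17, trim = TRUE, scientific = FALSE),
        sep = ","
      )
    ),
    path
  )
  invisible(path)
}

#' Read a per-epoch hypnogram CSV
#'
#' Expects columns `epoch,stage` (header optional; a single unnamed column of
#' labels is also accepted). Five-class AASM labels are collapsed through
#' `label_map` (N1, N2 to light sleep, N3 to deep sleep).
#'
#' @inheritParams read_rr
#' @param label_map Named character vector, see [default_label_map()].
#' @return A [hypnogram()].
#' @export
read_hypnogram <- function(path, label_map = default_label_map(), record_id = NULL) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) abort(sprintf("empty hypnogram file: %s", path))
  parts <- strsplit(lines, ",", fixed = TRUE)
  if (tolower(parts[[1]][length(parts[[1]])]) %in% c("stage", "label")) {
    parts <- parts[-1]
  }
  labels <- vapply(parts, function(p) trimws(p[length(p)]), "")
  hypnogram(labels,
    label_map = label_map, source = "annotation",
    record_id = record_id %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' Write a hypnogram as `epoch,stage` CSV
#' @param hyp A `hypnogram`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hypnogram <- function(hyp, path) {
  writeLines(c("epoch,stage", paste(hyp$epoch, hyp$stage, sep = ",")), path)
  invisible(path)
}

#' Read a single-lead ECG waveform
#'
#' Supports two plain-text layouts: (a) a one-column file of samples plus an
#' explicit `rate` argument, or (b) a WFDB-style pair where `path` is a `.hea`
#' header whose first line carries the sampling frequency and the samples live
#' in an ASCII `<record>.txt` beside it. Binary WFDB signals are out of scope.
#'
#' @param path Sample file or `.hea` header path.
#' @param rate Sampling rate in Hz; required for one-column files.
#' @return A list with `signal` (numeric vector, arbitrary units) and `rate`
#'   (Hz), of class `ecg_record`.
#' @export
read_ecg <- function(path, rate = NULL) {
  if (grepl("\\.hea$", path)) {
    if (!file.exists(path)) abort(sprintf("missing WFDB header: %s", path))
    hdr <- strsplit(trimws(readLines(path, n = 1L)), " +")[[1]]
    if (length(hdr) < 3) abort(sprintf("malformed WFDB header: %s", path))
    rate <- as.numeric(hdr[3])
    sig_path <- file.path(dirname(path), paste0(hdr[1], ".txt"))
    if (!file.exists(sig_path)) abort(sprintf("missing WFDB sample file: %s", sig_path))
    path <- sig_path
  }
  if (is.null(rate) || is.na(rate)) {
    abort("sampling rate is required: pass `rate` or use a .hea header.")
  }
  x <- scan(path, what = numeric(), quiet = TRUE, comment.char = "#")
  structure(list(signal = x, rate = rate), class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf(
    "<ecg_record> %d samples @ %g Hz (%.1f s)\n",
    length(x$signal), x$rate, length(x$signal) / x$rate
  ))
  invisible(x)
}

#' Read / write a per-epoch feature table CSV
#'
#' Feature tables have one row per retained epoch, keyed by
#' `(record_id, epoch)`; missing features are empty cells (`NA`).
#'
#' @param path CSV path.
#' @return A tibble.
#' @export
read_feature_table <- function(path) {
  readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
}

#' @rdname read_feature_table
#' @param features Feature table to write.
#' @export
write_feature_table <- function(features, path) {
  readr::write_csv(features, path)
  invisible(path)
}

#' Serialize / restore a fitted model bundle
#'
#' Model bundles (staging models, quality models) are written as a single
#' structured YAML document holding recognizer parameters, feature lists,
#' SVM support coefficients and Platt sigmoid constants, so a fit is
#' inspectable and survives a plain-text round trip.
#'
#' @param model A `stager` or `quality_model` object.
#' @param path Output path.
#' @return `path` invisibly; `read_model_bundle()` returns the restored object.
#' @export
write_model_bundle <- function(model, path) {
  yaml::write_yaml(serialize_model(model), path, precision = 15)
  invisible(path)
}

#' @rdname write_model_bundle
#' @export
read_model_bundle <- function(path) {
  deserialize_model(yaml::read_yaml(path))
}
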