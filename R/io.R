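EVENT_COLUMNS <- c("subject_id", "group", "arm", "muscle", "t_peak_s",
                   "f_central_hz", "psd_max", "duration_s",
                   "duration_periods", "bandwidth_hz", "rejected_code")

# full-precision CSV writer so numeric round trips are bit-exact
write_csv_exact <- function(df, path) {
  fmt <- function(v) {
    if (is.double(v)) sprintf("%.17g", v) else as.character(v)
  }
  header <- paste(names(df), collapse = ",")
  if (nrow(df) == 0L) {
    writeLines(header, path)
    return(invisible(path))
  }
  cells <- vapply(df, fmt, character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  writeLines(c(header, apply(cells, 1L, paste, collapse = ",")), path)
}

#' Write / read a signal record as CSV plus JSON sidecar
#'
#' The CSV carries one `value_uv` column; the sidecar `<path>.json` holds
#' the sampling rate, metadata, stage, edge flag and processing log, plus
#' any ground-truth burst table, so a written record restores exactly.
#'
#' @param rec A [signal_record()].
#' @param path CSV path.
#' @return `read_signal()` returns the [signal_record()].
#' @export
write_signal <- function(rec, path) {
  stopifnot(inherits(rec, "signal_record"))
  write_csv_exact(data.frame(value_uv = rec$samples), path)
  meta <- rec[c("fs", "subject_id", "group", "arm", "muscle", "stage",
                "edge_s", "log")]
  meta$truth <- rec$truth
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE, null = "null")
  invisible(path)
}

#' @rdname write_signal
#' @param format `"csv"` (with sidecar or explicit `fs`) or `"edf"`.
#' @param fs Sampling rate override in Hz, required for CSV files with no
#'   sidecar and ignored for EDF.
#' @param channel EDF channel index.
#' @export
read_signal <- function(path, format = c("csv", "edf"), fs = NULL,
                        channel = 1L) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("no such file: ", path)
  if (format == "edf") {
    edf <- read_edf(path)
    return(signal_record(edf$signals[[channel]], edf$fs[channel],
                         subject_id = edf$patient))
  }
  df <- utils::read.csv(path)
  v <- suppressWarnings(as.numeric(df[[1L]]))
  if (length(v) && any(!is.finite(v)))
    stop("non-numeric or non-finite sample at row ",
         which(!is.finite(v))[1L])
  sidecar <- paste0(path, ".json")
  if (file.exists(sidecar)) {
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
    rec <- signal_record(v, meta$fs, meta$subject_id, meta$group, meta$arm,
                         meta$muscle, meta$stage,
                         edge_s = if (is.null(meta$edge_s)) 0 else meta$edge_s)
    rec$log <- meta$log
    if (!is.null(meta$truth) && length(meta$truth))
      rec$truth <- as.data.frame(meta$truth)
    rec
  } else {
    if (is.null(fs)) stop("fs required: no sidecar found for ", path)
    signal_record(v, fs)
  }
}

#' Minimal EDF (European Data Format) reader
#'
#' Reads the fixed 256-byte ASCII header, the per-signal header block and
#' the int16 data records, applying the physical/digital calibration.
#' Read-only; continuous (EDF, not EDF+D) files.
#'
#' @param path EDF file path.
#' @return List: `patient`, `recording`, `fs` (per channel, Hz), `labels`,
#'   `signals` (list of numeric vectors in physical units).
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- function(nchar) trimws(rawToChar(readBin(con, "raw", nchar)))
  version <- hdr(8L)
  patient <- hdr(80L)
  recording <- hdr(80L)
  hdr(8L + 8L)                       # start date, start time
  header_bytes <- as.integer(hdr(8L))
  hdr(44L)                           # reserved
  n_records <- as.integer(hdr(8L))
  record_dur <- as.numeric(hdr(8L))
  ns <- as.integer(hdr(4L))
  field <- function(nchar) vapply(seq_len(ns), function(i) hdr(nchar), "")
  labels <- field(16L)
  field(80L)                         # transducer
  field(8L)                          # physical dimension
  phys_min <- as.numeric(field(8L))
  phys_max <- as.numeric(field(8L))
  dig_min <- as.numeric(field(8L))
  dig_max <- as.numeric(field(8L))
  field(80L)                         # prefiltering
  spr <- as.integer(field(8L))       # samples per record per signal
  field(32L)                         # reserved
  gain <- (phys_max - phys_min) / (dig_max - dig_min)
  signals <- lapply(seq_len(ns), function(i) numeric(n_records * spr[i]))
  for (r in seq_len(n_records)) {
    for (i in seq_len(ns)) {
      d <- readBin(con, "integer", spr[i], size = 2L, signed = TRUE,
                   endian = "little")
      signals[[i]][((r - 1L) * spr[i] + 1L):(r * spr[i])] <-
        phys_min[i] + gain[i] * (d - dig_min[i])
    }
  }
  list(patient = patient, recording = recording, version = version,
       fs = spr / record_dur, labels = labels, signals = signals)
}

#' Write / read a wave-train event table
#'
#' CSV with the fixed column order subject_id, group, arm, muscle,
#' t_peak_s, f_central_hz, psd_max, duration_s, duration_periods,
#' bandwidth_hz, rejected_code. For a cohort the per-subject valid
#' durations go to a `<path>.json` sidecar so rates can be recomputed.
#' Unknown extra columns are preserved with a warning on read.
#'
#' @param x A `wavetrain_set`, `wavetrain_cohort` or event data frame.
#' @param path CSV path.
#' @param include_rejected Also write rejected events (with their codes).
#' @return `read_event_table()` returns a `wavetrain_cohort` when the
#'   sidecar is present, else the event data frame.
#' @export
write_event_table <- function(x, path, include_rejected = FALSE) {
  ev <- events_of(x)
  if (include_rejected && inherits(x, "wavetrain_set"))
    ev <- rbind(ev, x$rejected)
  extra <- setdiff(names(ev), EVENT_COLUMNS)
  ev <- ev[c(EVENT_COLUMNS, extra)]
  write_csv_exact(ev, path)
  if (inherits(x, "wavetrain_cohort"))
    jsonlite::write_json(list(subjects = x$subjects), paste0(path, ".json"),
                         digits = NA, auto_unbox = TRUE)
  else if (inherits(x, "wavetrain_set"))
    jsonlite::write_json(list(subjects = data.frame(
      subject_id = x$subject_id, group = x$group,
      duration_s = x$duration_s)), paste0(path, ".json"),
      digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_event_table
#' @export
read_event_table <- function(path) {
  ev <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(rejected_code = "character"))
  extra <- setdiff(names(ev), EVENT_COLUMNS)
  if (length(extra))
    warning("unknown event-table column(s) preserved: ",
            paste(extra, collapse = ", "))
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) return(ev)
  meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  structure(list(events = ev, subjects = as.data.frame(meta$subjects)),
            class = "wavetrain_cohort")
}

#' Write / read a cohort manifest
#'
#' CSV columns subject_id, group, path, fs_hz, arm, muscle and optionally
#' tremor_side. `(subject_id, arm, muscle)` must be unique.
#'
#' @param manifest Manifest data frame.
#' @param path CSV path.
#' @return `read_manifest()` returns the manifest data frame.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.csv(manifest, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  m <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("subject_id", "group", "path", "fs_hz", "arm", "muscle")
  if (!all(need %in% names(m)))
    stop("manifest must have columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(m[c("subject_id", "arm", "muscle")]))
    stop("duplicate (subject_id, arm, muscle) rows in manifest")
  m
}

#' Write an AUC diagram in long CSV form
#'
#' Columns parameter, lower, upper, auc (plus p / R / alpha_b /
#' significant where available).
#'
#' @param d An `auc_diagram_2d` or `auc_diagram_3d`.
#' @param path CSV path.
#' @export
write_diagram_csv <- function(d, path) {
  utils::write.csv(as.data.frame(d), path, row.names = FALSE)
  invisible(path)
}
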