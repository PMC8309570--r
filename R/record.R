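#' Single-channel signal record
#'
#' The basic container moved through the pipeline: one channel's samples in
#' microvolts together with its sampling rate, subject/group metadata and a
#' processing stage marker. Stages only move forward along
#' `raw -> filtered -> envelope -> decimated_envelope`.
#'
#' @param samples Numeric vector of samples, in microvolts.
#' @param fs Sampling rate in Hz.
#' @param subject_id Subject identifier.
#' @param group Group label, typically `"patient"` or `"control"`.
#' @param arm `"left"`, `"right"` or `NA`.
#' @param muscle `"extensor"`, `"flexor"` or `NA`.
#' @param stage Processing stage of `samples`.
#' @param edge_s Width in seconds of the edge region flagged as unreliable
#'   (filter transients); excluded from downstream detection.
#'
#' @return An object of class `signal_record`.
#' @export
signal_record <- function(samples, fs, subject_id = "s1", group = NA_character_,
                          arm = NA_character_, muscle = NA_character_,
                          stage = c("raw", "filtered", "envelope",
                                    "decimated_envelope"),
                          edge_s = 0) {
  stage <- match.arg(stage)
  samples <- as.numeric(samples)
  if (!is.numeric(fs) || length(fs) != 1L || !is.finite(fs) || fs <= 0)
    stop("`fs` must be a single positive number")
  if (length(samples) && !all(is.finite(samples)))
    stop("samples must be finite; first bad index: ",
         which(!is.finite(samples))[1L])
  structure(
    list(samples = samples, fs = fs, subject_id = as.character(subject_id),
         group = as.character(group), arm = as.character(arm),
         muscle = as.character(muscle), stage = stage,
         edge_s = edge_s, log = character(0), truth = NULL),
    class = "signal_record")
}

.stage_rank <- c(raw = 1L, filtered = 2L, envelope = 3L,
                 decimated_envelope = 4L)

# advance the stage, refusing to move backwards, and append to the log
advance_record <- function(rec, samples, stage = rec$stage, fs = rec$fs,
                           log_entry = NULL) {
  if (.stage_rank[[stage]] < .stage_rank[[rec$stage]])
    stop("stage transition ", rec$stage, " -> ", stage, " goes backwards")
  out <- rec
  out$samples <- samples
  out$fs <- fs
  out$stage <- stage
  if (!is.null(log_entry)) out$log <- c(rec$log, log_entry)
  out
}

#' @export
print.signal_record <- function(x, ...) {
  n <- length(x$samples)
  cat(sprintf("<signal_record> %s [%s] %s/%s\n", x$subject_id, x$group,
              x$arm, x$muscle))
  cat(sprintf("  stage: %s, %d samples @ %g Hz (%.2f s)\n", x$stage, n,
              x$fs, n / x$fs))
  if (length(x$log)) cat("  log:", paste(x$log, collapse = " | "), "\n")
  if (!is.null(x$truth))
    cat(sprintf("  ground truth: %d injected bursts\n", nrow(x$truth)))
  invisible(x)
}

#' Record duration in seconds
#'
#' @param rec A [signal_record()].
#' @param valid If `TRUE`, subtract the flagged edge regions on both sides.
#' @return Duration in seconds.
#' @export
record_duration <- function(rec, valid = FALSE) {
  d <- length(rec$samples) / rec$fs
  if (valid) d <- max(0, d - 2 * rec$edge_s)
  d
}
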