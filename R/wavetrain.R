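#' Parameter box: bounds in the four-dimensional wave-train space
#'
#' Closed intervals on central frequency (Hz), maximal PSD (uV^2/Hz),
#' duration (periods) and bandwidth (Hz). Any bound may be infinite
#' (unbounded); the default box is fully unbounded.
#'
#' @param min_freq,max_freq Frequency bounds, Hz.
#' @param min_psd,max_psd Maximal-PSD bounds, uV^2/Hz.
#' @param min_duration,max_duration Duration bounds, periods.
#' @param min_bandwidth,max_bandwidth Bandwidth bounds, Hz.
#' @return An object of class `parameter_box`.
#' @export
parameter_box <- function(min_freq = -Inf, max_freq = Inf,
                          min_psd = -Inf, max_psd = Inf,
                          min_duration = -Inf, max_duration = Inf,
                          min_bandwidth = -Inf, max_bandwidth = Inf) {
  b <- list(min_freq = min_freq, max_freq = max_freq,
            min_psd = min_psd, max_psd = max_psd,
            min_duration = min_duration, max_duration = max_duration,
            min_bandwidth = min_bandwidth, max_bandwidth = max_bandwidth)
  for (p in c("freq", "psd", "duration", "bandwidth"))
    if (b[[paste0("min_", p)]] > b[[paste0("max_", p)]])
      stop("min_", p, " exceeds max_", p)
  structure(b, class = "parameter_box")
}

#' @export
print.parameter_box <- function(x, ...) {
  fmt <- function(lo, hi) sprintf("[%g, %g]", lo, hi)
  cat("<parameter_box>",
      "freq", fmt(x$min_freq, x$max_freq), "Hz;",
      "psd", fmt(x$min_psd, x$max_psd), "uV^2/Hz;",
      "duration", fmt(x$min_duration, x$max_duration), "periods;",
      "bandwidth", fmt(x$min_bandwidth, x$max_bandwidth), "Hz\n")
  invisible(x)
}

# intersection of two boxes
box_intersect <- function(a, b) {
  parameter_box(max(a$min_freq, b$min_freq), min(a$max_freq, b$max_freq),
                max(a$min_psd, b$min_psd), min(a$max_psd, b$max_psd),
                max(a$min_duration, b$min_duration),
                min(a$max_duration, b$max_duration),
                max(a$min_bandwidth, b$min_bandwidth),
                min(a$max_bandwidth, b$max_bandwidth))
}

empty_events <- function() {
  data.frame(subject_id = character(0), group = character(0),
             arm = character(0), muscle = character(0),
             t_peak_s = numeric(0), f_central_hz = numeric(0),
             psd_max = numeric(0), duration_s = numeric(0),
             duration_periods = numeric(0), bandwidth_hz = numeric(0),
             rejected_code = character(0), stringsAsFactors = FALSE)
}

#' Local maxima of a smoothed spectrogram
#'
#' Grid points strictly greater than all eight neighbours, restricted to
#' each row's valid (cone-free) column interval. Plateau cells - ties with
#' any neighbour - are not peaks.
#'
#' @param sg A smoothed `spectrogram`.
#' @return Data frame with grid indices (`fi`, `ti`), coordinates
#'   (`f_central_hz`, `t_peak_s`) and `psd_max`.
#' @export
find_local_maxima <- function(sg) {
  stopifnot(inherits(sg, "spectrogram"))
  if (!isTRUE(sg$smoothed))
    stop("find_local_maxima expects a smoothed spectrogram")
  m <- sg$psd
  nf <- nrow(m)
  nt <- ncol(m)
  if (nf < 3L || nt < 3L)
    return(data.frame(fi = integer(0), ti = integer(0),
                      f_central_hz = numeric(0), t_peak_s = numeric(0),
                      psd_max = numeric(0)))
  co <- m[2:(nf - 1L), 2:(nt - 1L)]
  is_peak <-
    co > m[1:(nf - 2L), 2:(nt - 1L)] & co > m[3:nf, 2:(nt - 1L)] &
    co > m[2:(nf - 1L), 1:(nt - 2L)] & co > m[2:(nf - 1L), 3:nt] &
    co > m[1:(nf - 2L), 1:(nt - 2L)] & co > m[1:(nf - 2L), 3:nt] &
    co > m[3:nf, 1:(nt - 2L)] & co > m[3:nf, 3:nt]
  idx <- which(is_peak, arr.ind = TRUE)
  fi <- idx[, 1L] + 1L
  ti <- idx[, 2L] + 1L
  keep <- ti >= sg$valid_lo[fi] & ti <= sg$valid_hi[fi]
  fi <- fi[keep]
  ti <- ti[keep]
  ord <- order(ti, fi)
  data.frame(fi = fi[ord], ti = ti[ord],
             f_central_hz = sg$freqs[fi][ord], t_peak_s = sg$times[ti][ord],
             psd_max = m[cbind(fi, ti)][ord])
}

# walk a 1D slice outward from position i0 until it drops below `half`;
# returns the interpolated crossing (in index units) or a rejection code:
# the slice rising above `peak` first means the maximum is engulfed by a
# larger neighbour, hitting the end of the slice means the half-max level
# is cut off by the record edge
half_crossing <- function(v, i0, peak, half, dir) {
  n <- length(v)
  if (i0 + dir < 1L || i0 + dir > n) return(list(code = "edge"))
  idx <- if (dir > 0) (i0 + 1L):n else (i0 - 1L):1L
  vals <- v[idx]
  below <- which(vals < half)
  above <- which(vals > peak)
  if (!length(below)) return(list(code = "edge"))
  b <- below[1L]
  if (length(above) && above[1L] < b) return(list(code = "engulfed"))
  # linear interpolation between the last sample >= half and the first below
  v1 <- if (b == 1L) v[i0] else vals[b - 1L]
  v2 <- vals[b]
  frac <- (v1 - half) / (v1 - v2)
  i1 <- if (b == 1L) i0 else idx[b - 1L]
  list(code = NA_character_, pos = i1 + dir * frac)
}

#' Measure the four attributes of one wave train
#'
#' Duration is the half-maximum width of the time slice through the peak
#' (the spectrogram row at the central frequency), bandwidth the
#' half-maximum width of the frequency slice (the column at the peak
#' time); both use linear interpolation at the crossings, and
#' `duration_periods = duration_s * f_central`. A peak whose half-maximum
#' crossing is not reached before the record edge, or whose slice rises
#' above the peak value first (a maximum engulfed by a larger neighbour),
#' is rejected with a coded reason rather than an error.
#'
#' @param sg A smoothed `spectrogram`.
#' @param fi,ti Grid indices of a peak from [find_local_maxima()].
#' @return One-row data frame in the event-table schema; `rejected_code` is
#'   `NA` for an accepted wave train, else one of `edge_time`,
#'   `engulfed_time`, `edge_freq`, `engulfed_freq`.
#' @export
measure_wavetrain <- function(sg, fi, ti) {
  peak <- sg$psd[fi, ti]
  half <- peak / 2
  f0 <- sg$freqs[fi]
  out <- data.frame(subject_id = as.character(sg$subject_id),
                    group = as.character(sg$group),
                    arm = as.character(sg$arm),
                    muscle = as.character(sg$muscle),
                    t_peak_s = sg$times[ti], f_central_hz = f0,
                    psd_max = peak, duration_s = NA_real_,
                    duration_periods = NA_real_, bandwidth_hz = NA_real_,
                    rejected_code = NA_character_,
                    stringsAsFactors = FALSE)
  dt <- 1 / sg$fs
  lo <- half_crossing(sg$psd[fi, ], ti, peak, half, -1L)
  hi <- half_crossing(sg$psd[fi, ], ti, peak, half, +1L)
  if (!is.na(lo$code) || !is.na(hi$code)) {
    code <- c(lo$code, hi$code)
    code <- code[!is.na(code)][1L]
    out$rejected_code <- paste0(code, "_time")
    return(out)
  }
  out$duration_s <- (hi$pos - lo$pos) * dt
  out$duration_periods <- out$duration_s * f0
  fstep <- if (nrow(sg$psd) > 1L) sg$freqs[2L] - sg$freqs[1L] else 1
  flo <- half_crossing(sg$psd[, ti], fi, peak, half, -1L)
  fhi <- half_crossing(sg$psd[, ti], fi, peak, half, +1L)
  if (!is.na(flo$code) || !is.na(fhi$code)) {
    code <- c(flo$code, fhi$code)
    code <- code[!is.na(code)][1L]
    out$rejected_code <- paste0(code, "_freq")
    return(out)
  }
  out$bandwidth_hz <- (fhi$pos - flo$pos) * fstep
  out
}

#' Drop wave trains shorter than a tenth of their period
#'
#' Removes events with `duration_periods < min_periods`; the boundary value
#' itself is kept (the rule is "less than").
#'
#' @param events Event data frame.
#' @param min_periods Threshold in periods (default 0.1).
#' @return Filtered data frame.
#' @export
filter_short <- function(events, min_periods = 0.1) {
  if (!nrow(events)) return(events)
  events[events$duration_periods >= min_periods, , drop = FALSE]
}

#' Detect the wave trains of a record
#'
#' Full detection chain: Morlet spectrogram ([cwt_spectrogram()]),
#' frequency-adaptive smoothing ([adaptive_smooth()]), 8-neighbour local
#' maxima ([find_local_maxima()]), attribute measurement
#' ([measure_wavetrain()]) and the short-event filter ([filter_short()]).
#'
#' @param rec A [signal_record()] (any real signal; normally a decimated
#'   envelope).
#' @param fmin,fmax,fstep Analysis frequency grid, Hz.
#' @param fb,fc Morlet parameters.
#' @param min_duration_periods Shortest admissible duration, periods.
#' @return An object of class `wavetrain_set`: accepted `events` sorted by
#'   peak time, `rejected` events with reason codes, and the record's valid
#'   duration for rate computation.
#' @export
detect_wavetrains <- function(rec, fmin = 0.1, fmax = 50, fstep = 0.1,
                              fb = 1, fc = 1, min_duration_periods = 0.1) {
  stopifnot(inherits(rec, "signal_record"))
  sg <- adaptive_smooth(cwt_spectrogram(rec, fmin, fmax, fstep, fb, fc))
  peaks <- find_local_maxima(sg)
  rows <- lapply(seq_len(nrow(peaks)),
                 function(i) measure_wavetrain(sg, peaks$fi[i], peaks$ti[i]))
  all_ev <- if (length(rows)) do.call(rbind, rows) else empty_events()
  ok <- is.na(all_ev$rejected_code)
  events <- all_ev[ok, , drop = FALSE]
  rejected <- all_ev[!ok, , drop = FALSE]
  short <- events$duration_periods < min_duration_periods
  if (any(short)) {
    sh <- events[short, , drop = FALSE]
    sh$rejected_code <- "short"
    rejected <- rbind(rejected, sh)
    events <- events[!short, , drop = FALSE]
  }
  events <- events[order(events$t_peak_s), , drop = FALSE]
  rownames(events) <- NULL
  rownames(rejected) <- NULL
  structure(list(events = events, rejected = rejected,
                 duration_s = record_duration(rec, valid = TRUE),
                 subject_id = rec$subject_id, group = rec$group,
                 arm = rec$arm, muscle = rec$muscle,
                 params = list(fmin = fmin, fmax = fmax, fstep = fstep,
                               fb = fb, fc = fc,
                               min_duration_periods = min_duration_periods)),
            class = "wavetrain_set")
}

#' @export
print.wavetrain_set <- function(x, ...) {
  cat(sprintf("<wavetrain_set> %s [%s]: %d wave trains in %.1f s (%.3f /s), %d rejected\n",
              x$subject_id, x$group, nrow(x$events), x$duration_s,
              nrow(x$events) / x$duration_s, nrow(x$rejected)))
  invisible(x)
}

#' @export
summary.wavetrain_set <- function(object, ...) {
  ev <- object$events
  cat(sprintf("%d wave trains, rate %.3f /s\n", nrow(ev),
              nrow(ev) / object$duration_s))
  if (nrow(ev))
    print(summary(ev[c("f_central_hz", "psd_max", "duration_periods",
                       "bandwidth_hz")]))
  invisible(object)
}

events_of <- function(x) {
  if (inherits(x, "wavetrain_set")) x$events
  else if (inherits(x, "wavetrain_cohort")) x$events
  else as.data.frame(x)
}

#' Select the wave trains inside a parameter box
#'
#' Membership in all four closed intervals of `box`. Selecting with the
#' intersection of two boxes equals selecting with one then the other.
#'
#' @param x A `wavetrain_set`, `wavetrain_cohort` or event data frame.
#' @param box A [parameter_box()].
#' @return Object of the same type with only the events inside the box.
#' @export
select_box <- function(x, box) {
  stopifnot(inherits(box, "parameter_box"))
  ev <- events_of(x)
  keep <- ev$f_central_hz >= box$min_freq & ev$f_central_hz <= box$max_freq &
    ev$psd_max >= box$min_psd & ev$psd_max <= box$max_psd &
    ev$duration_periods >= box$min_duration &
    ev$duration_periods <= box$max_duration &
    ev$bandwidth_hz >= box$min_bandwidth &
    ev$bandwidth_hz <= box$max_bandwidth
  ev <- ev[keep, , drop = FALSE]
  if (inherits(x, "wavetrain_set") || inherits(x, "wavetrain_cohort")) {
    x$events <- ev
    x
  } else {
    ev
  }
}

#' Wave trains per second
#'
#' @param x A `wavetrain_set` or an event data frame.
#' @param duration_s Record duration in seconds (taken from the set when
#'   `x` is a `wavetrain_set`).
#' @return Events per second.
#' @export
rate_per_second <- function(x, duration_s = NULL) {
  ev <- events_of(x)
  if (is.null(duration_s)) {
    if (!inherits(x, "wavetrain_set"))
      stop("duration_s required for plain event tables")
    duration_s <- x$duration_s
  }
  nrow(ev) / duration_s
}

#' Pool wave-train sets of several subjects into a cohort table
#'
#' @param sets List of `wavetrain_set` objects (one per subject/channel).
#' @return Object of class `wavetrain_cohort` with pooled `events` and a
#'   `subjects` table (subject_id, group, valid duration).
#' @export
wavetrain_cohort <- function(sets) {
  stopifnot(all(vapply(sets, inherits, TRUE, "wavetrain_set")))
  events <- do.call(rbind, lapply(sets, `[[`, "events"))
  rownames(events) <- NULL
  subjects <- data.frame(
    subject_id = vapply(sets, `[[`, "", "subject_id"),
    group = vapply(sets, `[[`, "", "group"),
    duration_s = vapply(sets, `[[`, 0, "duration_s"),
    stringsAsFactors = FALSE)
  if (anyDuplicated(subjects$subject_id))
    stop("duplicated subject_id in cohort")
  structure(list(events = events, subjects = subjects),
            class = "wavetrain_cohort")
}

#' @export
print.wavetrain_cohort <- function(x, ...) {
  cat(sprintf("<wavetrain_cohort> %d subjects (%s), %d wave trains\n",
              nrow(x$subjects),
              paste(sprintf("%d %s", table(x$subjects$group),
                            names(table(x$subjects$group))), collapse = ", "),
              nrow(x$events)))
  invisible(x)
}

#' Per-subject wave-train rates inside a parameter box
#'
#' @param cohort A `wavetrain_cohort`.
#' @param box A [parameter_box()].
#' @return Data frame subject_id, group, n_events, rate (events/s).
#' @export
cohort_rates <- function(cohort, box = parameter_box()) {
  stopifnot(inherits(cohort, "wavetrain_cohort"))
  ev <- select_box(cohort$events, box)
  n <- vapply(cohort$subjects$subject_id,
              function(s) sum(ev$subject_id == s), 0)
  data.frame(subject_id = cohort$subjects$subject_id,
             group = cohort$subjects$group, n_events = as.integer(n),
             rate = n / cohort$subjects$duration_s,
             stringsAsFactors = FALSE)
}

#' Match detected wave trains to injected ground truth
#'
#' Greedy one-to-one matching by time and frequency proximity; used to
#' score recall of the detector on synthetic records.
#'
#' @param truth Ground-truth burst table (from a synthetic record).
#' @param events Detected event table or `wavetrain_set`.
#' @param f_tol Frequency tolerance in Hz.
#' @param t_tol Extra time tolerance in seconds beyond half the burst
#'   duration.
#' @return `truth` with columns `matched` (logical), `f_detected_hz` and
#'   `t_detected_s`.
#' @export
match_wavetrains <- function(truth, events, f_tol = 2, t_tol = 0.5) {
  ev <- events_of(events)
  truth$matched <- FALSE
  truth$f_detected_hz <- NA_real_
  truth$t_detected_s <- NA_real_
  used <- rep(FALSE, nrow(ev))
  for (i in seq_len(nrow(truth))) {
    half_dur <- truth$duration_periods[i] / truth$f0_hz[i] / 2
    cand <- which(!used &
                    abs(ev$f_central_hz - truth$f0_hz[i]) <= f_tol &
                    abs(ev$t_peak_s - truth$onset_s[i]) <= half_dur + t_tol)
    if (!length(cand)) next
    j <- cand[which.min(abs(ev$t_peak_s[cand] - truth$onset_s[i]) +
                          abs(ev$f_central_hz[cand] - truth$f0_hz[i]))]
    used[j] <- TRUE
    truth$matched[i] <- TRUE
    truth$f_detected_hz[i] <- ev$f_central_hz[j]
    truth$t_detected_s[i] <- ev$t_peak_s[j]
  }
  truth
}
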