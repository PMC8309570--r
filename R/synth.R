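#' Specification of a single oscillatory burst
#'
#' A burst is a Gaussian-windowed sinusoid: `amplitude * G(t - onset) *
#' cos(2*pi*f0*(t - onset) + phase)`. The Gaussian envelope `G` is scaled so
#' that the full width at half maximum of the *squared* envelope equals
#' `duration_periods / f0` seconds, which makes the nominal duration directly
#' comparable with the half-maximum duration measured on spectrograms.
#'
#' @param f0 Oscillation frequency in Hz (> 0).
#' @param amplitude Peak amplitude in microvolts (>= 0).
#' @param duration_periods Nominal duration in oscillation periods (> 0).
#' @param onset Center time of the burst within the recording, seconds.
#' @param phase Initial phase in radians at the burst center.
#' @param envelope `"gaussian"` (default) or `"hann"`; the Hann window is
#'   matched to the same squared-envelope half-maximum width.
#' @return An object of class `burst_spec`.
#' @export
burst_spec <- function(f0, amplitude = 1, duration_periods = 1, onset = 0,
                       phase = 0, envelope = c("gaussian", "hann")) {
  envelope <- match.arg(envelope)
  if (!is.finite(f0) || f0 <= 0) stop("f0 must be > 0")
  if (!is.finite(duration_periods) || duration_periods <= 0)
    stop("duration_periods must be > 0")
  if (amplitude < 0) stop("amplitude must be >= 0")
  structure(list(f0 = f0, amplitude = amplitude,
                 duration_periods = duration_periods, onset = onset,
                 phase = phase, envelope = envelope),
            class = "burst_spec")
}

# Gaussian envelope SD (seconds) giving squared-envelope FWHM = d / f0
burst_sigma_s <- function(f0, duration_periods)
  duration_periods / (2 * f0 * sqrt(log(2)))

#' Sample a burst waveform
#'
#' Evaluates the burst of [burst_spec()] on a regular grid at rate `fs`. The
#' returned vector covers +/- 3 envelope standard deviations around the burst
#' center (>= 99% of the burst energy); attribute `center_index` marks the
#' sample at the center.
#'
#' @param spec A [burst_spec()].
#' @param fs Sampling rate in Hz; must exceed `2 * f0`.
#' @return Numeric vector with attributes `center_index` and `sigma_s`.
#' @export
make_burst <- function(spec, fs) {
  stopifnot(inherits(spec, "burst_spec"))
  if (spec$f0 >= fs / 2)
    stop("sampling violation: f0 = ", spec$f0, " Hz >= fs/2 = ", fs / 2)
  sigma <- burst_sigma_s(spec$f0, spec$duration_periods)
  L <- ceiling(3 * sigma * fs)
  t <- (-L:L) / fs
  env <- if (spec$envelope == "gaussian") {
    exp(-t^2 / (2 * sigma^2))
  } else {
    # Hann window matched to the same squared-envelope FWHM: the squared
    # envelope halves where 0.5*(1+cos(pi*t/Th)) = 2^(-1/2), i.e. at
    # t = Th * acos(sqrt(2)-1) / pi
    Th <- (spec$duration_periods / spec$f0) / 2 /
      (acos(sqrt(2) - 1) / pi)
    w <- numeric(length(t))
    inside <- abs(t) <= Th
    w[inside] <- 0.5 * (1 + cos(pi * t[inside] / Th))
    w
  }
  x <- spec$amplitude * env * cos(2 * pi * spec$f0 * t + spec$phase)
  attr(x, "center_index") <- L + 1L
  attr(x, "sigma_s") <- sigma
  x
}

#' Specification of a synthetic two-group cohort
#'
#' Describes surrogate recordings used to validate the detection and
#' comparison pipeline: background noise plus bursts whose onsets follow a
#' homogeneous Poisson process, with per-group, per-band rates. Defaults
#' emulate typical tremor-study conditions: 10 controls and 12 patients, 90 s single
#' channel records, envelope sampling at 125 Hz (500 Hz acquisition
#' decimated by 4), and a patient excess of bursts in the 8-20 Hz band
#' (three times the control rate in that band on top of a shared broadband
#' background).
#'
#' @param n_per_group Integer vector `c(control, patient)` (a single number
#'   is recycled to both groups).
#' @param duration_s Record duration in seconds.
#' @param fs Sampling rate of the generated records in Hz.
#' @param control_rates,patient_rates Data frames with columns `f_lo`, `f_hi`
#'   (Hz), `rate` (bursts per second) and optionally `cv`, the coefficient
#'   of variation of a per-subject lognormal rate multiplier (mean 1)
#'   modelling between-subject variability in wave-train profusion; bands
#'   may overlap. Defaults: a shared broadband background (1-50 Hz,
#'   1.2 bursts/s, CV 0.5) plus a physiological-tremor band (8-20 Hz)
#'   where patients have three times the control rate (1.5 vs 0.5
#'   bursts/s, CV 0.4).
#' @param noise Background model: `"white"` Gaussian noise or `"bandlimited"`
#'   (white noise band-passed to 1-50 Hz).
#' @param noise_sigma Background noise SD in microvolts.
#' @param amplitude Mean burst amplitude in microvolts.
#' @param amplitude_jitter Relative half-width of the uniform amplitude
#'   jitter (amplitude ~ U((1-j), (1+j)) * amplitude).
#' @param duration_periods Length-2 range from which burst durations in
#'   periods are drawn uniformly.
#' @param envelope Burst envelope shape, see [burst_spec()].
#' @param seed Integer master seed; all randomness in the generated cohort
#'   derives from it through per-subject subseeds.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = c(control = 10, patient = 12),
                        duration_s = 90, fs = 125,
                        control_rates = data.frame(
                          f_lo = c(1, 8), f_hi = c(50, 20),
                          rate = c(1.2, 0.5), cv = c(0.5, 0.4)),
                        patient_rates = data.frame(
                          f_lo = c(1, 8), f_hi = c(50, 20),
                          rate = c(1.2, 1.5), cv = c(0.5, 0.4)),
                        noise = c("white", "bandlimited"),
                        noise_sigma = 10, amplitude = 25,
                        amplitude_jitter = 0.25,
                        duration_periods = c(0.5, 2),
                        envelope = c("gaussian", "hann"), seed = 1L) {
  noise <- match.arg(noise)
  envelope <- match.arg(envelope)
  if (length(n_per_group) == 1L) n_per_group <- rep(n_per_group, 2L)
  n_per_group <- as.integer(n_per_group)
  if (any(n_per_group < 1L)) stop("n_per_group must be >= 1")
  for (r in list(control_rates, patient_rates)) {
    stopifnot(all(c("f_lo", "f_hi", "rate") %in% names(r)))
    if (any(r$rate < 0)) stop("negative burst rates are not allowed")
    if (fs <= 2 * max(r$f_hi))
      stop("fs must exceed twice the highest generated burst frequency")
  }
  structure(list(n_control = n_per_group[[1L]], n_patient = n_per_group[[2L]],
                 duration_s = duration_s, fs = fs,
                 control_rates = control_rates, patient_rates = patient_rates,
                 noise = noise, noise_sigma = noise_sigma,
                 amplitude = amplitude, amplitude_jitter = amplitude_jitter,
                 duration_periods = duration_periods, envelope = envelope,
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

group_rates <- function(spec, group)
  if (group == "patient") spec$patient_rates else spec$control_rates

# deterministic per-subject subseed derived from the master seed; keeps every
# subject's stream independent and the whole cohort reproducible
subject_seed <- function(master, subject_index) {
  (as.double(master) * 2654435761 + subject_index * 40503) %% (2^31 - 1)
}

# draw the ground-truth burst list for one subject; each band's rate gets
# a per-subject lognormal multiplier (mean 1, CV from the band's `cv`
# column) modelling between-subject variability in wave-train profusion
draw_truth <- function(spec, group) {
  rates <- group_rates(spec, group)
  if (is.null(rates$cv)) rates$cv <- 0
  rows <- lapply(seq_len(nrow(rates)), function(i) {
    sdlog <- sqrt(log(1 + rates$cv[i]^2))
    mult <- stats::rlnorm(1L, -sdlog^2 / 2, sdlog)
    n <- stats::rpois(1L, mult * rates$rate[i] * spec$duration_s)
    if (n == 0L) return(NULL)
    data.frame(onset_s = stats::runif(n, 0, spec$duration_s),
               f0_hz = stats::runif(n, rates$f_lo[i], rates$f_hi[i]),
               amplitude_uv = spec$amplitude *
                 stats::runif(n, 1 - spec$amplitude_jitter,
                              1 + spec$amplitude_jitter),
               duration_periods = stats::runif(n, spec$duration_periods[1L],
                                               spec$duration_periods[2L]),
               phase_rad = stats::runif(n, 0, 2 * pi))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(onset_s = numeric(0), f0_hz = numeric(0),
                      amplitude_uv = numeric(0), duration_periods = numeric(0),
                      phase_rad = numeric(0))
  out[order(out$onset_s), , drop = FALSE]
}

background_noise <- function(spec, n) {
  x <- stats::rnorm(n, 0, spec$noise_sigma)
  if (spec$noise == "bandlimited") {
    bf <- signal::butter(4, c(1, 50) / (spec$fs / 2), type = "pass")
    x <- as.numeric(signal::filtfilt(bf, x))
    # restore the requested marginal SD after filtering
    s <- stats::sd(x)
    if (s > 0) x <- x * spec$noise_sigma / s
  }
  x
}

# superimpose ground-truth bursts on a sample vector
inject_bursts <- function(samples, truth, spec) {
  n <- length(samples)
  for (i in seq_len(nrow(truth))) {
    b <- make_burst(burst_spec(truth$f0_hz[i], truth$amplitude_uv[i],
                               truth$duration_periods[i], truth$onset_s[i],
                               truth$phase_rad[i], spec$envelope), spec$fs)
    c0 <- round(truth$onset_s[i] * spec$fs) + 1L
    idx <- (c0 - attr(b, "center_index") + 1L):(c0 - attr(b, "center_index") +
                                                  length(b))
    keep <- idx >= 1L & idx <= n
    samples[idx[keep]] <- samples[idx[keep]] + b[keep]
  }
  samples
}

#' Generate one synthetic envelope record
#'
#' Background noise plus Poisson-timed oscillatory bursts, emulating a
#' preprocessed (decimated-envelope stage) EMG channel. The generated
#' ground-truth burst list is stored in the record's `truth` field.
#'
#' @param spec A [cohort_spec()].
#' @param subject_id Subject identifier.
#' @param group `"control"` or `"patient"`.
#' @param seed Optional integer overriding the seed derived from
#'   `spec$seed` and the subject id.
#' @param subject_index Index used for subseed derivation when `seed` is
#'   not given.
#' @return A [signal_record()] at stage `decimated_envelope`.
#' @export
synth_envelope_record <- function(spec, subject_id, group = "control",
                                  seed = NULL, subject_index = 1L) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- subject_seed(spec$seed, subject_index)
  set.seed(seed)
  n <- round(spec$duration_s * spec$fs)
  truth <- draw_truth(spec, group)
  samples <- inject_bursts(background_noise(spec, n), truth, spec)
  rec <- signal_record(samples, spec$fs, subject_id, group,
                       arm = "right", muscle = "extensor",
                       stage = "decimated_envelope")
  rec$log <- sprintf("synth_envelope_record(seed=%d)", as.integer(seed))
  rec$truth <- truth
  rec
}

#' Generate one synthetic raw EMG record
#'
#' Emulates an unprocessed surface EMG channel: a 60-240 Hz band-limited
#' noise carrier, amplitude-modulated by the same background-plus-bursts
#' envelope used by [synth_envelope_record()]. Running the record through
#' [preprocess_emg()] should recover the generating modulation.
#'
#' @inheritParams synth_envelope_record
#' @param fs_raw Acquisition sampling rate in Hz (default 500).
#' @param carrier_band Carrier pass band in Hz.
#' @param carrier_sd Carrier SD before modulation; 0 yields an all-zero
#'   record.
#' @param baseline Tonic envelope level in microvolts added under the
#'   bursts so the modulation stays mostly positive (clipped at zero);
#'   default half the burst amplitude, a strongly phasic regime in which
#'   the modulation dominates the carrier's own envelope fluctuations.
#' @return A [signal_record()] at stage `raw`; `truth` holds the burst list
#'   and attribute `modulation` of the record holds the generating envelope.
#' @export
synth_raw_emg_record <- function(spec, subject_id, group = "control",
                                 seed = NULL, subject_index = 1L,
                                 fs_raw = 500, carrier_band = c(60, 240),
                                 carrier_sd = 1, baseline = NULL) {
  stopifnot(inherits(spec, "cohort_spec"))
  if (is.null(seed)) seed <- subject_seed(spec$seed, subject_index)
  if (is.null(baseline)) baseline <- 0.5 * spec$amplitude
  set.seed(seed)
  n <- round(spec$duration_s * fs_raw)
  truth <- draw_truth(spec, group)
  spec_raw <- spec
  spec_raw$fs <- fs_raw
  modulation <- pmax(inject_bursts(rep(baseline, n), truth, spec_raw), 0)
  carrier <- if (carrier_sd > 0) {
    bf <- signal::butter(4, carrier_band / (fs_raw / 2), type = "pass")
    cw <- as.numeric(signal::filtfilt(bf, stats::rnorm(n)))
    cw * carrier_sd / stats::sd(cw)
  } else {
    numeric(n)
  }
  rec <- signal_record(modulation * carrier, fs_raw, subject_id, group,
                       arm = "right", muscle = "extensor", stage = "raw")
  rec$log <- sprintf("synth_raw_emg_record(seed=%d)", as.integer(seed))
  rec$truth <- truth
  attr(rec, "modulation") <- modulation
  rec
}

#' Generate a full synthetic cohort
#'
#' One record per subject per group plus a cohort manifest. With `dir` set,
#' records are written as CSV + JSON sidecar through [write_signal()] and
#' the manifest as `manifest.csv`.
#'
#' @param spec A [cohort_spec()].
#' @param dir Optional output directory.
#' @param kind `"envelope"` records (default) or `"raw"` EMG records.
#' @return List with `records` (list of [signal_record()]) and `manifest`
#'   (data frame with columns subject_id, group, path, fs_hz, arm, muscle).
#' @export
synth_cohort <- function(spec, dir = NULL, kind = c("envelope", "raw")) {
  kind <- match.arg(kind)
  stopifnot(inherits(spec, "cohort_spec"))
  groups <- c(rep("control", spec$n_control), rep("patient", spec$n_patient))
  ids <- sprintf("%s%02d", ifelse(groups == "control", "C", "P"),
                 c(seq_len(spec$n_control), seq_len(spec$n_patient)))
  records <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    records[[i]] <- if (kind == "envelope") {
      synth_envelope_record(spec, ids[i], groups[i], subject_index = i)
    } else {
      synth_raw_emg_record(spec, ids[i], groups[i], subject_index = i)
    }
  }
  names(records) <- ids
  paths <- rep(NA_character_, length(ids))
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    paths <- file.path(dir, paste0(ids, ".csv"))
    for (i in seq_along(ids)) write_signal(records[[i]], paths[i])
  }
  manifest <- data.frame(subject_id = ids, group = groups, path = paths,
                         fs_hz = vapply(records, function(r) r$fs, 0),
                         arm = "right", muscle = "extensor",
                         stringsAsFactors = FALSE)
  if (!is.null(dir)) write_manifest(manifest, file.path(dir, "manifest.csv"))
  list(records = records, manifest = manifest)
}
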