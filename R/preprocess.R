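#' Preprocessing configuration
#'
#' Parameters of the raw-EMG-to-envelope chain: power-line notch filters,
#' zero-phase Butterworth band-pass, Hilbert envelope and decimation.
#' Defaults follow common surface-EMG practice for 500 Hz recordings:
#' notches at the 50 Hz mains frequency and its harmonics, a 60-240 Hz
#' band-pass isolating the interference-free EMG band, and 4x decimation of
#' the envelope (500 -> 125 Hz).
#'
#' @param notch_freqs Notch frequencies in Hz.
#' @param bandpass_low_hz,bandpass_high_hz Band-pass corner frequencies, Hz.
#' @param butter_order Butterworth order (applied forward and reverse, so
#'   the effective magnitude response is the squared response).
#' @param decimation_factor Integer decimation factor (>= 1).
#' @return An object of class `preprocess_config`.
#' @export
preprocess_config <- function(notch_freqs = c(50, 100, 150, 200),
                              bandpass_low_hz = 60, bandpass_high_hz = 240,
                              butter_order = 4, decimation_factor = 4) {
  if (bandpass_low_hz <= 0 || bandpass_low_hz >= bandpass_high_hz)
    stop("need 0 < bandpass_low_hz < bandpass_high_hz")
  if (decimation_factor < 1 || decimation_factor != round(decimation_factor))
    stop("decimation_factor must be a positive integer")
  structure(list(notch_freqs = notch_freqs,
                 bandpass_low_hz = bandpass_low_hz,
                 bandpass_high_hz = bandpass_high_hz,
                 butter_order = butter_order,
                 decimation_factor = as.integer(decimation_factor)),
            class = "preprocess_config")
}

#' Read / write a preprocessing configuration file
#'
#' Flat YAML key-value file with keys `notch_freqs`, `bandpass_low_hz`,
#' `bandpass_high_hz`, `butter_order`, `decimation_factor`.
#'
#' @param path File path.
#' @return `read_preprocess_config()` returns a [preprocess_config()].
#' @export
read_preprocess_config <- function(path) {
  v <- yaml::read_yaml(path)
  do.call(preprocess_config, v[c("notch_freqs", "bandpass_low_hz",
                                 "bandpass_high_hz", "butter_order",
                                 "decimation_factor")])
}

#' @rdname read_preprocess_config
#' @param cfg A [preprocess_config()].
#' @export
write_preprocess_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

# second-order IIR notch (constrained pole-zero biquad); the `signal`
# package has no notch designer
notch_biquad <- function(f0, fs, q) {
  w0 <- 2 * pi * f0 / fs
  alpha <- sin(w0) / (2 * q)
  b <- c(1, -2 * cos(w0), 1)
  a <- c(1 + alpha, -2 * cos(w0), 1 - alpha)
  list(b = b / a[1L], a = a / a[1L])
}

#' Notch filtering of power-line interference
#'
#' Applies a second-order IIR notch at each frequency, zero-phase (forward
#' and reverse), so the stop-band attenuation is doubled and no group delay
#' is introduced. `Q = 35` gives roughly a 1 Hz wide -3 dB notch at 50 Hz
#' for the default quality factor.
#'
#' @param rec A [signal_record()].
#' @param freqs Notch frequencies in Hz; an empty vector is the identity.
#' @param q Notch quality factor (center frequency / -3 dB width).
#' @return The filtered record.
#' @export
notch_filter <- function(rec, freqs = c(50, 100, 150, 200), q = 35) {
  stopifnot(inherits(rec, "signal_record"))
  if (any(freqs >= rec$fs / 2))
    stop("notch frequency at or above Nyquist (", rec$fs / 2, " Hz)")
  x <- rec$samples
  for (f0 in freqs) {
    co <- notch_biquad(f0, rec$fs, q)
    x <- as.numeric(signal::filtfilt(co$b, co$a, x))
  }
  advance_record(rec, x,
                 log_entry = sprintf("notch(%s Hz, Q=%g)",
                                     paste(freqs, collapse = ","), q))
}

#' Zero-phase Butterworth band-pass
#'
#' Forward-backward filtering; the effective magnitude response is the
#' squared Butterworth response and the phase response is identically zero
#' (no group delay for in-band components).
#'
#' @param rec A [signal_record()].
#' @param low,high Pass band corners in Hz, `0 < low < high < fs/2`.
#' @param order Butterworth order of the single-pass prototype.
#' @return The filtered record, stage `filtered`.
#' @export
bandpass_zero_phase <- function(rec, low = 60, high = 240, order = 4) {
  stopifnot(inherits(rec, "signal_record"))
  if (!(low > 0 && low < high && high < rec$fs / 2))
    stop("invalid band: need 0 < low < high < fs/2")
  bf <- signal::butter(order, c(low, high) / (rec$fs / 2), type = "pass")
  x <- as.numeric(signal::filtfilt(bf, rec$samples))
  advance_record(rec, x, stage = "filtered",
                 log_entry = sprintf("bandpass(%g-%g Hz, order %d, zero-phase)",
                                     low, high, order))
}

# analytic signal via the frequency-domain construction: double the
# positive frequencies, zero the negative ones
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

#' Hilbert envelope
#'
#' Modulus of the analytic signal; carries the slow amplitude modulation of
#' the band-passed EMG.
#'
#' @param rec A [signal_record()] at stage `filtered`.
#' @return The envelope record, stage `envelope` (nonnegative samples).
#' @export
hilbert_envelope <- function(rec) {
  stopifnot(inherits(rec, "signal_record"))
  if (rec$stage != "filtered")
    stop("hilbert_envelope expects a record at stage 'filtered'")
  env <- Mod(analytic_signal(rec$samples))
  advance_record(rec, env, stage = "envelope",
                 log_entry = "hilbert_envelope")
}

#' Decimate an envelope record
#'
#' Anti-alias low-pass (zero-phase, effective 8th order Butterworth with
#' cut-off at 0.8x the target Nyquist) followed by sample picking. The
#' envelope is clamped at zero after filtering since a small undershoot of
#' the low-pass would otherwise break envelope nonnegativity.
#'
#' @param rec A [signal_record()] at stage `envelope`.
#' @param factor Positive integer decimation factor; 1 is the identity.
#' @return Decimated record, stage `decimated_envelope`, `fs = fs/factor`.
#' @export
decimate_envelope <- function(rec, factor = 4) {
  stopifnot(inherits(rec, "signal_record"))
  if (rec$stage != "envelope")
    stop("decimate_envelope expects a record at stage 'envelope'")
  if (length(factor) != 1L || factor < 1 || factor != round(factor))
    stop("factor must be a positive integer")
  factor <- as.integer(factor)
  x <- rec$samples
  if (factor > 1L) {
    cutoff <- 0.8 * (rec$fs / factor / 2)
    bf <- signal::butter(4, cutoff / (rec$fs / 2), type = "low")
    x <- pmax(as.numeric(signal::filtfilt(bf, x)), 0)
    x <- x[seq(1L, length(x), by = factor)]
  }
  advance_record(rec, x, stage = "decimated_envelope", fs = rec$fs / factor,
                 log_entry = sprintf("decimate(factor=%d)", factor))
}

#' Full preprocessing chain
#'
#' Notch -> zero-phase band-pass -> Hilbert envelope -> decimation, in that
#' order. The first and last second of the output are flagged as edge
#' transients (`edge_s = 1`) and excluded from downstream detection.
#'
#' @param rec A raw [signal_record()].
#' @param cfg A [preprocess_config()].
#' @return Record at stage `decimated_envelope` with the processing log.
#' @export
preprocess_emg <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(cfg, "preprocess_config"))
  out <- notch_filter(rec, cfg$notch_freqs)
  out <- bandpass_zero_phase(out, cfg$bandpass_low_hz, cfg$bandpass_high_hz,
                             cfg$butter_order)
  out <- hilbert_envelope(out)
  out <- decimate_envelope(out, cfg$decimation_factor)
  out$edge_s <- 1
  out
}
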