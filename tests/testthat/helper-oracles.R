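# Closed-form oracles and small fixture builders shared across tests.
# Everything here is computed from first principles, independently of the
# package's detection path.

# Expected half-maximum widths of an isolated Gaussian burst measured on
# the smoothed spectrogram: Gaussian-convolution calculus over
# burst envelope (SD s) x wavelet envelope (SD st) x smoothing kernels
# (SDs st/2 in time, sf/2 in frequency).
burst_width_oracle <- function(f0, d, fb = 1, fc = 1) {
  s <- d / (2 * f0 * sqrt(log(2)))     # burst amplitude-envelope SD, s
  st <- (fc / f0) * sqrt(fb / 2)       # wavelet time SD at f0
  sf <- 1 / (2 * pi * st)              # wavelet frequency SD at f0
  sbf <- 1 / (2 * pi * s)              # burst spectral amplitude SD, Hz
  list(
    duration_s = 2 * sqrt(2 * log(2) * ((s^2 + st^2) / 2 + st^2 / 4)),
    bandwidth_hz = 2 * sqrt(2 * log(2) * ((sbf^2 + sf^2) / 2 + sf^2 / 4)))
}

# record with white noise plus one injected burst (center at `onset` s)
burst_in_noise_record <- function(f0, d, amplitude = 60, sigma = 3,
                                  fs = 125, dur = 12, onset = dur / 2) {
  rec <- signal_record(stats::rnorm(round(dur * fs), 0, sigma), fs,
                       stage = "decimated_envelope")
  b <- make_burst(burst_spec(f0, amplitude, d, onset = onset), fs)
  c0 <- round(onset * fs) + 1L
  i0 <- c0 - attr(b, "center_index") + 1L
  idx <- i0:(i0 + length(b) - 1L)
  keep <- idx >= 1L & idx <= length(rec$samples)
  rec$samples[idx[keep]] <- rec$samples[idx[keep]] + b[keep]
  rec
}

# build a wavetrain_cohort directly from simulated per-subject event
# attributes (no signal processing): each subject gets Poisson counts in
# the given frequency bands; the other attributes are drawn iid
simulate_event_cohort <- function(n_control = 10, n_patient = 12,
                                  duration_s = 90,
                                  bands = data.frame(f_lo = 1, f_hi = 50,
                                                     rate = 1),
                                  patient_bands = bands) {
  draw <- function(id, group, bands) {
    rows <- lapply(seq_len(nrow(bands)), function(i) {
      n <- stats::rpois(1, bands$rate[i] * duration_s)
      if (n == 0) return(NULL)
      data.frame(subject_id = id, group = group, arm = "right",
                 muscle = "extensor",
                 t_peak_s = sort(stats::runif(n, 0, duration_s)),
                 f_central_hz = stats::runif(n, bands$f_lo[i], bands$f_hi[i]),
                 psd_max = stats::rlnorm(n, log(50), 0.8),
                 duration_s = NA_real_,
                 duration_periods = stats::runif(n, 0.5, 4),
                 bandwidth_hz = stats::runif(n, 1, 20),
                 rejected_code = NA_character_,
                 stringsAsFactors = FALSE)
    })
    do.call(rbind, rows)
  }
  ids_c <- sprintf("C%02d", seq_len(n_control))
  ids_p <- sprintf("P%02d", seq_len(n_patient))
  events <- rbind(
    do.call(rbind, lapply(ids_c, draw, group = "control", bands = bands)),
    do.call(rbind, lapply(ids_p, draw, group = "patient",
                          bands = patient_bands)))
  events$duration_s <- events$duration_periods / events$f_central_hz
  subjects <- data.frame(subject_id = c(ids_c, ids_p),
                         group = rep(c("control", "patient"),
                                     c(n_control, n_patient)),
                         duration_s = duration_s, stringsAsFactors = FALSE)
  structure(list(events = events, subjects = subjects),
            class = "wavetrain_cohort")
}

# hand-built spectrogram object with a given PSD matrix (regular axes),
# fully valid, marked smoothed - for testing peak finding and measurement
# in isolation
toy_spectrogram <- function(psd, freqs, fs = 100, smoothed = TRUE) {
  nt <- ncol(psd)
  structure(list(psd = psd, freqs = freqs,
                 times = (seq_len(nt) - 1) / fs, fs = fs,
                 fb = 1, fc = 1, smoothed = smoothed,
                 valid_lo = rep(1L, nrow(psd)),
                 valid_hi = rep(nt, nrow(psd)),
                 subject_id = "toy", group = "control", arm = NA,
                 muscle = NA),
            class = "spectrogram")
}

# minimal EDF file written byte-wise from the published header layout:
# one channel, int16 records, physical/digital calibration
write_edf_fixture <- function(path, x, fs, phys_range = c(-500, 500)) {
  spr <- fs                            # one-second records
  n_rec <- length(x) %/% spr
  x <- x[seq_len(n_rec * spr)]
  dig <- c(-32768, 32767)
  gain <- (phys_range[2] - phys_range[1]) / (dig[2] - dig[1])
  dx <- as.integer(round((x - phys_range[1]) / gain + dig[1]))
  con <- file(path, "wb")
  on.exit(close(con))
  pad <- function(s, n) writeChar(formatC(s, width = -n), con, n,
                                  eos = NULL)
  pad("0", 8); pad("test patient", 80); pad("test recording", 80)
  pad("01.01.20", 8); pad("00.00.00", 8)
  pad(as.character(256 + 256), 8)      # header bytes: fixed + 1 signal
  pad("", 44); pad(as.character(n_rec), 8); pad("1", 8); pad("1", 4)
  pad("EMG ch1", 16); pad("AgCl electrode", 80); pad("uV", 8)
  pad(as.character(phys_range[1]), 8); pad(as.character(phys_range[2]), 8)
  pad(as.character(dig[1]), 8); pad(as.character(dig[2]), 8)
  pad("none", 80); pad(as.character(spr), 8); pad("", 32)
  writeBin(dx, con, size = 2, endian = "little")
  invisible(list(digital = dx, gain = gain, phys_min = phys_range[1],
                 dig_min = dig[1]))
}
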