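#' Complex Morlet mother wavelet
#'
#' `psi(x) = (pi*Fb)^(-1/2) * exp(2*pi*i*Fc*x) * exp(-x^2/Fb)` with
#' bandwidth parameter `Fb` and center frequency parameter `Fc` (both
#' dimensionless, both 1 by default). Analysis at frequency `f` uses the
#' scale `a = Fc / f`.
#'
#' @param x Dimensionless argument (time / scale).
#' @param fb,fc Bandwidth and center-frequency parameters (> 0).
#' @return Complex value(s) of the wavelet.
#' @export
morlet <- function(x, fb = 1, fc = 1) {
  stopifnot(fb > 0, fc > 0, all(is.finite(x)))
  (pi * fb)^(-0.5) * exp(2i * pi * fc * x) * exp(-x^2 / fb)
}

#' Time and frequency widths of the wavelet at an analysis frequency
#'
#' The Gaussian envelope of the scaled wavelet has standard deviation
#' `sigma_t(f) = (Fc/f) * sqrt(Fb/2)` seconds in time; the matching
#' spectral width is `sigma_f(f) = 1 / (2*pi*sigma_t(f))` Hz, so
#' `sigma_t * sigma_f = 1/(2*pi)` at every frequency.
#'
#' @param f Analysis frequency in Hz (> 0).
#' @inheritParams morlet
#' @return List with numeric vectors `sigma_t` (s) and `sigma_f` (Hz).
#' @export
wavelet_widths <- function(f, fb = 1, fc = 1) {
  if (any(f <= 0)) stop("analysis frequency must be > 0")
  sigma_t <- (fc / f) * sqrt(fb / 2)
  list(sigma_t = sigma_t, sigma_f = 1 / (2 * pi * sigma_t))
}

#' Expected spectrogram readings: tone peak and noise floor
#'
#' Report the calibration of [cwt_spectrogram()]. The tone-power
#' calibration makes a stationary sinusoid `A*cos(2*pi*f*t)` read its
#' band power `A^2/2` at its own frequency regardless of `f`, so spectral
#' peaks of tones are unbiased on the frequency axis. Under this scaling
#' white noise of variance `sigma^2` reads an expected floor of
#' `2*sigma^2*f / (fs*Fc*sqrt(2*pi*Fb))`, rising with the analysis
#' frequency in proportion to the widening wavelet bandwidth.
#'
#' @param amplitude Tone amplitude (microvolts).
#' @param f Analysis frequency in Hz.
#' @inheritParams morlet
#' @return Expected reading in the spectrogram's power units.
#' @export
tone_peak_psd <- function(amplitude, f = NULL, fb = 1, fc = 1) {
  amplitude^2 / 2
}

#' @rdname tone_peak_psd
#' @param sigma White-noise standard deviation (microvolts).
#' @param fs Sampling rate, Hz.
#' @export
noise_floor_psd <- function(sigma, f, fs, fb = 1, fc = 1) {
  2 * sigma^2 * f / (fs * fc * sqrt(2 * pi * fb))
}

#' Morlet wavelet spectrogram
#'
#' Continuous wavelet transform of a record on a regular frequency grid.
#' For each analysis frequency `f` the signal is cross-correlated (via FFT)
#' with the conjugated, L2-normalized wavelet at scale `a = Fc/f`, and the
#' power row is the squared modulus under the tone-power calibration: a
#' stationary tone of amplitude `A` reads `A^2/2` at its own frequency at
#' every `f`, which keeps tone peaks unbiased along the frequency axis
#' (see [tone_peak_psd()] and [noise_floor_psd()] for the calibration and
#' the implied white-noise floor). Columns within `3*sigma_t(f)` of either
#' record edge - plus any
#' edge region flagged by preprocessing - are excluded from the per-row
#' valid interval (cone of influence).
#'
#' @param rec A [signal_record()] (typically stage `decimated_envelope`) or
#'   a numeric vector (then `fs` must be given).
#' @param fmin,fmax,fstep Frequency grid in Hz; `fmax` must stay below the
#'   Nyquist frequency.
#' @param fb,fc Morlet parameters, see [morlet()].
#' @param fs Sampling rate, only used when `rec` is a plain vector.
#' @return An object of class `spectrogram`: PSD matrix (frequency x time),
#'   axis vectors, per-row valid column intervals and smoothing provenance.
#' @export
cwt_spectrogram <- function(rec, fmin = 0.1, fmax = 50, fstep = 0.1,
                            fb = 1, fc = 1, fs = NULL) {
  if (inherits(rec, "signal_record")) {
    x <- rec$samples
    fs <- rec$fs
    edge_s <- rec$edge_s
    meta <- rec[c("subject_id", "group", "arm", "muscle")]
  } else {
    x <- as.numeric(rec)
    if (is.null(fs)) stop("fs required for plain numeric input")
    edge_s <- 0
    meta <- list(subject_id = NA, group = NA, arm = NA, muscle = NA)
  }
  n <- length(x)
  if (n == 0L) stop("empty signal")
  if (fmax >= fs / 2) stop("fmax must be below the Nyquist frequency")
  freqs <- seq(fmin, fmax, by = fstep)
  nf <- length(freqs)

  sigma_t <- wavelet_widths(freqs, fb, fc)$sigma_t
  # kernel support +/- 6 envelope SD: the truncation step is ~1.5e-8 in
  # amplitude, keeping spectral ripple below the flatness of tone profiles
  # at the top of the frequency grid
  lmax <- ceiling(6 * sigma_t[1L] * fs)          # longest kernel half-width
  nfft <- stats::nextn(n + 2L * lmax + 1L, 2L)
  # analyze the analytic representation (halved so a tone's positive
  # component keeps amplitude A/2): a real signal's negative-frequency
  # image would otherwise fold across Nyquist into the wavelet passband
  # at high analysis frequencies and tilt flat tone profiles
  xa <- analytic_signal(x) / 2
  X <- stats::fft(c(xa, complex(nfft - n)))

  psd <- matrix(0, nf, n)
  for (i in seq_len(nf)) {
    a <- fc / freqs[i]
    L <- ceiling(6 * sigma_t[i] * fs)
    j <- -L:L
    psi <- morlet(j / (fs * a), fb, fc) / sqrt(a)
    nrmsq <- sum(Mod(psi)^2)
    kpad <- complex(nfft)
    kpad[(j %% nfft) + 1L] <- psi
    w <- stats::fft(X * Conj(stats::fft(kpad)), inverse = TRUE)[1:n] / nfft
    psd[i, ] <- 2 * Mod(w)^2 / (fs * nrmsq * a * sqrt(2 * pi * fb))
  }

  cone <- ceiling(pmax(3 * sigma_t, edge_s) * fs)
  valid_lo <- pmin(cone + 1L, n + 1L)            # first valid column per row
  valid_hi <- pmax(n - cone, 0L)                 # last valid column per row

  structure(list(psd = psd, freqs = freqs, times = (seq_len(n) - 1L) / fs,
                 fs = fs, fb = fb, fc = fc, smoothed = FALSE,
                 valid_lo = as.integer(valid_lo),
                 valid_hi = as.integer(valid_hi),
                 subject_id = meta$subject_id, group = meta$group,
                 arm = meta$arm, muscle = meta$muscle),
            class = "spectrogram")
}

#' @export
print.spectrogram <- function(x, ...) {
  cat(sprintf("<spectrogram> %d freqs (%g-%g Hz) x %d times (%.2f s) @ %g Hz\n",
              length(x$freqs), min(x$freqs), max(x$freqs), length(x$times),
              max(x$times), x$fs))
  cat(sprintf("  Morlet Fb=%g Fc=%g, smoothed: %s\n", x$fb, x$fc, x$smoothed))
  invisible(x)
}

#' @export
plot.spectrogram <- function(x, ...) {
  graphics::image(x$times, x$freqs, t(x$psd), col = jet_colors(256),
                  xlab = "time, s", ylab = "frequency, Hz",
                  main = if (x$smoothed) "smoothed spectrogram"
                         else "spectrogram", ...)
  invisible(x)
}

# reflecting index into 1..n
reflect_index <- function(i, n) {
  i <- abs(i - 1L) + 1L
  over <- i > n
  i[over] <- 2L * n - i[over]
  i
}

# centered Gaussian FIR taps truncated at +/- 3 SD, unit sum; sd in samples
gauss_taps <- function(sd) {
  k <- max(1L, ceiling(3 * sd))
  w <- stats::dnorm(-k:k, sd = sd)
  w / sum(w)
}

#' Frequency-adaptive 2D Gaussian smoothing of a spectrogram
#'
#' Smooths away the speckle of the raw squared-modulus spectrogram without
#' distorting its shape: at each analysis frequency the 2D Gaussian kernel
#' has standard deviations equal to half the wavelet's own time and
#' frequency widths at that frequency (`0.5*sigma_t(f)` seconds,
#' `0.5*sigma_f(f)` Hz). Kernels are truncated at +/- 3 SD, normalized to
#' unit sum, and boundaries are handled by reflection, so a constant
#' spectrogram is left unchanged and nonnegativity is preserved.
#'
#' @param sg An unsmoothed `spectrogram`.
#' @return The smoothed spectrogram (`smoothed = TRUE`).
#' @export
adaptive_smooth <- function(sg) {
  stopifnot(inherits(sg, "spectrogram"))
  if (isTRUE(sg$smoothed)) stop("spectrogram is already smoothed")
  psd <- sg$psd
  nf <- nrow(psd)
  nt <- ncol(psd)
  ww <- wavelet_widths(sg$freqs, sg$fb, sg$fc)
  fstep <- if (nf > 1L) sg$freqs[2L] - sg$freqs[1L] else 1
  out <- matrix(0, nf, nt)
  # scatter formulation: every source row is spread with the 2D kernel of
  # its own frequency (the kernel varies with f, so no single separable
  # pass). Spreading - rather than gathering with the output row's kernel
  # - keeps each pixel's energy exactly (unit-sum kernels) and leaves the
  # location of a symmetric peak unbiased; a gather formulation pulls
  # peaks toward higher frequencies, where the kernels widen.
  for (i in seq_len(nf)) {
    # time pass of this source row, with reflect padding
    wt <- gauss_taps(0.5 * ww$sigma_t[i] * sg$fs)
    kt <- (length(wt) - 1L) %/% 2L
    padded <- psd[i, reflect_index((1L - kt):(nt + kt), nt)]
    sm <- stats::filter(padded, wt, sides = 2)
    row <- as.numeric(sm[(kt + 1L):(kt + nt)])
    # spread across neighbouring frequency rows (reflected at the edges)
    wf <- gauss_taps(0.5 * ww$sigma_f[i] / fstep)
    kf <- (length(wf) - 1L) %/% 2L
    rows <- reflect_index(i + (-kf:kf), nf)
    for (k in seq_along(rows))
      out[rows[k], ] <- out[rows[k], ] + wf[k] * row
  }
  # varying kernel widths make the deposited weights per output row sum to
  # slightly more or less than one; renormalizing keeps a constant field
  # exactly invariant
  wsum <- numeric(nf)
  for (i in seq_len(nf)) {
    wf <- gauss_taps(0.5 * ww$sigma_f[i] / fstep)
    kf <- (length(wf) - 1L) %/% 2L
    rows <- reflect_index(i + (-kf:kf), nf)
    for (k in seq_along(rows)) wsum[rows[k]] <- wsum[rows[k]] + wf[k]
  }
  out <- out / wsum
  sg$psd <- out
  sg$smoothed <- TRUE
  sg
}

#' Write / read a spectrogram as delimited text with a JSON sidecar
#'
#' The PSD matrix goes to CSV (rows = frequencies); the axes, grid and
#' calibration parameters go to `<path>.json`.
#'
#' @param sg A `spectrogram`.
#' @param path Output CSV path.
#' @return `read_spectrogram()` returns the restored `spectrogram`.
#' @export
write_spectrogram <- function(sg, path) {
  utils::write.table(sg$psd, path, sep = ",", row.names = FALSE,
                     col.names = FALSE)
  meta <- sg[c("freqs", "times", "fs", "fb", "fc", "smoothed",
               "valid_lo", "valid_hi", "subject_id", "group", "arm",
               "muscle")]
  jsonlite::write_json(meta, paste0(path, ".json"), digits = NA,
                       auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_spectrogram
#' @export
read_spectrogram <- function(path) {
  psd <- as.matrix(utils::read.table(path, sep = ","))
  dimnames(psd) <- NULL
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(c(list(psd = psd), meta), class = "spectrogram")
}
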