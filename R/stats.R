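#' Area under the ROC curve for two groups of rates
#'
#' Probability-of-superiority form with midrank tie handling:
#' `AUC = [#(a_i > b_j) + 0.5 * #(a_i = b_j)] / (n_a * n_b)`, with the
#' patients as the positive class, so `AUC > 0.5` means the wave-train
#' rate is higher in the patients. Equals the midrank Mann-Whitney U
#' statistic divided by `n_a * n_b`, and
#' `roc_auc(a, b) + roc_auc(b, a) = 1` exactly.
#'
#' @param a Rates of the positive class (patients).
#' @param b Rates of the negative class (controls).
#' @return AUC in `[0, 1]`.
#' @export
roc_auc <- function(a, b) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  d <- outer(a, b, "-")
  (sum(d > 0) + 0.5 * sum(d == 0)) / (length(a) * length(b))
}

#' Mann-Whitney U test between two groups
#'
#' Midrank U statistic plus a two-sided p-value: the exact distribution
#' when both groups have at most `exact_max` observations and there are no
#' ties (matching typical tremor-study group sizes of 10-12), otherwise the normal
#' approximation with tie and continuity corrections.
#'
#' @param a,b Numeric vectors (patients, controls).
#' @param exact_max Largest per-group size for which the exact p-value is
#'   used.
#' @return List with `U` (midrank statistic for `a` over `b`), `p`
#'   (two-sided) and `auc` (`U / (n_a * n_b)`).
#' @export
mann_whitney_p <- function(a, b, exact_max = 12L) {
  if (!length(a) || !length(b)) stop("both groups must be nonempty")
  r <- rank(c(a, b))
  u <- sum(r[seq_along(a)]) - length(a) * (length(a) + 1) / 2
  ties <- anyDuplicated(c(a, b)) > 0L
  use_exact <- !ties && length(a) <= exact_max && length(b) <= exact_max
  p <- suppressWarnings(
    stats::wilcox.test(a, b, exact = use_exact, correct = TRUE)$p.value)
  if (is.nan(p)) p <- 1   # all observations tied: no evidence at all
  list(U = u, p = min(p, 1), auc = u / (length(a) * length(b)))
}

#' Number of comparisons in a triangular range-scan diagram
#'
#' A diagram with resolution `R` (rows/columns) has `C = R*(R+1)/2` cells
#' in its upper triangle including the diagonal.
#'
#' @param R Resolution (positive integer, vectorized).
#' @return Comparison count `C`.
#' @export
correction_count <- function(R) {
  if (any(R < 1 | R != round(R))) stop("R must be a positive integer")
  R * (R + 1) / 2
}

#' Sidak-form Bonferroni-corrected alpha level
#'
#' `alpha_B = 1 - (1 - alpha0)^(1/C)`: the level at which each of `C`
#' independent comparisons must be tested for a family-wise error rate of
#' `alpha0`. Slightly less conservative than the classical `alpha0 / C`.
#'
#' @param alpha0 Family-wise error level (default 0.05).
#' @param C Number of comparisons (>= 1, vectorized).
#' @return Corrected per-comparison level.
#' @export
bonferroni_alpha <- function(alpha0 = 0.05, C = 1) {
  stopifnot(alpha0 > 0, alpha0 < 1, all(C >= 1))
  1 - (1 - alpha0)^(1 / C)
}

#' Pearson and Spearman correlation between two rate vectors
#'
#' @param x,y Numeric vectors of equal length >= 3 (e.g. per-subject
#'   wave-train rates in two frequency bands).
#' @return List `pearson_r`, `pearson_p`, `spearman_rho`, `spearman_p`
#'   (two-sided; Spearman p exact for small tie-free samples).
#' @export
correlate_rates <- function(x, y) {
  if (length(x) != length(y) || length(x) < 3L)
    stop("x and y must have equal length >= 3")
  pe <- stats::cor.test(x, y, method = "pearson")
  sp <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(pearson_r = unname(pe$estimate), pearson_p = pe$p.value,
       spearman_rho = unname(sp$estimate), spearman_p = sp$p.value)
}

#' Welch power spectral density
#'
#' Averaged modified periodograms: Hann-windowed overlapping segments,
#' one-sided density scaling (`2|X|^2 / (fs * sum(w^2))`; DC and Nyquist
#' bins not doubled), segment means removed. Defaults match a 10 s window
#' with 7/8 overlap.
#'
#' @param x Numeric signal (typically an EMG envelope).
#' @param fs Sampling rate, Hz.
#' @param window_s Segment length in seconds.
#' @param overlap Fractional overlap between consecutive segments.
#' @return Data frame with `freq` (Hz) and `psd`.
#' @export
welch_psd <- function(x, fs, window_s = 10, overlap = 7 / 8) {
  L <- round(window_s * fs)
  if (length(x) < L) stop("signal shorter than one Welch window")
  step <- max(1L, round(L * (1 - overlap)))
  starts <- seq(1L, length(x) - L + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * (0:(L - 1)) / (L - 1))
  u <- sum(w^2)
  nb <- L %/% 2L + 1L
  acc <- numeric(nb)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * w
    p <- Mod(stats::fft(seg)[1:nb])^2 / (fs * u)
    p[2:(nb - 1L)] <- 2 * p[2:(nb - 1L)]
    acc <- acc + p
  }
  data.frame(freq = (0:(nb - 1L)) * fs / L, psd = acc / length(starts))
}

#' Welch-spectrum group comparison
#'
#' The baseline spectral method: per-subject Welch PSD of the envelope,
#' then a per-frequency-bin Mann-Whitney test between the groups, with an
#' uncorrected significance mask at `alpha0` and a corrected mask at the
#' Sidak-form level for the number of compared bins. The default band of
#' 0.1-25 Hz at the 0.1 Hz bin spacing of a 10 s window yields 250
#' compared bins.
#'
#' @param group_a,group_b Lists of [signal_record()] envelopes (patients,
#'   controls) or numeric vectors; all at the same sampling rate.
#' @param window_s,overlap Welch parameters, see [welch_psd()].
#' @param fmin,fmax Compared frequency band, Hz.
#' @param alpha0 Uncorrected level.
#' @param fs Sampling rate when plain vectors are supplied.
#' @return Object of class `welch_comparison`: per-bin p-values, both
#'   masks, the corrected level `alpha_b`, bin count `C` and the group
#'   mean spectra.
#' @export
welch_group_compare <- function(group_a, group_b, window_s = 10,
                                overlap = 7 / 8, fmin = 0.1, fmax = 25,
                                alpha0 = 0.05, fs = NULL) {
  get_psd <- function(r) {
    if (inherits(r, "signal_record")) welch_psd(r$samples, r$fs, window_s,
                                                overlap)
    else welch_psd(as.numeric(r), fs, window_s, overlap)
  }
  pa <- lapply(group_a, get_psd)
  pb <- lapply(group_b, get_psd)
  freq <- pa[[1L]]$freq
  keep <- freq >= fmin & freq <= fmax
  freq <- freq[keep]
  ma <- vapply(pa, function(d) d$psd[keep], freq)
  mb <- vapply(pb, function(d) d$psd[keep], freq)
  p <- vapply(seq_along(freq), function(i)
    mann_whitney_p(ma[i, ], mb[i, ])$p, 0)
  C <- length(freq)
  ab <- bonferroni_alpha(alpha0, C)
  structure(list(freq = freq, p = p, sig_uncorrected = p <= alpha0,
                 sig_corrected = p <= ab, alpha0 = alpha0, alpha_b = ab,
                 C = C, mean_psd_a = rowMeans(ma), mean_psd_b = rowMeans(mb),
                 n_a = length(pa), n_b = length(pb)),
            class = "welch_comparison")
}

#' @export
print.welch_comparison <- function(x, ...) {
  cat(sprintf("<welch_comparison> %d vs %d subjects, %d bins (%g-%g Hz)\n",
              x$n_a, x$n_b, x$C, min(x$freq), max(x$freq)))
  cat(sprintf("  alpha0 = %g -> corrected %.3g; significant bins: %d (uncorrected %d)\n",
              x$alpha0, x$alpha_b, sum(x$sig_corrected),
              sum(x$sig_uncorrected)))
  invisible(x)
}

#' @export
plot.welch_comparison <- function(x, ...) {
  rng <- range(c(x$mean_psd_a, x$mean_psd_b))
  graphics::plot(x$freq, x$mean_psd_a, type = "l", col = "red", log = "y",
                 ylim = rng, xlab = "frequency, Hz",
                 ylab = "PSD, uV^2/Hz", ...)
  graphics::lines(x$freq, x$mean_psd_b, col = "darkgreen")
  if (any(x$sig_uncorrected))
    graphics::points(x$freq[x$sig_uncorrected],
                     rep(rng[1L], sum(x$sig_uncorrected)), pch = 15,
                     col = "magenta")
  if (any(x$sig_corrected))
    graphics::points(x$freq[x$sig_corrected],
                     rep(rng[1L] * 1.2, sum(x$sig_corrected)), pch = 15,
                     col = "purple")
  invisible(x)
}
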