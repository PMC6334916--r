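# Per-channel time-series descriptor: 9 amplitude statistics, 7 spectral
# band powers, 6 spectral peak locations + 6 heights, and the zero-lag
# autocorrelation height -- 29 features per channel, 174 per phase.

# band edges in Hz; the last band collects everything above 20 Hz up to
# Nyquist and is closed at the top edge
FEATURE_BAND_EDGES <- c(0, 0.5, 1.5, 5, 10, 15, 20)

FEATURE_SUFFIXES <- c(
  "mean", "rms", "skew", "kurtosis", "range", "max", "min", "sd", "peak2rms",
  paste0("band", 1:7, "_power"),
  paste0("peak", 1:6, "_loc"), paste0("peak", 1:6, "_height"),
  "autocorr0_height")

#' Names of the per-phase feature vector
#'
#' @param channels channel names, in canonical order.
#' @return character vector of `<channel>_<feature>` names (174 for the six
#'   kinematic channels).
#' @export
feature_names <- function(channels = KINEMATIC_CHANNEL_NAMES) {
  as.vector(vapply(channels, function(ch) paste(ch, FEATURE_SUFFIXES,
                                                sep = "_"),
                   character(length(FEATURE_SUFFIXES))))
}

# one-sided periodogram of the mean-removed series, rectangular window.
# Power is normalized so the bin powers sum to mean((x - mean(x))^2)
# (Parseval); resolution is rate/N Hz.
periodogram <- function(x, rate) {
  n <- length(x)
  x <- x - mean(x)
  X <- stats::fft(x)
  p <- Mod(X)^2 / n^2
  half <- floor(n / 2)
  k <- seq_len(half)                    # positive-frequency bins
  pw <- 2 * p[k + 1L]
  if (n %% 2L == 0L) pw[half] <- p[half + 1L]  # Nyquist bin is unpaired
  list(freq = k * rate / n, power = pw)
}

#' Signal power within a frequency band
#'
#' Sums the one-sided periodogram of the mean-removed series over bins with
#' frequency in `[f_lo, f_hi)`; when `f_hi` equals the Nyquist frequency the
#' band is closed at the top so the seven canonical bands partition the
#' total power exactly.
#'
#' @param series numeric vector, equally spaced samples.
#' @param rate sampling rate, Hz.
#' @param f_lo,f_hi band edges, Hz, with `0 <= f_lo < f_hi <= rate / 2`.
#' @return the band power (same units as `series` squared).
#' @export
band_power <- function(series, rate, f_lo, f_hi) {
  if (!(f_lo >= 0 && f_lo < f_hi && f_hi <= rate / 2 + 1e-9))
    stop("band edges must satisfy 0 <= f_lo < f_hi <= rate/2")
  pg <- periodogram(series, rate)
  sel <- pg$freq >= f_lo & (pg$freq < f_hi |
                              (f_hi >= rate / 2 - 1e-9 & pg$freq <= f_hi))
  sum(pg$power[sel])
}

#' Locations and heights of the first k spectral peaks
#'
#' Peaks are strict local maxima of the one-sided periodogram of the
#' mean-removed series, ordered by ascending frequency. If fewer than `k`
#' peaks exist the remaining pairs are padded with `(0, 0)`.
#'
#' @inheritParams band_power
#' @param k number of peaks to return.
#' @return a list with numeric vectors `loc` (Hz) and `height` (power),
#'   each of length `k`.
#' @export
spectral_peaks <- function(series, rate, k = 6L) {
  pg <- periodogram(series, rate)
  p <- pg$power
  n <- length(p)
  loc <- numeric(k)
  height <- numeric(k)
  if (n >= 3L) {
    interior <- 2:(n - 1L)
    is_peak <- p[interior] > p[interior - 1L] & p[interior] > p[interior + 1L]
    # ignore floating-point leakage: a maximum must carry non-negligible
    # power relative to the strongest bin
    floor_p <- 1e-12 * max(p)
    is_peak <- is_peak & p[interior] > floor_p
    idx <- interior[is_peak]
    m <- min(k, length(idx))
    if (m > 0L) {
      loc[seq_len(m)] <- pg$freq[idx[seq_len(m)]]
      height[seq_len(m)] <- p[idx[seq_len(m)]]
    }
  }
  list(loc = loc, height = height)
}

#' Zero-lag autocorrelation height
#'
#' The biased autocovariance of the series at lag zero: the mean of squared
#' mean-removed samples (sample variance with divisor N). A normalized
#' autocorrelation would be identically 1 at lag zero and carry no
#' information, so the unnormalized estimator is used.
#'
#' @param series numeric vector.
#' @return nonnegative scalar.
#' @export
autocorr_zero_height <- function(series) {
  if (length(series) == 0L) stop("empty series")
  mean((series - mean(series))^2)
}

#' Extract the 29-feature descriptor of one channel
#'
#' Returns, in fixed order: mean, RMS, skew, kurtosis, range, max, min, SD
#' and peak-to-RMS amplitude; power in the seven canonical frequency bands
#' (0-0.5, 0.5-1.5, 1.5-5, 5-10, 10-15, 15-20 and >20 Hz); locations then
#' heights of the first six periodogram peaks by ascending frequency; and
#' the zero-lag autocorrelation height. Kurtosis is the non-excess moment
#' ratio (3 for a Gaussian); skew and kurtosis of a zero-variance series
#' are mapped to 0, and peak-to-RMS of an all-zero series to 0, so every
#' feature is finite on any input.
#'
#' @inheritParams band_power
#' @return named numeric vector of length 29.
#' @export
extract_channel_features <- function(series, rate) {
  if (length(series) < 2 * rate)
    stop("series must cover at least 2 s of samples")
  if (any(!is.finite(series))) stop("series contains non-finite samples")
  mu <- mean(series)
  centered <- series - mu
  m2 <- mean(centered^2)
  rms <- sqrt(mean(series^2))
  stats9 <- c(
    mean = mu,
    rms = rms,
    skew = if (m2 > 0) mean(centered^3) / m2^1.5 else 0,
    kurtosis = if (m2 > 0) mean(centered^4) / m2^2 else 0,
    range = max(series) - min(series),
    max = max(series),
    min = min(series),
    sd = stats::sd(series),
    peak2rms = if (rms > 0) max(abs(series)) / rms else 0)

  edges <- c(FEATURE_BAND_EDGES, rate / 2)
  bands <- vapply(seq_len(7L), function(b)
    band_power(series, rate, edges[b], edges[b + 1L]), numeric(1))
  names(bands) <- paste0("band", 1:7, "_power")

  pk <- spectral_peaks(series, rate, k = 6L)
  peaks <- c(pk$loc, pk$height)
  names(peaks) <- c(paste0("peak", 1:6, "_loc"), paste0("peak", 1:6, "_height"))

  c(stats9, bands, peaks, autocorr0_height = autocorr_zero_height(series))
}

#' Extract the 174-value feature vector of a phase segment
#'
#' Concatenates the 29-feature descriptor of each of the six kinematic
#' channels in canonical order (`ah`, `av`, `omegah`, `omegav`, `alpha`,
#' `gamma`); names follow the `<channel>_<feature>` scheme of
#' [feature_names()].
#'
#' @param segment a `phase_segment` from [segment_phases()].
#' @return named numeric vector of length 174.
#' @export
extract_phase_features <- function(segment) {
  stopifnot(inherits(segment, "phase_segment"))
  rate <- segment$channels$rate
  out <- lapply(KINEMATIC_CHANNEL_NAMES, function(ch) {
    v <- extract_channel_features(segment$channels[[ch]], rate)
    names(v) <- paste(ch, names(v), sep = "_")
    v
  })
  do.call(c, out)
}
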