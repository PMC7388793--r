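#' Canonical EEG frequency bands
#'
#' The six bands used throughout the pipeline: delta 1-4, theta 4-8,
#' alpha 8-12, low beta 12-18, high beta 18-30 and gamma 30-55 Hz. Band
#' membership is half-open, `[lo, hi)`, so the six bands tile 1-55 Hz
#' without double-counting the shared edges.
#'
#' @return data frame with columns `name`, `lo`, `hi` (Hz).
#' @export
eeg_bands <- function() {
  data.frame(
    name = c("delta", "theta", "alpha", "low_beta", "high_beta", "gamma"),
    lo = c(1, 4, 8, 12, 18, 30),
    hi = c(4, 8, 12, 18, 30, 55),
    stringsAsFactors = FALSE
  )
}

band_lookup <- function(band) {
  bands <- eeg_bands()
  if (is.character(band)) {
    i <- match(band, bands$name)
    if (is.na(i)) stop("unknown band name: ", band)
    return(bands[i, ])
  }
  if (is.data.frame(band)) return(band)
  if (is.numeric(band) && length(band) == 2)
    return(data.frame(name = "custom", lo = band[1], hi = band[2]))
  stop("band must be a name, a (lo, hi) pair, or a row of eeg_bands()")
}

#' Zero-phase Butterworth band-pass filter
#'
#' 3rd-order Butterworth band-pass applied forward and backward (zero phase
#' delay). Signals are filtered along time; a matrix is treated as one signal
#' per row.
#'
#' @param x numeric vector, or matrix with signals in rows
#'   (channels x samples).
#' @param fs sampling rate (Hz).
#' @param band a band name (see [eeg_bands()]), a `c(lo, hi)` pair in Hz, or
#'   a one-row band data frame.
#' @param order filter order per pass (default 3).
#' @return filtered data, same shape as `x`.
#' @export
bandpass_filter <- function(x, fs, band, order = 3) {
  b <- band_lookup(band)
  if (b$hi >= fs / 2)
    stop("band upper edge (", b$hi, " Hz) must be below Nyquist (", fs / 2,
         " Hz)")
  if (b$lo <= 0) stop("band lower edge must be positive")
  d <- butter_design(order, c(b$lo, b$hi) / (fs / 2), "pass")
  apply_rowwise(x, function(m) filtfilt_zi(d$b, d$a, m))
}

#' Zero-phase Butterworth high-pass filter
#'
#' @inheritParams bandpass_filter
#' @param cutoff cutoff frequency in Hz (must be below Nyquist).
#' @return filtered data, same shape as `x`.
#' @export
highpass_signal <- function(x, fs, cutoff, order = 3) {
  if (cutoff <= 0 || cutoff >= fs / 2)
    stop("cutoff must lie in (0, Nyquist)")
  d <- butter_design(order, cutoff / (fs / 2), "high")
  apply_rowwise(x, function(m) filtfilt_zi(d$b, d$a, m))
}

# Run a samples-x-signals operation on row-oriented data.
apply_rowwise <- function(x, f) {
  if (is.null(dim(x))) return(as.numeric(f(matrix(x, ncol = 1))))
  t(f(t(x)))
}

#' Welch power spectral density
#'
#' Welch's averaged periodogram with Hann-windowed segments (1 s long, 50%
#' overlap by default). For a matrix input the PSD is averaged across
#' channels (rows).
#'
#' @param x numeric vector, or channels x samples matrix.
#' @param fs sampling rate (Hz).
#' @param seg_len_s segment length in seconds.
#' @param overlap fractional overlap between consecutive segments.
#' @return list with `freq` (Hz) and `psd` (signal units^2 / Hz, one-sided).
#' @export
welch_psd <- function(x, fs, seg_len_s = 1, overlap = 0.5) {
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  ns <- ncol(x)
  nper <- round(seg_len_s * fs)
  if (ns < nper)
    stop("signal shorter than one Welch segment (", seg_len_s, " s)")
  step <- max(1L, round(nper * (1 - overlap)))
  starts <- seq(1L, ns - nper + 1L, by = step)
  w <- 0.5 - 0.5 * cos(2 * pi * seq_len(nper) / (nper + 1))  # Hann
  scale <- 1 / (fs * sum(w^2))
  nfreq <- nper %/% 2 + 1L
  acc <- numeric(nfreq)
  for (s in starts) {
    seg <- x[, s:(s + nper - 1L), drop = FALSE]
    seg <- seg - rowMeans(seg)
    ft <- stats::mvfft(t(seg * rep(w, each = nrow(seg))))
    p <- rowMeans(Mod(ft[seq_len(nfreq), , drop = FALSE])^2) * scale
    # one-sided: double everything except DC (and Nyquist when nper is even)
    dbl <- rep(2, nfreq); dbl[1] <- 1
    if (nper %% 2 == 0) dbl[nfreq] <- 1
    acc <- acc + p * dbl
  }
  list(freq = (seq_len(nfreq) - 1) * fs / nper, psd = acc / length(starts))
}

#' Band power and relative band power
#'
#' Power is the Welch PSD integrated over the half-open band `[lo, hi)`.
#' Relative power divides by the total power over 1-55 Hz, so the six
#' canonical bands' relative powers sum to one.
#'
#' @inheritParams welch_psd
#' @param band band name, `c(lo, hi)` pair, or band data-frame row.
#' @param psd optional precomputed result of [welch_psd()] (avoids
#'   recomputation when several bands are read from one signal).
#' @return `band_power`: power in signal units^2. `relative_band_power`:
#'   fraction in \[0, 1\].
#' @export
band_power <- function(x, fs, band, psd = NULL) {
  b <- band_lookup(band)
  if (is.null(psd)) psd <- welch_psd(x, fs)
  df <- psd$freq[2] - psd$freq[1]
  sel <- psd$freq >= b$lo & psd$freq < b$hi
  sum(psd$psd[sel]) * df
}

#' @rdname band_power
#' @param total_range frequency range (Hz) whose power is the denominator.
#' @export
relative_band_power <- function(x, fs, band, total_range = c(1, 55),
                                psd = NULL) {
  if (is.null(psd)) psd <- welch_psd(x, fs)
  df <- psd$freq[2] - psd$freq[1]
  tot_sel <- psd$freq >= total_range[1] & psd$freq < total_range[2]
  tot <- sum(psd$psd[tot_sel]) * df
  if (tot <= 0) stop("zero total power in the reference range")
  band_power(x, fs, band, psd = psd) / tot
}
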