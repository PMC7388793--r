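#' Re-reference to the common average
#'
#' Subtracts the instantaneous mean of the non-EOG channels from every
#' non-EOG channel, so the channel mean of the output is zero at every
#' sample. EOG channels are excluded from the average and left untouched.
#'
#' @param raw a [raw_recording()] not already average-referenced.
#' @return the re-referenced [raw_recording()] (`reference = "average"`).
#' @export
rereference_average <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  if (raw$reference == "average")
    stop("recording is already average-referenced")
  ei <- eeg_idx(raw)
  if (length(ei) < 2) stop("average reference needs at least 2 EEG channels")
  m <- colMeans(raw$data[ei, , drop = FALSE])
  raw$data[ei, ] <- sweep(raw$data[ei, , drop = FALSE], 2, m)
  raw$reference <- "average"
  raw
}

#' Zero-phase high-pass filter of a recording
#'
#' 3rd-order Butterworth high-pass, applied forward and backward (zero phase
#' delay) to every channel, removing DC and slow drift. The default 1 Hz
#' cutoff is the conventional resting-state choice.
#'
#' @param raw a [raw_recording()].
#' @param cutoff high-pass cutoff in Hz (default 1).
#' @return the filtered [raw_recording()].
#' @export
highpass_recording <- function(raw, cutoff = 1) {
  stopifnot(inherits(raw, "raw_recording"))
  raw$data <- highpass_signal(raw$data, raw$fs, cutoff)
  raw
}

#' Regress EOG out of the EEG channels
#'
#' Least-squares regression of every EEG channel on all EOG channels
#' (covariance/regression ocular correction): each channel has
#' `sum_k b_k * EOG_k` subtracted, with `b` the per-channel ordinary
#' least-squares coefficients. On the fitted data the output channels are
#' exactly uncorrelated with every EOG channel. A constant-zero EOG channel
#' is skipped with a warning.
#'
#' @param raw a [raw_recording()] with at least one EOG channel.
#' @return the corrected [raw_recording()] (EOG channels unchanged).
#' @export
regress_eog <- function(raw) {
  stopifnot(inherits(raw, "raw_recording"))
  oi <- which(raw$labels %in% raw$eog_channels)
  if (!length(oi)) stop("no EOG channels present")
  E <- t(raw$data[oi, , drop = FALSE])        # samples x n_eog
  keep <- apply(E, 2, function(v) sd(v) > 0)
  if (!all(keep)) {
    warning("skipping constant EOG regressor(s): ",
            paste(raw$labels[oi[!keep]], collapse = ", "))
    E <- E[, keep, drop = FALSE]
  }
  if (!ncol(E)) return(raw)
  Ec <- sweep(E, 2, colMeans(E))
  ei <- eeg_idx(raw)
  Y <- t(raw$data[ei, , drop = FALSE])
  Yc <- sweep(Y, 2, colMeans(Y))
  B <- solve(crossprod(Ec), crossprod(Ec, Yc))  # n_eog x n_eeg
  raw$data[ei, ] <- t(Y - E %*% B)
  raw
}

#' Cut a recording into fixed-length epochs
#'
#' Consecutive, non-overlapping epochs from the first sample; a trailing
#' partial segment is discarded. All epochs start with status `"kept"`.
#'
#' @param raw a [raw_recording()].
#' @param epoch_len_s epoch length in seconds (default 2).
#' @param subject optional subject id carried into error messages.
#' @return an [epoch_set()].
#' @export
epoch_recording <- function(raw, epoch_len_s = 2, subject = NULL) {
  stopifnot(inherits(raw, "raw_recording"))
  len <- round(epoch_len_s * raw$fs)
  n_ep <- floor(ncol(raw$data) / len)
  if (n_ep < 1) stop("recording shorter than one epoch")
  arr <- array(NA_real_, c(n_ep, nrow(raw$data), len))
  for (e in seq_len(n_ep))
    arr[e, , ] <- raw$data[, ((e - 1L) * len + 1L):(e * len)]
  epoch_set(arr, fs = raw$fs, labels = raw$labels,
            eog_channels = raw$eog_channels, epoch_len_s = epoch_len_s,
            subject = subject)
}

#' Reject epochs by amplitude
#'
#' Marks any kept epoch whose absolute amplitude strictly exceeds the
#' threshold on any non-EOG channel as `rejected_amplitude`. An epoch whose
#' maximum is exactly at the threshold is kept ("exceeding" is strict).
#'
#' @param es an [epoch_set()].
#' @param threshold_uV rejection threshold in microvolts (default 75).
#' @return the updated [epoch_set()].
#' @export
reject_amplitude <- function(es, threshold_uV = 75) {
  stopifnot(inherits(es, "epoch_set"), threshold_uV > 0)
  ei <- which(!(es$labels %in% es$eog_channels))
  for (e in kept_epochs(es)) {
    if (max(abs(es$epochs[e, ei, ])) > threshold_uV)
      es$status[e] <- "rejected_amplitude"
  }
  es
}

#' Reject drowsy epochs by the theta/alpha power ratio
#'
#' For each kept epoch, computes channel-averaged Welch band power in theta
#' (4-8 Hz) and alpha (8-12 Hz) over the non-EOG channels and rejects the
#' epoch when theta power strictly exceeds alpha power (ratio > 1), the
#' conventional proxy for sleep-onset EEG. Zero alpha power counts as an
#' infinite ratio (rejected, with a warning).
#'
#' @param es an [epoch_set()].
#' @return the updated [epoch_set()].
#' @export
reject_drowsy <- function(es) {
  stopifnot(inherits(es, "epoch_set"))
  if (es$fs <= 24) stop("sampling rate too low to resolve the alpha band")
  ei <- which(!(es$labels %in% es$eog_channels))
  for (e in kept_epochs(es)) {
    x <- es$epochs[e, ei, , drop = TRUE]
    psd <- welch_psd(x, es$fs)
    th <- band_power(x, es$fs, "theta", psd = psd)
    al <- band_power(x, es$fs, "alpha", psd = psd)
    if (al <= 0) {
      warning("epoch ", e, ": zero alpha power; treating ratio as infinite")
      es$status[e] <- "rejected_drowsy"
    } else if (th / al > 1) {
      es$status[e] <- "rejected_drowsy"
    }
  }
  es
}

#' Select the first n kept epochs
#'
#' Retains the first `n` kept epochs in temporal order; later kept epochs
#' become `not_selected`. Fewer than `n` survivors is an error (naming the
#' subject when the epoch set carries one).
#'
#' @param es an [epoch_set()].
#' @param n number of epochs to keep (default 30).
#' @return the updated [epoch_set()].
#' @export
select_epochs <- function(es, n = 30) {
  stopifnot(inherits(es, "epoch_set"), n >= 1)
  kept <- kept_epochs(es)
  if (length(kept) < n) {
    who <- if (is.null(es$subject)) "subject" else es$subject
    stop("insufficient artifact-free epochs for ", who, ": ", length(kept),
         " kept, ", n, " required")
  }
  if (length(kept) > n) es$status[kept[-seq_len(n)]] <- "not_selected"
  es
}

#' Full preprocessing chain for one subject
#'
#' Average reference, zero-phase high-pass, EOG regression (when EOG
#' channels are present), 2-s epoching, amplitude rejection, drowsiness
#' rejection, and selection of the first `n_epochs` survivors — in that
#' fixed order.
#'
#' @param raw a [raw_recording()].
#' @param epoch_len_s epoch length (s).
#' @param n_epochs number of epochs to retain.
#' @param amp_thresh_uV amplitude rejection threshold (uV).
#' @param highpass_hz high-pass cutoff (Hz).
#' @param subject optional subject id for error messages.
#' @return a screened [epoch_set()].
#' @export
preprocess_subject <- function(raw, epoch_len_s = 2, n_epochs = 30,
                               amp_thresh_uV = 75, highpass_hz = 1,
                               subject = NULL) {
  raw <- rereference_average(raw)
  raw <- highpass_recording(raw, highpass_hz)
  if (length(raw$eog_channels)) raw <- regress_eog(raw)
  es <- epoch_recording(raw, epoch_len_s, subject = subject)
  es <- reject_amplitude(es, amp_thresh_uV)
  es <- reject_drowsy(es)
  select_epochs(es, n_epochs)
}
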