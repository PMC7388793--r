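#' Continuous multichannel EEG recording
#'
#' Lightweight container for a continuous recording: a channels-by-samples
#' numeric matrix (nominally in microvolts), the sampling rate, channel
#' labels, and which labels are electro-oculogram (EOG) channels. EOG
#' channels ride along through the pipeline but are excluded from
#' referencing, artifact screening and source imaging.
#'
#' @param data numeric matrix, channels x samples (microvolts).
#' @param fs sampling rate in Hz.
#' @param labels character vector of unique channel names; defaults to
#'   `"E01"`, `"E02"`, ...
#' @param eog_channels subset of `labels` carrying EOG.
#' @param reference reference tag, `"original"` or `"average"`.
#' @return an object of class `raw_recording`.
#' @export
raw_recording <- function(data, fs, labels = NULL, eog_channels = character(),
                          reference = "original") {
  stopifnot(is.matrix(data), is.numeric(data), fs > 0)
  if (is.null(labels))
    labels <- sprintf("E%02d", seq_len(nrow(data)))
  if (length(labels) != nrow(data))
    stop("need one label per channel")
  if (anyDuplicated(labels)) stop("channel labels must be unique")
  if (!all(eog_channels %in% labels))
    stop("eog_channels must be a subset of labels")
  reference <- match.arg(reference, c("original", "average"))
  rownames(data) <- labels
  structure(list(data = data, fs = fs, labels = labels,
                 eog_channels = eog_channels, reference = reference),
            class = "raw_recording")
}

#' @export
print.raw_recording <- function(x, ...) {
  cat(sprintf("<raw_recording> %d channels x %d samples @ %g Hz (%s reference",
              nrow(x$data), ncol(x$data), x$fs, x$reference))
  if (length(x$eog_channels))
    cat(sprintf("; EOG: %s", paste(x$eog_channels, collapse = ", ")))
  cat(")\n")
  invisible(x)
}

# Indices of the non-EOG (EEG) channels.
eeg_idx <- function(raw) which(!(raw$labels %in% raw$eog_channels))

#' Fixed-length epoch set
#'
#' Epochs cut from a continuous recording, with a per-epoch screening status:
#' `kept`, `rejected_amplitude`, `rejected_drowsy`, or `not_selected`.
#'
#' @param epochs numeric array, n_epochs x channels x samples.
#' @param fs sampling rate (Hz).
#' @param labels,eog_channels channel metadata (see [raw_recording()]).
#' @param epoch_len_s epoch duration in seconds.
#' @param status character vector of per-epoch statuses.
#' @param subject optional subject identifier used in error messages.
#' @return an object of class `epoch_set`.
#' @export
epoch_set <- function(epochs, fs, labels, eog_channels = character(),
                      epoch_len_s, status = NULL, subject = NULL) {
  stopifnot(is.array(epochs), length(dim(epochs)) == 3)
  n <- dim(epochs)[1]
  if (is.null(status)) status <- rep("kept", n)
  ok <- c("kept", "rejected_amplitude", "rejected_drowsy", "not_selected")
  if (length(status) != n || !all(status %in% ok))
    stop("status must assign one of ", paste(ok, collapse = "/"),
         " to every epoch")
  if (dim(epochs)[3] != round(epoch_len_s * fs))
    stop("epoch sample count must equal round(epoch_len_s * fs)")
  structure(list(epochs = epochs, fs = fs, labels = labels,
                 eog_channels = eog_channels, epoch_len_s = epoch_len_s,
                 status = status, subject = subject),
            class = "epoch_set")
}

#' @export
print.epoch_set <- function(x, ...) {
  tab <- table(factor(x$status, levels = c("kept", "rejected_amplitude",
                                           "rejected_drowsy", "not_selected")))
  cat(sprintf("<epoch_set> %d epochs x %d channels x %d samples (%g s @ %g Hz)\n",
              dim(x$epochs)[1], dim(x$epochs)[2], dim(x$epochs)[3],
              x$epoch_len_s, x$fs))
  cat("  status:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "),
      "\n")
  invisible(x)
}

#' Indices of kept epochs
#' @param es an [epoch_set()].
#' @return integer vector of epoch indices with status `"kept"`.
#' @export
kept_epochs <- function(es) which(es$status == "kept")
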