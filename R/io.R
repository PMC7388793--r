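#' Write / read a recording as TSV plus a JSON sidecar header
#'
#' The sample matrix (channels x samples) goes to `<path>.tsv` (no header,
#' tab-separated, one channel per row) and the metadata (sampling rate,
#' channel labels, EOG channels, reference) to `<path>.json`.
#'
#' @param raw a [raw_recording()].
#' @param path file stem (without extension).
#' @return `write_recording`: the stem, invisibly. `read_recording`: the
#'   reconstructed [raw_recording()].
#' @export
write_recording <- function(raw, path) {
  stopifnot(inherits(raw, "raw_recording"))
  utils::write.table(raw$data, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(
    list(fs = raw$fs, labels = raw$labels,
         eog_channels = raw$eog_channels, reference = raw$reference),
    paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  hdr <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  dat <- as.matrix(utils::read.table(paste0(path, ".tsv"), sep = "\t"))
  dimnames(dat) <- NULL
  raw_recording(dat, fs = hdr$fs, labels = hdr$labels,
                eog_channels = as.character(unlist(hdr$eog_channels)),
                reference = hdr$reference)
}

#' Write a simulated cohort to disk
#'
#' One TSV + JSON pair per subject (see [write_recording()]), a
#' `metadata.tsv` table, and a `ground_truth.json` file with the injected
#' drowsy/artifact segment indices.
#'
#' @param cohort result of [simulate_cohort()].
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (sid in names(cohort$recordings))
    write_recording(cohort$recordings[[sid]], file.path(dir, sid))
  utils::write.table(cohort$metadata, file.path(dir, "metadata.tsv"),
                     sep = "\t", row.names = FALSE, quote = FALSE)
  jsonlite::write_json(cohort$ground_truth,
                       file.path(dir, "ground_truth.json"))
  invisible(dir)
}

#' Write a connectivity matrix as TSV with a JSON header
#'
#' @param cm a `conn_matrix` from [plv_matrix()].
#' @param path file stem (without extension).
#' @return the stem, invisibly.
#' @export
write_connectivity <- function(cm, path) {
  stopifnot(inherits(cm, "conn_matrix"))
  utils::write.table(cm$W, paste0(path, ".tsv"), sep = "\t",
                     row.names = FALSE, col.names = FALSE)
  jsonlite::write_json(list(band = cm$band, n_epochs = cm$n_epochs),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
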