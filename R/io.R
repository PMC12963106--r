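#' Read and write ABP waveforms as CSV
#'
#' The interchange format is a two-column CSV (`time_s`, `abp_mmHg`) with a
#' uniform sampling grid; the sampling frequency is recovered from the time
#' column on read (or overridden).
#'
#' @param waveform an `abp_waveform`.
#' @param path file path.
#' @export
write_abp_csv <- function(waveform, path) {
  n <- length(waveform$samples)
  utils::write.csv(data.frame(
    time_s = waveform$start_time_s + (seq_len(n) - 1) / waveform$fs,
    abp_mmHg = waveform$samples), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_abp_csv
#' @param fs sampling frequency; inferred from the time column when `NULL`.
#' @param patient_id identifier attached to the waveform.
#' @return `read_abp_csv` returns an `abp_waveform`.
#' @export
read_abp_csv <- function(path, fs = NULL, patient_id = basename(path)) {
  df <- utils::read.csv(path)
  stopifnot(all(c("time_s", "abp_mmHg") %in% names(df)))
  if (is.null(fs)) {
    dt <- stats::median(diff(df$time_s))
    fs <- round(1 / dt)
  }
  abp_waveform(df$abp_mmHg, fs, start_time_s = df$time_s[1],
               patient_id = patient_id)
}

#' Write ground truth or quality reports as JSON sidecars
#'
#' @param x a list or data.frame (ground truth, severity summary, quality
#'   report, provenance).
#' @param path file path.
#' @export
write_json_sidecar <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(path)
}

#' Write a beats table as CSV
#'
#' @param beats data.frame from [detect_beats()].
#' @param path file path.
#' @export
write_beats_csv <- function(beats, path) {
  utils::write.csv(beats, path, row.names = FALSE)
  invisible(path)
}
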