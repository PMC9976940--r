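#' Multichannel acceleration recording
#'
#' Container for a raw tri-axial cervical accelerometry trace. Channels are
#' stored column-wise; the canonical axis order is anterior-posterior (A-P),
#' superior-inferior (S-I) and medial-lateral (M-L).
#'
#' @param samples numeric matrix (or vector for a single channel), one column
#'   per channel, amplitude in arbitrary sensor units.
#' @param fs sampling rate in Hz.
#' @param channels character vector of axis labels, one per column.
#' @return An object of class `"ues_recording"` with elements `samples`,
#'   `fs` and `channels`.
#' @export
ues_recording <- function(samples, fs,
                          channels = c("A-P", "S-I", "M-L")[seq_len(ncol(samples))]) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix", call. = FALSE)
  stopifnot_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  if (length(channels) != ncol(samples))
    stop("one channel label per column is required", call. = FALSE)
  structure(list(samples = samples, fs = fs, channels = as.character(channels)),
            class = "ues_recording")
}

#' @export
print.ues_recording <- function(x, ...) {
  cat(sprintf("<ues_recording> %d samples x %d channels @ %g Hz (%.1f ms)\n",
              nrow(x$samples), ncol(x$samples), x$fs,
              1000 * nrow(x$samples) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

#' Denoised working-rate signal
#'
#' Output container of [preprocess()]: the cleaned multichannel trace at the
#' working rate together with the ordered provenance of the applied stages.
#'
#' @param samples numeric matrix, one column per channel.
#' @param fs sampling rate in Hz (4000 for the standard chain).
#' @param stages character vector naming the applied stages in order.
#' @param channels axis labels.
#' @return An object of class `"ues_clean"`.
#' @export
ues_clean <- function(samples, fs, stages,
                      channels = c("A-P", "S-I", "M-L")[seq_len(ncol(samples))]) {
  if (is.vector(samples)) samples <- matrix(samples, ncol = 1L)
  stopifnot_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  structure(list(samples = samples, fs = fs, stages = as.character(stages),
                 channels = as.character(channels)),
            class = "ues_clean")
}

#' @export
print.ues_clean <- function(x, ...) {
  cat(sprintf("<ues_clean> %d samples x %d channels @ %g Hz\n",
              nrow(x$samples), ncol(x$samples), x$fs))
  cat("  stages:", paste(x$stages, collapse = " -> "), "\n")
  invisible(x)
}

signal_matrix <- function(x) {
  if (inherits(x, "ues_recording") || inherits(x, "ues_clean")) x$samples
  else if (is.vector(x) && is.numeric(x)) matrix(x, ncol = 1L)
  else if (is.matrix(x)) x
  else stop("expected a recording, matrix or numeric vector", call. = FALSE)
}
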