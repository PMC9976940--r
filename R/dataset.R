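# Conversion of cleaned signals + annotations into fixed-shape model inputs:
# per-frame 66-sample chunks, 90-chunk padded sequences, binary UES-opening
# masks and normalized distension targets.

#' Samples per videofluoroscopy frame
#'
#' `floor(fs / fps)`: the number of signal samples spanned by one VF frame
#' (66 at the working rate of 4 kHz and 60 FPS; the discarded ~0.67
#' sample/frame amounts to under 1 ms over a 90-frame swallow).
#'
#' @param fs signal sampling rate, Hz.
#' @param fps video frame rate, frames/s.
#' @return integer count.
#' @export
samples_per_frame <- function(fs, fps) {
  stopifnot_scalar(fs, "fs", lower = 0, open_lower = TRUE)
  stopifnot_scalar(fps, "fps", lower = 0, open_lower = TRUE)
  as.integer(floor(fs / fps))
}

#' Split a cleaned signal into per-frame chunks
#'
#' Consecutive non-overlapping windows of [samples_per_frame()] samples, one
#' per VF frame; a trailing partial window is dropped. Sequences longer than
#' `max_chunks` frames are truncated (keeping the earliest frames, with a
#' warning); shorter ones are zero-padded at the tail.
#'
#' @param clean an `"ues_clean"` (or numeric matrix plus `fs`).
#' @param fps video frame rate.
#' @param max_chunks fixed sequence length after padding (90 for the
#'   standard 1500 ms @ 60 FPS design).
#' @param fs sampling rate when `clean` is a bare matrix.
#' @return list with `chunks` (array `max_chunks x spf x channels`),
#'   `valid_chunks` (count of unpadded chunks) and `spf`.
#' @export
chunk_signal <- function(clean, fps = 60, max_chunks = 90L, fs = NULL) {
  m <- signal_matrix(clean)
  fs_in <- if (inherits(clean, "ues_clean") || inherits(clean, "ues_recording"))
    clean$fs else fs
  if (is.null(fs_in)) stop("`fs` must be supplied for bare signals",
                           call. = FALSE)
  n <- nrow(m)
  if (n == 0L) stop("empty signal", call. = FALSE)
  spf <- samples_per_frame(fs_in, fps)
  n_valid <- n %/% spf
  if (n_valid < 1L) stop("signal shorter than one frame", call. = FALSE)
  if (n_valid > max_chunks) {
    warning(sprintf("swallow spans %d frames; truncating to the first %d",
                    n_valid, max_chunks), call. = FALSE)
    n_valid <- as.integer(max_chunks)
  }
  nch <- ncol(m)
  chunks <- array(0, dim = c(max_chunks, spf, nch))
  for (t in seq_len(n_valid))
    chunks[t, , ] <- m[((t - 1L) * spf + 1L):(t * spf), ]
  list(chunks = chunks, valid_chunks = as.integer(n_valid), spf = spf)
}

#' Binary UES-opening mask
#'
#' Ones on the 0-based frames `onset..offset` inclusive, zeros elsewhere:
#' the expert-labeled UES opening duration that drives the attention
#' generators.
#'
#' @param onset_frame,offset_frame 0-based VF frame indices,
#'   `0 <= onset <= offset < T`.
#' @param T sequence length in frames.
#' @return numeric 0/1 vector of length `T`.
#' @export
build_ues_mask <- function(onset_frame, offset_frame, T = 90L) {
  if (onset_frame < 0 || offset_frame < onset_frame || offset_frame >= T)
    stop(sprintf("annotation error: need 0 <= onset (%g) <= offset (%g) < T (%g)",
                 onset_frame, offset_frame, T), call. = FALSE)
  mask <- numeric(T)
  mask[(onset_frame:offset_frame) + 1L] <- 1
  mask
}

#' One model-ready swallow sample
#'
#' @param chunks array `T x spf x channels`.
#' @param mask binary vector of length `T`, zero on padded chunks.
#' @param target_ratio normalized distension ground truth in (0, 1].
#' @param valid_chunks number of unpadded chunks.
#' @param id swallow identifier.
#' @return An object of class `"ues_sample"`.
#' @export
swallow_sample <- function(chunks, mask, target_ratio, valid_chunks,
                           id = NA_character_) {
  stopifnot(length(dim(chunks)) == 3L, length(mask) == dim(chunks)[1])
  if (!all(mask %in% c(0, 1)))
    stop("mask entries must be 0 or 1", call. = FALSE)
  if (valid_chunks < dim(chunks)[1] && any(mask[(valid_chunks + 1L):length(mask)] != 0))
    stop("mask must be zero on padded chunks", call. = FALSE)
  if (target_ratio <= 0 || target_ratio > 1)
    stop("`target_ratio` must lie in (0, 1]", call. = FALSE)
  structure(list(chunks = chunks, mask = mask, target_ratio = target_ratio,
                 valid_chunks = as.integer(valid_chunks), id = id),
            class = "ues_sample")
}

#' @export
print.ues_sample <- function(x, ...) {
  d <- dim(x$chunks)
  cat(sprintf("<ues_sample> %s: %d x %d x %d chunks (%d valid), UES-open frames %d, target %.3f\n",
              x$id, d[1], d[2], d[3], x$valid_chunks, sum(x$mask),
              x$target_ratio))
  invisible(x)
}

#' Assemble model-ready samples from a manifest
#'
#' Joins each manifest row to its cleaned signal and target: chunks the
#' signal, builds the UES-opening mask from the annotated frames, and
#' attaches the normalized distension target. Targets above 1 are clipped to
#' 1 with a warning (ratios above one are not physiologic for this
#' normalization); rows whose annotations fall outside the recorded frames,
#' or with missing signals/targets, are skipped with a logged reason.
#'
#' @param manifest data.frame with columns `swallow_id`, `onset_frame`,
#'   `offset_frame`, `fps` and `truth_ratio` (see [generate_dataset()]).
#' @param signals named list of `"ues_clean"` objects keyed by swallow id,
#'   or `NULL` to read `manifest$path` signal files.
#' @param targets optional named numeric vector overriding
#'   `manifest$truth_ratio` (e.g. geometric measurements).
#' @param max_chunks fixed sequence length.
#' @return list of [swallow_sample()] objects; skipped rows are recorded in
#'   the `"skipped"` attribute (data.frame of id, reason).
#' @export
assemble <- function(manifest, signals = NULL, targets = NULL,
                     max_chunks = 90L) {
  out <- list()
  skipped <- data.frame(id = character(0), reason = character(0))
  skip <- function(id, reason) {
    message(sprintf("skipping %s: %s", id, reason))
    skipped[nrow(skipped) + 1L, ] <<- c(id, reason)
  }
  for (i in seq_len(nrow(manifest))) {
    row <- manifest[i, ]
    id <- row$swallow_id
    sig <- if (!is.null(signals)) signals[[id]]
           else if (!is.na(row$path) && file.exists(row$path)) read_signal(row$path)
           else NULL
    if (is.null(sig)) { skip(id, "missing signal"); next }
    target <- if (!is.null(targets)) unname(targets[id]) else row$truth_ratio
    if (is.null(target) || is.na(target)) { skip(id, "missing target"); next }
    if (target > 1) {
      warning(sprintf("%s: measured ratio %.3f exceeds 1; clipping", id, target),
              call. = FALSE)
      target <- 1
    }
    if (target <= 0) { skip(id, "non-positive target"); next }
    if (row$offset_frame >= max_chunks) {
      skip(id, sprintf("offset frame %d beyond the %d-frame window",
                       row$offset_frame, max_chunks))
      next
    }
    ch <- tryCatch(chunk_signal(sig, fps = row$fps, max_chunks = max_chunks),
                   error = function(e) conditionMessage(e))
    if (is.character(ch)) { skip(id, ch); next }
    if (row$offset_frame >= ch$valid_chunks) {
      skip(id, "annotation extends beyond recorded frames")
      next
    }
    mask <- build_ues_mask(row$onset_frame, row$offset_frame, max_chunks)
    out[[id]] <- swallow_sample(ch$chunks, mask, target, ch$valid_chunks, id)
  }
  attr(out, "skipped") <- skipped
  out
}
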