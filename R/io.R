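# Plain-text I/O for signals, manifests, landmark sets and noise-model
# sidecars. All formats are delimited or key-value text so artifacts stay
# portable and diffable.

#' Write / read a multichannel signal file
#'
#' Signals are stored as whitespace-delimited columns (one per channel) with
#' `#`-prefixed header lines carrying the sampling rate and channel labels.
#'
#' @param rec an `"ues_recording"` or `"ues_clean"` object.
#' @param path file path.
#' @return `write_signal()` returns `path` invisibly; `read_signal()`
#'   returns an `"ues_recording"`.
#' @export
write_signal <- function(rec, path) {
  m <- signal_matrix(rec)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(sprintf("# fs %.10g", rec$fs),
               paste("# channels", paste(rec$channels, collapse = " "))), con)
  utils::write.table(format(m, digits = 10, trim = TRUE, scientific = TRUE),
                     con, row.names = FALSE, col.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  hdr <- readLines(path, n = 2L)
  fs <- as.numeric(sub("^# fs ", "", hdr[1]))
  channels <- strsplit(sub("^# channels ", "", hdr[2]), " ")[[1]]
  m <- as.matrix(utils::read.table(path, comment.char = "#"))
  dimnames(m) <- NULL
  ues_recording(m, fs, channels)
}

#' Write / read a dataset manifest
#'
#' Tab-delimited table with one row per swallow: `swallow_id`, `path`,
#' `landmark_path`, `onset_frame`, `offset_frame`, `fps`, `truth_ratio`.
#'
#' @param manifest a data.frame as produced by [generate_dataset()].
#' @param path file path.
#' @export
write_manifest <- function(manifest, path) {
  utils::write.table(manifest, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

#' Write / read landmark files
#'
#' Structured text: one block per frame starting with `frame <index>`,
#' followed by `name x y` lines for each named 2-D point.
#'
#' @param landmarks a single [landmark_set()] or a list of them.
#' @param path file path.
#' @export
write_landmarks <- function(landmarks, path) {
  if (inherits(landmarks, "ues_landmarks")) landmarks <- list(landmarks)
  con <- file(path, "w")
  on.exit(close(con))
  for (lm in landmarks) {
    writeLines(sprintf("frame %d", lm$frame_index), con)
    for (nm in c("c2_ai", "c3_as", "c3_ai", "c4_ai", "tracheal_notch",
                 "ues_anterior", "ues_posterior")) {
      p <- lm[[nm]]
      writeLines(sprintf("%s %.10g %.10g", nm, p[1], p[2]), con)
    }
  }
  invisible(path)
}

#' @rdname write_landmarks
#' @export
read_landmarks <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  starts <- grep("^frame ", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    blk <- lines[starts[i]:ends[i]]
    idx <- as.integer(sub("^frame ", "", blk[1]))
    pts <- list()
    for (ln in blk[-1]) {
      tok <- strsplit(ln, "[[:space:]]+")[[1]]
      pts[[tok[1]]] <- as.numeric(tok[2:3])
    }
    out[[i]] <- landmark_set(c2_ai = pts$c2_ai, c3_as = pts$c3_as,
                             c3_ai = pts$c3_ai, c4_ai = pts$c4_ai,
                             tracheal_notch = pts$tracheal_notch,
                             ues_anterior = pts$ues_anterior,
                             ues_posterior = pts$ues_posterior,
                             frame_index = idx)
  }
  out
}

#' Write / read a device-noise model sidecar
#'
#' Key-value text: AR order, coefficients and the BIC score of the selected
#' model, so a preprocessing run is reproducible from files alone.
#'
#' @param model an [ar_noise_model()] or a list of them (one per channel).
#' @param path file path.
#' @export
write_noise_model <- function(model, path) {
  if (inherits(model, "ues_ar_model")) model <- list(model)
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(model)) {
    m <- model[[i]]
    writeLines(c(sprintf("channel %d", i),
                 sprintf("order %d", m$order),
                 paste("coefficients",
                       paste(sprintf("%.12g", m$coefficients), collapse = " ")),
                 sprintf("bic %.12g", m$bic)), con)
  }
  invisible(path)
}

#' @rdname write_noise_model
#' @export
read_noise_model <- function(path) {
  lines <- readLines(path)
  starts <- grep("^channel ", lines)
  ends <- c(starts[-1] - 1L, length(lines))
  out <- vector("list", length(starts))
  for (i in seq_along(starts)) {
    blk <- lines[starts[i]:ends[i]]
    coef_ln <- sub("^coefficients ", "", grep("^coefficients", blk, value = TRUE))
    a <- as.numeric(strsplit(coef_ln, " ")[[1]])
    bic <- as.numeric(sub("^bic ", "", grep("^bic", blk, value = TRUE)))
    out[[i]] <- ar_noise_model(a, bic = bic)
  }
  if (length(out) == 1L) out[[1]] else out
}
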