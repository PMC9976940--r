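# Videofluoroscopic landmark geometry: converts per-frame 2-D pixel
# landmarks into the C2C4-normalized anterior-posterior UES opening
# distension. Coordinates are treated as abstract Euclidean points (0-based
# pixel centers, y increasing downward in the image convention); every
# measurement below is built from rotation/translation-invariant operations,
# so axis polarity only affects I/O, never the measured ratio.

#' Per-frame landmark set
#'
#' Named 2-D pixel points for one videofluoroscopy frame: the
#' anterior-inferior corners of C2 and C4 (the pseudo-vertical axis), the
#' anterior-superior/-inferior corners of C3 (its height standardizes the
#' UES region), the tracheal-notch anchor, and the marked anterior and
#' posterior UES wall points.
#'
#' @param c2_ai,c3_as,c3_ai,c4_ai,tracheal_notch,ues_anterior,ues_posterior
#'   numeric length-2 vectors `c(x, y)`.
#' @param frame_index VF frame number (0-based).
#' @return An object of class `"ues_landmarks"`.
#' @export
landmark_set <- function(c2_ai, c3_as, c3_ai, c4_ai, tracheal_notch,
                         ues_anterior, ues_posterior, frame_index = 0) {
  pts <- list(c2_ai = c2_ai, c3_as = c3_as, c3_ai = c3_ai, c4_ai = c4_ai,
              tracheal_notch = tracheal_notch, ues_anterior = ues_anterior,
              ues_posterior = ues_posterior)
  for (nm in names(pts)) {
    p <- pts[[nm]]
    if (!is.numeric(p) || length(p) != 2L || !all(is.finite(p)))
      stop(sprintf("landmark `%s` must be a finite 2-D point", nm),
           call. = FALSE)
  }
  if (all(c2_ai == c4_ai))
    stop("C2 and C4 anterior-inferior corners coincide: pseudo-axis undefined",
         call. = FALSE)
  structure(c(pts, list(frame_index = as.integer(frame_index))),
            class = "ues_landmarks")
}

#' @export
print.ues_landmarks <- function(x, ...) {
  cat(sprintf("<ues_landmarks> frame %d\n", x$frame_index))
  for (nm in c("c2_ai", "c3_as", "c3_ai", "c4_ai", "tracheal_notch",
               "ues_anterior", "ues_posterior"))
    cat(sprintf("  %-14s (%.2f, %.2f)\n", nm, x[[nm]][1], x[[nm]][2]))
  invisible(x)
}

#' C2-C4 pseudo-vertical axis
#'
#' Unit direction from the C2 anterior-inferior corner to the C4
#' anterior-inferior corner, and the Euclidean segment length. The length
#' doubles as the anatomical scalar for the subject's height used to
#' normalize distension.
#'
#' @param lm a [landmark_set()].
#' @return list with `direction` (unit 2-vector) and `length` (px).
#' @export
c2c4_axis <- function(lm) {
  v <- lm$c4_ai - lm$c2_ai
  len <- sqrt(sum(v^2))
  if (len == 0)
    stop("degenerate C2-C4 axis: corners coincide", call. = FALSE)
  list(direction = v / len, length = len)
}

#' C3 vertebral height
#'
#' Euclidean distance between the anterior-superior and anterior-inferior
#' corners of C3; it standardizes the superior/inferior extent of the UES
#' region.
#'
#' @param lm a [landmark_set()].
#' @return height in px.
#' @export
c3_height <- function(lm) {
  h <- sqrt(sum((lm$c3_as - lm$c3_ai)^2))
  if (h == 0)
    stop("degenerate C3 height: corners coincide", call. = FALSE)
  h
}

#' Anchor the C3-height segment at the tracheal notch
#'
#' Repositions a segment of length [c3_height()] so it starts at the
#' tracheal notch and extends inferiorly, parallel to the C2-C4 axis
#' direction (C2 toward C4).
#'
#' @param lm a [landmark_set()].
#' @return list with `from` and `to` 2-D points.
#' @export
anchor_c3_segment <- function(lm) {
  ax <- c2c4_axis(lm)
  h <- c3_height(lm)
  list(from = lm$tracheal_notch, to = lm$tracheal_notch + h * ax$direction)
}

#' Anterior-posterior measurement axis
#'
#' The line perpendicular to the C2-C4 axis passing through the point at
#' fraction `t` along the anchored C3 segment; distension is measured along
#' its direction rather than along an arbitrary horizontal, which
#' compensates for head and neck rotation.
#'
#' @param anchored segment from [anchor_c3_segment()].
#' @param t fraction in `[0, 1]` along the anchored segment.
#' @param axis_dir unit direction of the C2-C4 axis.
#' @return list with `point` and unit `direction`.
#' @export
ap_axis <- function(anchored, t, axis_dir) {
  stopifnot_scalar(t, "t", lower = 0, upper = 1)
  point <- anchored$from + t * (anchored$to - anchored$from)
  list(point = point, direction = c(-axis_dir[2], axis_dir[1]))
}

#' A-P separation of the UES wall points
#'
#' Absolute scalar separation of the anterior and posterior wall points'
#' projections onto the A-P direction.
#'
#' @param anterior,posterior 2-D points.
#' @param ap_line line from [ap_axis()].
#' @return distension in px.
#' @export
measure_distension <- function(anterior, posterior, ap_line) {
  abs(sum((anterior - posterior) * ap_line$direction))
}

#' Measure one frame's landmark set
#'
#' Runs the full per-frame protocol: C2-C4 axis, C3 height, anchored
#' segment, A-P axis at fraction `t`, wall-point projection.
#'
#' @param lm a [landmark_set()].
#' @param t A-P axis position along the anchored segment.
#' @return An object of class `"ues_measurement"`: `distension_px`,
#'   `c2c4_len_px`, `normalized_ratio`, `frame_index`.
#' @export
measure_frame <- function(lm, t = 0.5) {
  ax <- c2c4_axis(lm)
  seg <- anchor_c3_segment(lm)
  line <- ap_axis(seg, t, ax$direction)
  d <- measure_distension(lm$ues_anterior, lm$ues_posterior, line)
  structure(list(distension_px = d, c2c4_len_px = ax$length,
                 normalized_ratio = d / ax$length,
                 frame_index = lm$frame_index),
            class = "ues_measurement")
}

#' @export
print.ues_measurement <- function(x, ...) {
  cat(sprintf("<ues_measurement> frame %d: %.2f px / C2C4 %.2f px = ratio %.4f\n",
              x$frame_index, x$distension_px, x$c2c4_len_px,
              x$normalized_ratio))
  invisible(x)
}

#' Normalized maximal distension across measured frames
#'
#' Combines the per-frame distensions measured around the frame of maximal
#' hyoid displacement (5-7 frames in the protocol) into one C2C4-normalized
#' value. The default takes the maximum across frames (it is a *maximal*
#' distension); `method = "mean"` is available since the protocol's
#' combining rule across frames is not fully pinned down.
#'
#' @param per_frame list of `"ues_measurement"` objects, or a numeric vector
#'   of per-frame distensions in px.
#' @param c2c4_len C2-C4 segment length in px, positive.
#' @param method `"max"` (default) or `"mean"`.
#' @return dimensionless ratio.
#' @export
normalized_max_distension <- function(per_frame, c2c4_len,
                                      method = c("max", "mean")) {
  method <- match.arg(method)
  if (length(per_frame) == 0)
    stop("no measured frames supplied", call. = FALSE)
  stopifnot_scalar(c2c4_len, "c2c4_len", lower = 0, open_lower = TRUE)
  d <- if (is.numeric(per_frame)) per_frame
       else vapply(per_frame, `[[`, numeric(1), "distension_px")
  agg <- if (method == "max") max(d) else mean(d)
  agg / c2c4_len
}

#' Measure a landmark series end-to-end
#'
#' Convenience wrapper: measures each frame with [measure_frame()] and
#' combines them with [normalized_max_distension()], normalizing by the
#' C2-C4 length of the frame that attains the maximum.
#'
#' @param landmarks list of [landmark_set()] objects (one per frame).
#' @param t A-P axis position along the anchored segment.
#' @param method combining rule across frames.
#' @return list with `ratio`, `per_frame` (data.frame of frame, distension,
#'   C2C4 length, ratio).
#' @export
measure_landmarks <- function(landmarks, t = 0.5, method = c("max", "mean")) {
  method <- match.arg(method)
  if (inherits(landmarks, "ues_landmarks")) landmarks <- list(landmarks)
  ms <- lapply(landmarks, measure_frame, t = t)
  tab <- data.frame(
    frame = vapply(ms, `[[`, integer(1), "frame_index"),
    distension_px = vapply(ms, `[[`, numeric(1), "distension_px"),
    c2c4_px = vapply(ms, `[[`, numeric(1), "c2c4_len_px"),
    ratio = vapply(ms, `[[`, numeric(1), "normalized_ratio"))
  ratio <- if (method == "max") max(tab$ratio) else mean(tab$ratio)
  list(ratio = ratio, per_frame = tab)
}
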