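#' Simulation specification for synthetic swallows
#'
#' Bundles every tunable of the synthetic swallow generator. A synthetic
#' swallow is a tri-axial recording built from four planted components:
#' a band-limited vibration burst confined to the UES-open window whose
#' per-channel in-window RMS follows the strictly monotone mapping
#' `a0 + a1 * truth_ratio`; slow motion drift (a sinusoid below 1 Hz plus an
#' integrated-white-noise walk); stationary AR-coloured device noise; and
#' broadband white noise. Each component exists to exercise one stage of the
#' cleaning chain, and the monotone burst mapping gives the regression
#' network a recoverable planted effect.
#'
#' @param n_swallows number of swallows for [generate_dataset()].
#' @param fs_raw acquisition sampling rate in Hz.
#' @param fs_work working sampling rate in Hz after decimation.
#' @param fps videofluoroscopy frame rate (frames/s).
#' @param duration_range swallow duration range in ms.
#' @param distension_range range of the planted distension ratio, inside (0,1).
#' @param burst_gain length-2 vector `c(a0, a1)`: offset and slope of the
#'   ratio-to-RMS mapping; `a1` must be positive (strict monotonicity).
#' @param burst_band passband of the vibration burst in Hz.
#' @param drift_freq sinusoidal drift frequency in Hz (below 1 Hz).
#' @param drift_amp drift amplitude (sensor units); 0 disables drift.
#' @param ar_coeffs autoregressive coefficients of the device noise
#'   (order at most 10, stationary); `NULL` disables.
#' @param ar_sd innovation standard deviation of the device noise.
#' @param noise_sd broadband white-noise standard deviation.
#' @param c2c4_len_px planted C2-C4 segment length for landmark synthesis, px.
#' @param lm_frames landmark frames synthesised per swallow (protocol: 5-7).
#' @param seed master seed; all per-swallow seeds derive from it.
#' @return An object of class `"ues_sim_spec"`.
#' @seealso [generate_swallow()], [generate_dataset()], [generate_landmarks()]
#' @export
sim_spec <- function(n_swallows = 434,
                     fs_raw = 20000,
                     fs_work = 4000,
                     fps = 60,
                     duration_range = c(300, 1500),
                     distension_range = c(0.2, 0.8),
                     burst_gain = c(a0 = 0.2, a1 = 1.0),
                     burst_band = c(60, 300),
                     drift_freq = 0.3,
                     drift_amp = 0.5,
                     ar_coeffs = default_ar_coeffs(),
                     ar_sd = 0.05,
                     noise_sd = 0.05,
                     c2c4_len_px = 100,
                     lm_frames = 5,
                     seed = 1) {
  stopifnot_scalar(n_swallows, "n_swallows", lower = 1)
  stopifnot_scalar(fs_raw, "fs_raw", lower = 0, open_lower = TRUE)
  stopifnot_scalar(fs_work, "fs_work", lower = 0, open_lower = TRUE)
  stopifnot_scalar(fps, "fps", lower = 0, open_lower = TRUE)
  if (length(distension_range) != 2L ||
      distension_range[1] <= 0 || distension_range[2] >= 1 ||
      diff(distension_range) < 0)
    stop("`distension_range` must lie within the open interval (0, 1)",
         call. = FALSE)
  if (length(burst_gain) != 2L || burst_gain[2] <= 0)
    stop("`burst_gain` must be c(a0, a1) with a1 > 0 (strictly monotone burst mapping)",
         call. = FALSE)
  stopifnot_scalar(drift_freq, "drift_freq", lower = 0, upper = 1,
                   open_upper = TRUE)
  if (!is.null(ar_coeffs) && length(ar_coeffs) > 0) {
    if (length(ar_coeffs) > 10)
      stop("device-noise AR order is capped at 10", call. = FALSE)
    if (!ar_is_stationary(ar_coeffs))
      stop("`ar_coeffs` define a non-stationary AR model", call. = FALSE)
  }
  structure(list(n_swallows = as.integer(n_swallows), fs_raw = fs_raw,
                 fs_work = fs_work, fps = fps,
                 duration_range = duration_range,
                 distension_range = distension_range,
                 burst_gain = unname(burst_gain), burst_band = burst_band,
                 drift_freq = drift_freq, drift_amp = drift_amp,
                 ar_coeffs = ar_coeffs, ar_sd = ar_sd, noise_sd = noise_sd,
                 c2c4_len_px = c2c4_len_px, lm_frames = as.integer(lm_frames),
                 seed = as.integer(seed)),
            class = "ues_sim_spec")
}

#' Default device-noise AR coefficients
#'
#' A stationary AR(10) built from fixed pole pairs: damped resonances at
#' about 1.2, 3, 6 and 8.5 kHz (at the 20 kHz acquisition rate) over two
#' broad real poles. The resonances sit above the swallow vibration band
#' (below ~300 Hz), emulating electronic self-noise that the whitening
#' stage can flatten without erasing physiological content.
#'
#' @return numeric vector `a1..a10` in the convention
#'   `x[t] = sum(a[i] * x[t-i]) + e[t]`.
#' @export
default_ar_coeffs <- function() {
  fs <- 20000
  poles <- c(
    0.92 * exp(2i * pi * 1200 / fs), 0.92 * exp(-2i * pi * 1200 / fs),
    0.85 * exp(2i * pi * 3000 / fs), 0.85 * exp(-2i * pi * 3000 / fs),
    0.5, 0.3,
    0.6 * exp(2i * pi * 6000 / fs), 0.6 * exp(-2i * pi * 6000 / fs),
    0.4 * exp(2i * pi * 8500 / fs), 0.4 * exp(-2i * pi * 8500 / fs)
  )
  # monic polynomial prod(1 - p/z); coefficients of z^-1..z^-10 negated
  coefs <- 1
  for (p in poles) coefs <- c(coefs, 0) - c(0, p * coefs)
  a <- -Re(coefs[-1])
  a
}

ar_is_stationary <- function(a) {
  # roots of z^p - a1 z^(p-1) - ... - ap; ascending coefficient order
  r <- polyroot(c(-rev(a), 1))
  all(Mod(r) < 1)
}

tukey_window <- function(n, alpha = 0.5) {
  if (n == 1L) return(1)
  t <- seq(0, 1, length.out = n)
  w <- rep(1, n)
  edge <- alpha / 2
  lo <- t < edge
  hi <- t > 1 - edge
  w[lo] <- 0.5 * (1 + cos(pi * (2 * t[lo] / alpha - 1)))
  w[hi] <- 0.5 * (1 + cos(pi * (2 * (1 - t[hi]) / alpha - 1)))
  w
}

# Ideal band-pass white noise via FFT bin masking (exactly band-limited).
bandlimited_noise <- function(n, fs, band) {
  x <- stats::rnorm(n)
  f <- (seq_len(n) - 1) / n * fs
  f <- pmin(f, fs - f)
  keep <- f >= band[1] & f <= band[2]
  if (!any(keep)) return(numeric(n))
  Re(stats::fft(stats::fft(x) * keep, inverse = TRUE)) / n
}

#' Generate one synthetic swallow with planted ground truth
#'
#' Produces a tri-axial recording at the acquisition rate composed of a
#' band-limited burst confined to the UES-open frame window (per-channel
#' in-window RMS exactly `a0 + a1 * truth_ratio`), low-frequency drift,
#' AR-coloured device noise and white noise, together with a landmark series
#' whose geometric measurement recovers `truth_ratio`. Deterministic given
#' `seed`.
#'
#' @param spec a [sim_spec()].
#' @param truth_ratio planted C2C4-normalized distension ratio, in (0, 1).
#' @param seed integer seed for this swallow.
#' @return An object of class `"ues_synth_swallow"`: a list with `recording`
#'   (class `"ues_recording"`), `truth_ratio`, `onset_frame`/`offset_frame`
#'   (0-based VF frames), `fps`, `n_frames`, `landmarks` (list of
#'   [landmark_set()] objects) and `components` (the planted burst, drift,
#'   device and white matrices, for oracle checks).
#' @export
generate_swallow <- function(spec, truth_ratio, seed = spec$seed) {
  stopifnot(inherits(spec, "ues_sim_spec"))
  if (!is.numeric(truth_ratio) || length(truth_ratio) != 1L ||
      truth_ratio <= 0 || truth_ratio >= 1)
    stop("`truth_ratio` must lie in the open interval (0, 1)", call. = FALSE)
  with_seed(seed, {
    dur_ms <- stats::runif(1, spec$duration_range[1], spec$duration_range[2])
    n <- floor(dur_ms / 1000 * spec$fs_raw)
    n_frames <- max(3L, floor(dur_ms / 1000 * spec$fps))
    # UES window strictly inside the frame span (0-based frames)
    open_frames <- max(1L, round(stats::runif(1, 0.2, 0.5) * n_frames))
    open_frames <- min(open_frames, n_frames - 2L)
    onset <- sample(seq_len(n_frames - open_frames - 1L), 1L)
    offset <- onset + open_frames - 1L

    s_lo <- floor(onset / spec$fps * spec$fs_raw) + 1L
    s_hi <- min(n, floor((offset + 1) / spec$fps * spec$fs_raw))
    win <- s_lo:s_hi
    env <- numeric(n)
    env[win] <- tukey_window(length(win), alpha = 0.5)

    target_rms <- spec$burst_gain[1] + spec$burst_gain[2] * truth_ratio
    nch <- 3L
    burst <- drift <- device <- white <- matrix(0, n, nch)
    tt <- (seq_len(n) - 1) / spec$fs_raw
    for (ch in seq_len(nch)) {
      b <- bandlimited_noise(n, spec$fs_raw, spec$burst_band) * env
      r0 <- rms(b[win])
      if (r0 > 0) b <- b * (target_rms / r0)
      burst[, ch] <- b
      if (spec$drift_amp > 0) {
        ph <- stats::runif(1, 0, 2 * pi)
        walk <- cumsum(stats::rnorm(n))
        sw <- stats::sd(walk)
        if (sw > 0) walk <- walk / sw * spec$drift_amp
        drift[, ch] <- spec$drift_amp * sin(2 * pi * spec$drift_freq * tt + ph) + walk
      }
      if (!is.null(spec$ar_coeffs) && length(spec$ar_coeffs) > 0 && spec$ar_sd > 0) {
        device[, ch] <- as.numeric(stats::filter(
          stats::rnorm(n, sd = spec$ar_sd), spec$ar_coeffs,
          method = "recursive"))
      }
      if (spec$noise_sd > 0) white[, ch] <- stats::rnorm(n, sd = spec$noise_sd)
    }
    samples <- burst + drift + device + white
    lm_seed <- sample.int(.Machine$integer.max, 1L)
    landmarks <- generate_landmark_series(truth_ratio, spec$c2c4_len_px,
                                          n_frames = spec$lm_frames,
                                          seed = lm_seed)
    structure(list(
      recording = ues_recording(samples, spec$fs_raw),
      truth_ratio = truth_ratio,
      onset_frame = as.integer(onset), offset_frame = as.integer(offset),
      fps = spec$fps, n_frames = as.integer(n_frames),
      landmarks = landmarks,
      components = list(burst = burst, drift = drift,
                        device = device, white = white)),
      class = "ues_synth_swallow")
  })
}

#' @export
print.ues_synth_swallow <- function(x, ...) {
  cat(sprintf("<ues_synth_swallow> truth ratio %.3f, UES frames %d-%d of %d @ %g FPS\n",
              x$truth_ratio, x$onset_frame, x$offset_frame, x$n_frames, x$fps))
  print(x$recording)
  invisible(x)
}

#' Generate a zero-input (device noise only) recording
#'
#' Emulates recording the sensor with no physiological input: AR-coloured
#' device noise plus broadband white noise at the acquisition rate. Used to
#' fit the whitening model exactly as in the clinical procedure.
#'
#' @param spec a [sim_spec()].
#' @param duration_ms recording length in ms.
#' @param seed integer seed.
#' @return An `"ues_recording"` with 3 channels.
#' @export
generate_zero_input <- function(spec, duration_ms = 2000, seed = spec$seed) {
  stopifnot(inherits(spec, "ues_sim_spec"))
  n <- floor(duration_ms / 1000 * spec$fs_raw)
  with_seed(seed, {
    out <- matrix(0, n, 3L)
    for (ch in 1:3) {
      x <- numeric(n)
      if (!is.null(spec$ar_coeffs) && length(spec$ar_coeffs) > 0 && spec$ar_sd > 0)
        x <- as.numeric(stats::filter(stats::rnorm(n, sd = spec$ar_sd),
                                      spec$ar_coeffs, method = "recursive"))
      if (spec$noise_sd > 0) x <- x + stats::rnorm(n, sd = spec$noise_sd)
      out[, ch] <- x
    }
    ues_recording(out, spec$fs_raw)
  })
}

#' Synthesize a landmark set with a planted distension ratio
#'
#' Places the vertebral corner points on a line rotated by `rotation`
#' degrees, anchors the C3-height segment at the tracheal notch, and puts
#' the UES anterior/posterior wall points `truth_ratio * c2c4_len` apart
#' along the perpendicular (anterior-posterior) direction, so that the
#' geometric measurement protocol recovers `truth_ratio` exactly (or to
#' within 1 px when `quantize = TRUE`).
#'
#' @param truth_ratio planted ratio (0 gives coincident wall points).
#' @param c2c4_len planted C2-C4 length in px, positive.
#' @param rotation in-plane rotation of the whole scene, degrees.
#' @param seed seed (reserved for jitter; placement itself is deterministic).
#' @param t fraction along the anchored C3 segment where the A-P axis sits.
#' @param frame_index VF frame number attached to the set.
#' @param quantize round all coordinates to whole pixels.
#' @return A [landmark_set()].
#' @export
generate_landmarks <- function(truth_ratio, c2c4_len, rotation = 0, seed = 1,
                               t = 0.5, frame_index = 0, quantize = FALSE) {
  stopifnot_scalar(c2c4_len, "c2c4_len", lower = 0, open_lower = TRUE)
  stopifnot_scalar(truth_ratio, "truth_ratio", lower = 0, upper = 1)
  L <- c2c4_len
  # y grows downward (image convention); the column runs from C2 (top) to C4
  pts <- list(
    c2_ai = c(0, 0),
    c3_as = c(0, 0.30 * L),
    c3_ai = c(0, 0.52 * L),
    c4_ai = c(0, L),
    tracheal_notch = c(-0.25 * L, 0.40 * L)
  )
  h <- 0.22 * L                           # planted C3 height
  q <- pts$tracheal_notch + t * h * c(0, 1) # point on the anchored segment
  pts$ues_posterior <- q + c(0.05 * L, 0)
  pts$ues_anterior <- pts$ues_posterior - c(truth_ratio * L, 0)

  th <- rotation * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  pts <- lapply(pts, function(p) as.numeric(R %*% p))
  if (quantize) pts <- lapply(pts, round)
  landmark_set(c2_ai = pts$c2_ai, c3_as = pts$c3_as, c3_ai = pts$c3_ai,
               c4_ai = pts$c4_ai, tracheal_notch = pts$tracheal_notch,
               ues_anterior = pts$ues_anterior,
               ues_posterior = pts$ues_posterior,
               frame_index = frame_index)
}

# A short series of frames around the maximal distension: the middle frame
# carries the planted ratio, neighbours are scaled below it, so the
# protocol's max-over-frames recovers truth exactly.
generate_landmark_series <- function(truth_ratio, c2c4_len, n_frames = 5,
                                     seed = 1, quantize = FALSE) {
  with_seed(seed, {
    rot <- stats::runif(1, -10, 10)
    mid <- ceiling(n_frames / 2)
    scale <- stats::runif(n_frames, 0.75, 0.95)
    scale[mid] <- 1
    lapply(seq_len(n_frames), function(i)
      generate_landmarks(truth_ratio * scale[i], c2c4_len, rotation = rot,
                         frame_index = i - 1L, quantize = quantize))
  })
}

#' Generate a synthetic dataset with manifest
#'
#' Draws `spec$n_swallows` truth ratios uniformly from
#' `spec$distension_range`, simulates each swallow with a derived seed, and
#' (optionally) writes signal files, landmark files and a tab-delimited
#' manifest to `dir`. Two calls with the same spec produce identical
#' artifacts.
#'
#' @param spec a [sim_spec()].
#' @param dir output directory, or `NULL` to keep everything in memory.
#' @return Invisibly, a list with `swallows` (list of
#'   `"ues_synth_swallow"`), `manifest` (data.frame with columns
#'   `swallow_id`, `path`, `landmark_path`, `onset_frame`, `offset_frame`,
#'   `fps`, `truth_ratio`) and `dir`.
#' @export
generate_dataset <- function(spec, dir = NULL) {
  stopifnot(inherits(spec, "ues_sim_spec"))
  n <- spec$n_swallows
  ratios <- with_seed(spec$seed,
                      stats::runif(n, spec$distension_range[1],
                                   spec$distension_range[2]))
  seeds <- derive_seeds(spec$seed + 1L, n)
  swallows <- vector("list", n)
  for (i in seq_len(n))
    swallows[[i]] <- generate_swallow(spec, ratios[i], seed = seeds[i])
  ids <- sprintf("sw%04d", seq_len(n))
  manifest <- data.frame(
    swallow_id = ids,
    path = if (is.null(dir)) NA_character_ else file.path(dir, paste0(ids, ".txt")),
    landmark_path = if (is.null(dir)) NA_character_ else file.path(dir, paste0(ids, "_lm.txt")),
    onset_frame = vapply(swallows, `[[`, integer(1), "onset_frame"),
    offset_frame = vapply(swallows, `[[`, integer(1), "offset_frame"),
    fps = spec$fps,
    truth_ratio = ratios,
    stringsAsFactors = FALSE
  )
  if (!is.null(dir)) {
    if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
      stop("cannot create output directory: ", dir, call. = FALSE)
    for (i in seq_len(n)) {
      write_signal(swallows[[i]]$recording, manifest$path[i])
      write_landmarks(swallows[[i]]$landmarks, manifest$landmark_path[i])
    }
    write_manifest(manifest, file.path(dir, "manifest.tsv"))
  }
  invisible(structure(list(swallows = swallows, manifest = manifest, dir = dir),
                      class = "ues_synth_dataset"))
}

#' @export
print.ues_synth_dataset <- function(x, ...) {
  cat(sprintf("<ues_synth_dataset> %d swallows, truth ratios in [%.3f, %.3f]\n",
              nrow(x$manifest), min(x$manifest$truth_ratio),
              max(x$manifest$truth_ratio)))
  if (!is.null(x$dir)) cat("  written to:", x$dir, "\n")
  invisible(x)
}
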