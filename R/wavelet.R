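# Discrete Meyer wavelet machinery: FIR filter bank generated from the
# Meyer frequency-domain construction, periodized multilevel DWT with the
# synthesis implemented as the exact adjoint of analysis, and universal
# soft-threshold denoising.

# Meyer auxiliary taper: smooth 0->1 on [0,1] with vanishing derivatives.
meyer_nu <- function(x) {
  x <- pmin(pmax(x, 0), 1)
  x^4 * (35 - 84 * x + 70 * x^2 - 20 * x^3)
}

#' Discrete Meyer scaling filter
#'
#' FIR approximation of the Meyer conjugate mirror filter, obtained by
#' sampling the closed-form frequency response (flat to pi/3, polynomial
#' cosine taper to 2*pi/3, zero beyond), inverse-DFT on a fine grid, and
#' truncating to `length` taps centered on the peak. The result is
#' renormalized so its coefficients sum to sqrt(2); it is orthogonal to its
#' even translates up to the truncation error (~1e-7 for 102 taps).
#'
#' @param length number of taps (even; 102 gives the standard discrete
#'   Meyer filter length).
#' @return numeric vector of low-pass taps.
#' @export
meyer_filter <- function(length = 102L) {
  M <- 8192L
  w <- 2 * pi * (seq_len(M) - 1) / M
  w <- ifelse(w > pi, w - 2 * pi, w)
  aw <- abs(w)
  H <- numeric(M)
  H[aw <= pi / 3] <- sqrt(2)
  mid <- aw > pi / 3 & aw < 2 * pi / 3
  H[mid] <- sqrt(2) * cos(pi / 2 * meyer_nu(3 * aw[mid] / pi - 1))
  h_full <- Re(stats::fft(H, inverse = TRUE)) / M    # h[n], n = 0, 1, ..., M-1
  half <- length %/% 2L
  # taps for n = -half .. half-1 (even-symmetric response, near-symmetric FIR)
  idx <- c((M - half + 1L):M, 1L:half)
  h <- h_full[idx]
  h * sqrt(2) / sum(h)
}

# Quadrature mirror high-pass from an even-length orthogonal low-pass.
qmf_highpass <- function(h) {
  L <- length(h)
  (-1)^(seq_len(L)) * rev(h)
}

# Circular cross-correlation / convolution via FFT; filters longer than the
# signal are folded modulo its length (periodization).
fold_filter <- function(h, n) {
  hp <- numeric(n)
  for (i in seq_along(h)) {
    j <- (i - 1L) %% n + 1L
    hp[j] <- hp[j] + h[i]
  }
  hp
}
circ_corr <- function(x, h) {
  n <- length(x)
  hp <- fold_filter(h, n)
  Re(stats::fft(stats::fft(x) * Conj(stats::fft(hp)), inverse = TRUE)) / n
}
circ_conv <- function(x, h) {
  n <- length(x)
  hp <- fold_filter(h, n)
  Re(stats::fft(stats::fft(x) * stats::fft(hp), inverse = TRUE)) / n
}

#' Periodized multilevel discrete wavelet transform
#'
#' Analysis by circular correlation with the low/high-pass pair and dyadic
#' downsampling; `idwt_periodic()` applies the exact adjoint, so perfect
#' reconstruction holds to the (small) orthogonality error of the truncated
#' filter. Signal length must be divisible by `2^levels`.
#'
#' @param x numeric vector.
#' @param levels decomposition depth.
#' @param h low-pass filter taps (defaults to the discrete Meyer filter).
#' @return list with `approx` (coarsest approximation) and `details` (list
#'   of detail bands, finest first) plus the filter as an attribute.
#' @export
dwt_periodic <- function(x, levels, h = meyer_filter()) {
  n <- length(x)
  if (n %% 2^levels != 0)
    stop("signal length must be divisible by 2^levels", call. = FALSE)
  g <- qmf_highpass(h)
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    ya <- circ_corr(a, h)
    yd <- circ_corr(a, g)
    keep <- seq(1L, length(a), by = 2L)
    details[[j]] <- yd[keep]
    a <- ya[keep]
  }
  structure(list(approx = a, details = details), filter = h)
}

#' @rdname dwt_periodic
#' @param decomp result of `dwt_periodic()` (possibly with modified
#'   coefficients).
#' @return `idwt_periodic()` returns the reconstructed signal.
#' @export
idwt_periodic <- function(decomp, h = attr(decomp, "filter")) {
  g <- qmf_highpass(h)
  a <- decomp$approx
  for (j in rev(seq_along(decomp$details))) {
    d <- decomp$details[[j]]
    n <- 2L * length(a)
    ua <- numeric(n); ua[seq(1L, n, by = 2L)] <- a
    ud <- numeric(n); ud[seq(1L, n, by = 2L)] <- d
    a <- circ_conv(ua, h) + circ_conv(ud, g)
  }
  a
}

#' Soft thresholding
#'
#' Shrinks every coefficient toward zero by `threshold`, zeroing those whose
#' magnitude falls below it: each magnitude shrinks by exactly
#' `min(|c|, threshold)`.
#'
#' @param x numeric vector of coefficients.
#' @param threshold nonnegative threshold.
#' @return shrunk coefficients.
#' @export
soft_threshold <- function(x, threshold) {
  stopifnot_scalar(threshold, "threshold", lower = 0)
  sign(x) * pmax(abs(x) - threshold, 0)
}

#' Universal threshold
#'
#' The standard wavelet denoising threshold `sigma * sqrt(2 * log(N))` for a
#' length-`N` signal with noise scale `sigma` (natural logarithm).
#'
#' @param sigma noise standard deviation estimate.
#' @param n signal length.
#' @return threshold value.
#' @export
universal_threshold <- function(sigma, n) {
  stopifnot_scalar(sigma, "sigma", lower = 0)
  stopifnot_scalar(n, "n", lower = 2)
  sigma * sqrt(2 * log(n))
}

#' Meyer-wavelet soft-threshold denoising
#'
#' Multilevel periodized Meyer DWT, soft thresholding of every detail band
#' at the universal threshold, and reconstruction. The noise scale is the
#' robust estimate from the finest detail band, median absolute deviation
#' divided by 0.6745; the requested depth is capped by the signal length
#' relative to the filter support. Signals are reflection-padded to a
#' multiple of `2^levels` and cropped after reconstruction.
#'
#' @param x numeric vector (one channel).
#' @param levels requested decomposition depth (default 10, capped).
#' @param filter_length Meyer FIR length.
#' @return denoised vector with attributes `levels` (depth used) and
#'   `threshold`.
#' @export
wavelet_denoise <- function(x, levels = 10L, filter_length = 102L) {
  n0 <- length(x)
  if (n0 < 4L)
    stop("signal too short for even one decomposition step", call. = FALSE)
  if (levels < 1L) stop("`levels` must be at least 1", call. = FALSE)
  h <- meyer_filter(filter_length)
  max_lev <- max(1L, floor(log2(n0 / (length(h) - 1))))
  J <- min(as.integer(levels), max_lev)
  np <- ceiling(n0 / 2^J) * 2^J
  xp <- if (np > n0) c(x, rev(x)[seq_len(np - n0)]) else x
  dec <- dwt_periodic(xp, J, h)
  sigma <- stats::mad(dec$details[[1L]], center = 0)
  thr <- universal_threshold(sigma, n0)
  dec$details <- lapply(dec$details, soft_threshold, threshold = thr)
  out <- idwt_periodic(dec, h)[seq_len(n0)]
  attr(out, "levels") <- J
  attr(out, "threshold") <- thr
  out
}
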