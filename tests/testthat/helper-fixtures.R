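# Shared fixtures: tiny model configurations and quick synthetic datasets.

tiny_config <- function(...) {
  args <- utils::modifyList(
    list(chunk_len = 12L, channels = 2L, conv_filters = 2L,
         kernel_len = 3L, pool = 2L, T = 4L, gru_layers = 2L,
         gru_units = 5L, attn_hidden = 6L, fc_units = 7L,
         fc_layers = 3L, dropout = 0, batch_size = 3L),
    list(...))
  do.call(model_config, args)
}

# Quiet low-noise spec at the working rate (no decimation needed), used
# where the planted burst-to-ratio mapping should dominate.
quiet_spec <- function(n = 10, seed = 1, ...) {
  sim_spec(n_swallows = n, fs_raw = 4000, duration_range = c(500, 1200),
           drift_amp = 0.05, ar_sd = 0.01, noise_sd = 0.02, seed = seed, ...)
}

samples_from_dataset <- function(ds) {
  sigs <- stats::setNames(lapply(ds$swallows, `[[`, "recording"),
                          ds$manifest$swallow_id)
  assemble(ds$manifest, signals = sigs)
}

# In-window sample indices of a synthetic swallow at its native rate.
ues_window_idx <- function(sw, fs) {
  lo <- floor(sw$onset_frame / sw$fps * fs) + 1L
  hi <- floor((sw$offset_frame + 1) / sw$fps * fs)
  lo:hi
}

rms_of <- function(x) sqrt(mean(x^2))

snr_db <- function(est, clean) {
  # amplitude-matched SNR: least-squares scale the clean reference onto the
  # estimate first, so overall gain changes introduced by the chain (the
  # whitening FIR is not unit-gain in the burst band) do not masquerade as
  # noise
  a <- sum(est * clean) / sum(clean^2)
  10 * log10(sum((a * clean)^2) / sum((est - a * clean)^2))
}
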