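# Brute-force reference implementations (naive scalar loops), kept
# deliberately independent of the package's vectorized code paths.

naive_cnn <- function(chunk, p, cfg) {
  d <- model_dims(cfg)
  K <- cfg$kernel_len
  conv1 <- matrix(0, d$conv1_len, d$conv1_channels)
  for (ci in seq_len(cfg$channels))
    for (f in seq_len(cfg$conv_filters)) {
      j <- (ci - 1) * cfg$conv_filters + f
      for (i in seq_len(d$conv1_len))
        conv1[i, j] <- max(0, sum(chunk[i:(i + K - 1), ci] * p$K1[, f, ci]) +
                              p$b1[j])
    }
  pooled <- matrix(0, d$pool_len, d$conv1_channels)
  for (i in seq_len(d$pool_len))
    for (j in seq_len(d$conv1_channels))
      pooled[i, j] <- max(conv1[2 * i - 1, j], conv1[2 * i, j])
  out <- matrix(0, d$conv2_len, d$conv1_channels)
  for (i in seq_len(d$conv2_len))
    for (j in seq_len(d$conv1_channels))
      out[i, j] <- max(0, sum(pooled[i:(i + K - 1), j] * p$K2[, j]) + p$b2[j])
  as.vector(out)   # feature index (channel-1)*conv2_len + position
}

naive_gru_cell <- function(x, h, g, U) {
  zi <- seq_len(U); ri <- U + zi; ni <- 2 * U + zi
  gx <- as.numeric(x %*% g$W) + g$bx
  gh <- as.numeric(h %*% g$U) + g$bh
  z <- 1 / (1 + exp(-(gx[zi] + gh[zi])))
  r <- 1 / (1 + exp(-(gx[ri] + gh[ri])))
  n <- tanh(gx[ni] + r * gh[ni])
  (1 - z) * n + z * h
}

naive_head <- function(v, p) {
  h <- v
  for (i in seq_along(p$head$W))
    h <- pmax(0, as.numeric(h %*% p$head$W[[i]]) + p$head$b[[i]])
  1 / (1 + exp(-(sum(h * p$head$Wout) + p$head$bout)))
}
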