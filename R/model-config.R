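# Architecture configuration and parameter initialization for the
# attention-masked CNN-GRU distension regressor.

#' Model configuration
#'
#' All architecture hyperparameters of the distension regression network.
#' The defaults are the standard architecture: per-chunk 1-D CNN (16
#' unpadded length-5 filters per input channel, ReLU, 2/2 max pooling, a
#' second depthwise length-5 convolution, ReLU), two attention generators
#' (dense 2048 ReLU -> dense sigmoid sized to the gated sequence), a 3-layer
#' unidirectional GRU of 64 units, and a head of three 128-unit ReLU layers
#' with 20 % dropout between them feeding a single sigmoid output. With
#' unpadded convolutions the per-chunk feature length is
#' `48 * floor((66-5+1)/2 - 5 + 1) = 1296`, so the CNN attention mask is
#' `90 x 1296` and the RNN mask `90 x 64`. Every field is tunable so that
#' reduced configurations can be trained at desk scale.
#'
#' @param chunk_len samples per chunk (one VF frame).
#' @param channels input channels (3 accelerometer axes).
#' @param conv_filters first-layer filters per input channel.
#' @param kernel_len convolution kernel length.
#' @param pool max-pooling window and stride.
#' @param T sequence length in chunks (frames).
#' @param gru_layers,gru_units GRU stack depth and width.
#' @param attn_hidden hidden units of each attention generator.
#' @param fc_units,fc_layers head width and depth.
#' @param dropout dropout rate between head layers (training only).
#' @param epochs default training epochs.
#' @param lr,beta1,beta2,eps Adam hyperparameters.
#' @param weight_decay decoupled L2 weight decay applied with the Adam
#'   update (0 disables).
#' @param batch_size minibatch size.
#' @return An object of class `"ues_model_config"`.
#' @export
model_config <- function(chunk_len = 66L, channels = 3L, conv_filters = 16L,
                         kernel_len = 5L, pool = 2L, T = 90L,
                         gru_layers = 3L, gru_units = 64L,
                         attn_hidden = 2048L, fc_units = 128L, fc_layers = 3L,
                         dropout = 0.20, epochs = 100L, lr = 1e-3,
                         beta1 = 0.9, beta2 = 0.999, eps = 1e-8,
                         weight_decay = 0, batch_size = 32L) {
  cfg <- structure(list(chunk_len = as.integer(chunk_len),
                        channels = as.integer(channels),
                        conv_filters = as.integer(conv_filters),
                        kernel_len = as.integer(kernel_len),
                        pool = as.integer(pool), T = as.integer(T),
                        gru_layers = as.integer(gru_layers),
                        gru_units = as.integer(gru_units),
                        attn_hidden = as.integer(attn_hidden),
                        fc_units = as.integer(fc_units),
                        fc_layers = as.integer(fc_layers),
                        dropout = dropout, epochs = as.integer(epochs),
                        lr = lr, beta1 = beta1, beta2 = beta2, eps = eps,
                        weight_decay = weight_decay,
                        batch_size = as.integer(batch_size)),
                   class = "ues_model_config")
  d <- model_dims(cfg)
  if (d$conv2_len < 1L)
    stop("chunk too short for two unpadded convolutions", call. = FALSE)
  cfg
}

#' Derived layer dimensions
#'
#' Sizes implied by a configuration with unpadded ("valid") convolutions:
#' conv1 output length `chunk_len - kernel_len + 1`, pooled length
#' `floor(conv1_len / pool)`, conv2 output length
#' `pool_len - kernel_len + 1`, per-chunk feature dimension
#' `channels * conv_filters * conv2_len`, and the two attention mask shapes.
#'
#' @param cfg a [model_config()].
#' @return list of derived sizes.
#' @export
model_dims <- function(cfg) {
  conv1_len <- cfg$chunk_len - cfg$kernel_len + 1L
  conv1_channels <- cfg$channels * cfg$conv_filters
  pool_len <- conv1_len %/% cfg$pool
  conv2_len <- pool_len - cfg$kernel_len + 1L
  feat_dim <- conv1_channels * conv2_len
  list(conv1_len = conv1_len, conv1_channels = conv1_channels,
       pool_len = pool_len, conv2_len = conv2_len, feat_dim = feat_dim,
       cnn_attn_shape = c(cfg$T, feat_dim),
       rnn_attn_shape = c(cfg$T, cfg$gru_units),
       attn_hidden = cfg$attn_hidden,
       head_in = cfg$T * cfg$gru_units)
}

#' @export
print.ues_model_config <- function(x, ...) {
  d <- model_dims(x)
  cat("<ues_model_config>\n")
  cat(sprintf("  CNN: %d ch x %d filters, kernel %d, pool %d/%d -> %d features/chunk\n",
              x$channels, x$conv_filters, x$kernel_len, x$pool, x$pool,
              d$feat_dim))
  cat(sprintf("  attention: mask(%d) -> %d -> %dx%d and %dx%d (sigmoid gates)\n",
              x$T, x$attn_hidden, d$cnn_attn_shape[1], d$cnn_attn_shape[2],
              d$rnn_attn_shape[1], d$rnn_attn_shape[2]))
  cat(sprintf("  GRU: %d layers x %d units over T=%d; head: %d x %d (dropout %.2f) -> 1\n",
              x$gru_layers, x$gru_units, x$T, x$fc_layers, x$fc_units,
              x$dropout))
  invisible(x)
}

#' Initialize model parameters
#'
#' Seeded scaled-Gaussian initialization (variance inversely proportional to
#' fan-in; biases zero) of every learnable collection: convolution kernels,
#' both attention generators, the GRU stack and the head.
#'
#' @param cfg a [model_config()].
#' @param seed integer seed.
#' @return nested list of parameter arrays with attribute `"seed"`.
#' @export
init_params <- function(cfg, seed = 1) {
  d <- model_dims(cfg)
  with_seed(seed, {
    rn <- function(n, sd) stats::rnorm(n, sd = sd)
    K <- cfg$kernel_len; Fc <- cfg$conv_filters; C <- cfg$channels
    C1 <- d$conv1_channels; U <- cfg$gru_units; H <- cfg$attn_hidden
    Tn <- cfg$T; feat <- d$feat_dim
    gru <- vector("list", cfg$gru_layers)
    for (l in seq_len(cfg$gru_layers)) {
      nin <- if (l == 1L) feat else U
      gru[[l]] <- list(W = matrix(rn(nin * 3 * U, sqrt(1 / nin)), nin, 3 * U),
                       U = matrix(rn(U * 3 * U, sqrt(1 / U)), U, 3 * U),
                       bx = numeric(3 * U), bh = numeric(3 * U))
    }
    hw <- vector("list", cfg$fc_layers); hb <- vector("list", cfg$fc_layers)
    nin <- d$head_in
    for (i in seq_len(cfg$fc_layers)) {
      hw[[i]] <- matrix(rn(nin * cfg$fc_units, sqrt(2 / nin)), nin, cfg$fc_units)
      hb[[i]] <- numeric(cfg$fc_units)
      nin <- cfg$fc_units
    }
    p <- list(
      K1 = array(rn(K * Fc * C, sqrt(2 / K)), c(K, Fc, C)),
      b1 = numeric(C1),
      K2 = matrix(rn(K * C1, sqrt(2 / K)), K, C1),
      b2 = numeric(C1),
      att_c = list(W1 = matrix(rn(Tn * H, sqrt(2 / Tn)), Tn, H),
                   b1 = numeric(H),
                   W2 = matrix(rn(H * Tn * feat, sqrt(1 / H)), H, Tn * feat),
                   b2 = numeric(Tn * feat)),
      att_r = list(W1 = matrix(rn(Tn * H, sqrt(2 / Tn)), Tn, H),
                   b1 = numeric(H),
                   W2 = matrix(rn(H * Tn * U, sqrt(1 / H)), H, Tn * U),
                   b2 = numeric(Tn * U)),
      gru = gru,
      head = list(W = hw, b = hb,
                  Wout = matrix(rn(cfg$fc_units, sqrt(1 / cfg$fc_units)),
                                cfg$fc_units, 1),
                  bout = 0)
    )
    attr(p, "seed") <- as.integer(seed)
    p
  })
}

# Apply a function over corresponding numeric leaves of parallel nested
# lists, preserving structure (used for Adam state and updates).
map_leaves <- function(f, ...) {
  args <- list(...)
  if (is.list(args[[1]])) {
    out <- lapply(seq_along(args[[1]]), function(i)
      do.call(map_leaves, c(list(f), lapply(args, `[[`, i))))
    names(out) <- names(args[[1]])
    out
  } else {
    do.call(f, args)
  }
}

#' Total learnable parameter count
#'
#' @param params parameter list from [init_params()].
#' @return integer count.
#' @export
n_params <- function(params) {
  tot <- 0
  walk <- function(x) {
    if (is.list(x)) lapply(x, walk) else tot <<- tot + length(x)
    invisible(NULL)
  }
  walk(params)
  tot
}
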