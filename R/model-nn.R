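# Batched forward and backward passes of the attention-masked CNN-GRU
# regressor. Chunk rows are stored step-major (row m = (t-1)*B + b) so each
# GRU step is a contiguous slice; CNN intermediate matrices are stored
# position-major ((pos-1)*M + m) so convolutions become one BLAS product per
# input channel. Attention gate vectors are ordered feature-fastest within
# each time step.

add_bias <- function(M, b) M + rep(b, each = nrow(M))

# Row indices selecting the given positions for all M items at once
# (position-major layout).
pos_rows <- function(pos, M) as.vector(outer(seq_len(M), (pos - 1L) * M, `+`))

# ---- CNN stage --------------------------------------------------------------

# Xm: array (M, chunk_len, channels). Returns M x feat_dim features.
conv_stage <- function(Xm, params, cfg, keep_cache = FALSE) {
  d <- model_dims(cfg)
  M <- dim(Xm)[1]; K <- cfg$kernel_len
  P1 <- d$conv1_len; PL <- d$pool_len; P2 <- d$conv2_len
  C <- cfg$channels; Fc <- cfg$conv_filters; C1 <- d$conv1_channels

  Cmat <- vector("list", C)
  Z <- matrix(0, M * P1, C1)
  for (ci in seq_len(C)) {
    Xc <- matrix(Xm[, , ci], M, cfg$chunk_len)
    Cm <- matrix(0, M * P1, K)
    for (k in seq_len(K)) Cm[, k] <- as.vector(Xc[, k:(k + P1 - 1L)])
    Z[, (ci - 1L) * Fc + seq_len(Fc)] <- Cm %*% params$K1[, , ci]
    if (keep_cache) Cmat[[ci]] <- Cm
  }
  Z <- add_bias(Z, params$b1)
  S1 <- Z > 0
  A1 <- Z * S1

  io <- pos_rows(seq(1L, 2L * PL, by = 2L), M)
  ie <- pos_rows(seq(2L, 2L * PL, by = 2L), M)
  Ao <- A1[io, , drop = FALSE]; Ae <- A1[ie, , drop = FALSE]
  sel <- Ao >= Ae
  Pm <- Ao * sel + Ae * (1 - sel)

  idx2 <- lapply(seq_len(K), function(k) pos_rows(k:(k + P2 - 1L), M))
  Z2 <- matrix(rep(params$b2, each = M * P2), M * P2, C1)
  for (k in seq_len(K))
    Z2 <- Z2 + Pm[idx2[[k]], , drop = FALSE] *
      rep(params$K2[k, ], each = M * P2)
  S2 <- Z2 > 0
  A2 <- Z2 * S2
  Fm <- A2
  dim(Fm) <- c(M, P2 * C1)    # feature index f = (channel-1)*conv2_len + pos

  cache <- if (keep_cache)
    list(Cmat = Cmat, S1 = S1, io = io, ie = ie, sel = sel, Pm = Pm,
         idx2 = idx2, S2 = S2, M = M)
  list(F = Fm, cache = cache)
}

conv_stage_backward <- function(dFm, cache, params, cfg) {
  d <- model_dims(cfg)
  M <- cache$M; K <- cfg$kernel_len
  P1 <- d$conv1_len; P2 <- d$conv2_len
  C <- cfg$channels; Fc <- cfg$conv_filters; C1 <- d$conv1_channels

  dA2 <- dFm
  dim(dA2) <- c(M * P2, C1)
  dZ2 <- dA2 * cache$S2
  db2 <- colSums(dZ2)
  dK2 <- matrix(0, K, C1)
  dPm <- matrix(0, nrow(cache$Pm), C1)
  for (k in seq_len(K)) {
    rows <- cache$idx2[[k]]
    dK2[k, ] <- colSums(cache$Pm[rows, , drop = FALSE] * dZ2)
    dPm[rows, ] <- dPm[rows, , drop = FALSE] +
      dZ2 * rep(params$K2[k, ], each = M * P2)
  }
  dAo <- dPm * cache$sel
  dAe <- dPm * (1 - cache$sel)
  dA1 <- matrix(0, M * P1, C1)
  dA1[cache$io, ] <- dAo
  dA1[cache$ie, ] <- dAe
  dZ1 <- dA1 * cache$S1
  db1 <- colSums(dZ1)
  dK1 <- array(0, dim(params$K1))
  for (ci in seq_len(C)) {
    cols <- (ci - 1L) * Fc + seq_len(Fc)
    dK1[, , ci] <- crossprod(cache$Cmat[[ci]], dZ1[, cols, drop = FALSE])
  }
  list(K1 = dK1, b1 = db1, K2 = dK2, b2 = db2)
}

# ---- Attention generators ---------------------------------------------------

# masks: B x T. Returns flat gate matrix B x (T*out_dim), feature-fastest.
attn_generator <- function(masks, ap, keep_cache = FALSE) {
  Hpre <- add_bias(masks %*% ap$W1, ap$b1)
  S <- Hpre > 0
  Hh <- Hpre * S
  A <- sigmoid(add_bias(Hh %*% ap$W2, ap$b2))
  cache <- if (keep_cache) list(S = S, H = Hh, A = A, masks = masks)
  list(A = A, cache = cache)
}

attn_generator_backward <- function(dA, cache, ap) {
  dpre <- dA * cache$A * (1 - cache$A)
  dW2 <- crossprod(cache$H, dpre)
  db2 <- colSums(dpre)
  dH <- tcrossprod(dpre, ap$W2) * cache$S
  list(W1 = crossprod(cache$masks, dH), b1 = colSums(dH),
       W2 = dW2, b2 = db2)
}

# ---- Full forward -----------------------------------------------------------

# X: array (B, T, chunk_len, channels); masks: B x T.
nn_forward <- function(X, masks, params, cfg, training = FALSE,
                       keep_cache = FALSE) {
  d <- model_dims(cfg)
  B <- dim(X)[1]; Tn <- cfg$T; M <- B * Tn
  U <- cfg$gru_units; feat <- d$feat_dim; L <- cfg$gru_layers
  if (dim(X)[2] != Tn) stop("sequence length does not match config T",
                            call. = FALSE)
  zi <- seq_len(U); ri <- U + zi; ni <- 2L * U + zi

  Xm <- X
  dim(Xm) <- c(M, cfg$chunk_len, cfg$channels)  # row m = (t-1)*B + b
  cs <- conv_stage(Xm, params, cfg, keep_cache)
  Fm <- cs$F

  ac <- attn_generator(masks, params$att_c, keep_cache)
  ar <- attn_generator(masks, params$att_r, keep_cache)
  Ac <- ac$A; dim(Ac) <- c(B, feat, Tn)
  Ar <- ar$A; dim(Ar) <- c(B, U, Tn)

  Hs <- replicate(L, matrix(0, B, U), simplify = FALSE)
  Hout <- replicate(L, array(0, c(B, U, Tn)), simplify = FALSE)
  cz <- cr <- cn <- cg <- if (keep_cache)
    replicate(L, array(0, c(B, U, Tn)), simplify = FALSE)
  xg <- if (keep_cache) array(0, c(B, feat, Tn))

  for (t in seq_len(Tn)) {
    rows_t <- ((t - 1L) * B + 1L):(t * B)
    Xt <- Fm[rows_t, , drop = FALSE] * matrix(Ac[, , t], B, feat)
    if (keep_cache) xg[, , t] <- Xt
    for (l in seq_len(L)) {
      g <- params$gru[[l]]
      gx <- add_bias(Xt %*% g$W, g$bx)
      gh <- add_bias(Hs[[l]] %*% g$U, g$bh)
      z <- sigmoid(gx[, zi, drop = FALSE] + gh[, zi, drop = FALSE])
      r <- sigmoid(gx[, ri, drop = FALSE] + gh[, ri, drop = FALSE])
      ghn <- gh[, ni, drop = FALSE]
      nn <- tanh(gx[, ni, drop = FALSE] + r * ghn)
      Hnew <- (1 - z) * nn + z * Hs[[l]]
      if (keep_cache) {
        cz[[l]][, , t] <- z; cr[[l]][, , t] <- r
        cn[[l]][, , t] <- nn; cg[[l]][, , t] <- ghn
      }
      Hout[[l]][, , t] <- Hnew
      Hs[[l]] <- Hnew
      Xt <- Hnew
    }
  }

  Y <- Hout[[L]]
  Ym <- Y * Ar
  flat <- Ym
  dim(flat) <- c(B, U * Tn)

  fcin <- vector("list", cfg$fc_layers)
  fcS <- vector("list", cfg$fc_layers)
  fcD <- vector("list", cfg$fc_layers)
  Hh <- flat
  for (i in seq_len(cfg$fc_layers)) {
    fcin[[i]] <- Hh
    Zi <- add_bias(Hh %*% params$head$W[[i]], params$head$b[[i]])
    Si <- Zi > 0
    Ai <- Zi * Si
    if (training && cfg$dropout > 0 && i < cfg$fc_layers) {
      Dm <- (matrix(stats::runif(length(Ai)), nrow(Ai)) >= cfg$dropout) /
        (1 - cfg$dropout)
      Ai <- Ai * Dm
      fcD[[i]] <- Dm
    }
    fcS[[i]] <- Si
    Hh <- Ai
  }
  logit <- add_bias(Hh %*% params$head$Wout, params$head$bout)
  pred <- sigmoid(logit)

  cache <- if (keep_cache)
    list(B = B, conv = cs$cache, Fm = Fm, ac = ac$cache, ar = ar$cache,
         Ac = Ac, Ar = Ar, xg = xg, cz = cz, cr = cr, cn = cn, cg = cg,
         Hout = Hout, Y = Y, fcin = fcin, fcS = fcS, fcD = fcD,
         fclast = Hh, pred = pred, masks = masks)
  list(pred = as.numeric(pred), cache = cache)
}

# ---- Full backward ----------------------------------------------------------

nn_backward <- function(dpred, cache, params, cfg) {
  d <- model_dims(cfg)
  B <- cache$B; Tn <- cfg$T; U <- cfg$gru_units
  feat <- d$feat_dim; L <- cfg$gru_layers
  zi <- seq_len(U); ri <- U + zi; ni <- 2L * U + zi

  dlogit <- matrix(dpred * cache$pred * (1 - cache$pred), B, 1)
  ghead <- list(W = vector("list", cfg$fc_layers),
                b = vector("list", cfg$fc_layers),
                Wout = crossprod(cache$fclast, dlogit),
                bout = sum(dlogit))
  dH <- tcrossprod(dlogit, params$head$Wout)
  for (i in rev(seq_len(cfg$fc_layers))) {
    if (!is.null(cache$fcD[[i]])) dH <- dH * cache$fcD[[i]]
    dZ <- dH * cache$fcS[[i]]
    ghead$b[[i]] <- colSums(dZ)
    ghead$W[[i]] <- crossprod(cache$fcin[[i]], dZ)
    dH <- tcrossprod(dZ, params$head$W[[i]])
  }

  dYm <- dH
  dim(dYm) <- c(B, U, Tn)
  dY <- dYm * cache$Ar
  dAr <- dYm * cache$Y
  dim(dAr) <- c(B, U * Tn)
  gar <- attn_generator_backward(dAr, cache$ar, params$att_r)

  ggru <- lapply(params$gru, function(g)
    list(W = array(0, dim(g$W)), U = array(0, dim(g$U)),
         bx = numeric(length(g$bx)), bh = numeric(length(g$bh))))
  dHnext <- replicate(L, matrix(0, B, U), simplify = FALSE)
  dFm <- matrix(0, B * Tn, feat)
  dAc <- array(0, c(B, feat, Tn))

  for (t in rev(seq_len(Tn))) {
    dx_above <- matrix(dY[, , t], B, U)
    for (l in rev(seq_len(L))) {
      g <- params$gru[[l]]
      dh <- dHnext[[l]] + dx_above
      z <- matrix(cache$cz[[l]][, , t], B, U)
      r <- matrix(cache$cr[[l]][, , t], B, U)
      nn <- matrix(cache$cn[[l]][, , t], B, U)
      ghn <- matrix(cache$cg[[l]][, , t], B, U)
      hprev <- if (t > 1L) matrix(cache$Hout[[l]][, , t - 1L], B, U)
               else matrix(0, B, U)
      xin <- if (l > 1L) matrix(cache$Hout[[l - 1L]][, , t], B, U)
             else matrix(cache$xg[, , t], B, feat)

      dz <- dh * (hprev - nn)
      dn <- dh * (1 - z)
      dhp <- dh * z
      dnp <- dn * (1 - nn^2)
      dghn <- dnp * r
      dr <- dnp * ghn
      dzp <- dz * z * (1 - z)
      drp <- dr * r * (1 - r)
      dGx <- cbind(dzp, drp, dnp)
      dGh <- cbind(dzp, drp, dghn)

      ggru[[l]]$W <- ggru[[l]]$W + crossprod(xin, dGx)
      ggru[[l]]$U <- ggru[[l]]$U + crossprod(hprev, dGh)
      ggru[[l]]$bx <- ggru[[l]]$bx + colSums(dGx)
      ggru[[l]]$bh <- ggru[[l]]$bh + colSums(dGh)
      dHnext[[l]] <- dhp + tcrossprod(dGh, g$U)
      dx_above <- tcrossprod(dGx, g$W)
    }
    rows_t <- ((t - 1L) * B + 1L):(t * B)
    dXg <- dx_above
    dFm[rows_t, ] <- dXg * matrix(cache$Ac[, , t], B, feat)
    dAc[, , t] <- dXg * cache$Fm[rows_t, , drop = FALSE]
  }
  dim(dAc) <- c(B, feat * Tn)
  gac <- attn_generator_backward(dAc, cache$ac, params$att_c)
  gconv <- conv_stage_backward(dFm, cache$conv, params, cfg)

  list(K1 = gconv$K1, b1 = gconv$b1, K2 = gconv$K2, b2 = gconv$b2,
       att_c = gac, att_r = gar, gru = ggru, head = ghead)
}

# ---- Public per-operation surface ------------------------------------------

#' Per-chunk CNN forward pass
#'
#' Two unpadded ReLU convolutions with 2/2 max pooling in between, applied
#' to one `chunk_len x channels` chunk; the flattened output has
#' `channels * conv_filters * conv2_len` entries (1296 for the standard
#' configuration).
#'
#' @param chunk numeric matrix `chunk_len x channels`.
#' @param params parameters from [init_params()].
#' @param cfg the matching [model_config()].
#' @return numeric feature vector.
#' @export
cnn_forward <- function(chunk, params, cfg = model_config()) {
  if (!is.matrix(chunk) || nrow(chunk) != cfg$chunk_len ||
      ncol(chunk) != cfg$channels)
    stop(sprintf("chunk must be %d x %d", cfg$chunk_len, cfg$channels),
         call. = FALSE)
  Xm <- array(chunk, c(1L, cfg$chunk_len, cfg$channels))
  as.numeric(conv_stage(Xm, params, cfg)$F)
}

#' Attention generator forward pass
#'
#' Both generators share one layout: the binary UES-opening mask is passed
#' through a ReLU hidden layer and a sigmoid output layer sized to the gated
#' sequence, yielding multiplicative gates in (0, 1) for the CNN feature
#' sequence (`T x feat_dim`) and the RNN output sequence (`T x gru_units`).
#'
#' @param mask binary vector of length `cfg$T`.
#' @inheritParams cnn_forward
#' @return list with matrices `cnn` (`T x feat_dim`) and `rnn`
#'   (`T x gru_units`).
#' @export
attention_forward <- function(mask, params, cfg = model_config()) {
  if (length(mask) != cfg$T)
    stop(sprintf("mask must have length %d", cfg$T), call. = FALSE)
  d <- model_dims(cfg)
  m <- matrix(mask, 1L)
  Ac <- attn_generator(m, params$att_c)$A
  Ar <- attn_generator(m, params$att_r)$A
  list(cnn = t(matrix(Ac, d$feat_dim, cfg$T)),
       rnn = t(matrix(Ar, cfg$gru_units, cfg$T)))
}

#' GRU stack forward pass
#'
#' Stacked unidirectional gated recurrent units (zero initial state) over an
#' input sequence; returns the per-step outputs of the last layer. Gate
#' equations: `z = sigmoid(x Wz + h Uz + bz)`, `r = sigmoid(x Wr + h Ur +
#' br)`, `n = tanh(x Wn + bxn + r * (h Un + bhn))`,
#' `h' = (1 - z) * n + z * h`.
#'
#' @param x_seq numeric matrix `T x feat_dim` (already attention-gated).
#' @inheritParams cnn_forward
#' @return matrix `T x gru_units`.
#' @export
rnn_forward <- function(x_seq, params, cfg = model_config()) {
  d <- model_dims(cfg)
  if (!is.matrix(x_seq) || nrow(x_seq) != cfg$T || ncol(x_seq) != d$feat_dim)
    stop(sprintf("x_seq must be %d x %d", cfg$T, d$feat_dim), call. = FALSE)
  U <- cfg$gru_units
  zi <- seq_len(U); ri <- U + zi; ni <- 2L * U + zi
  Hs <- replicate(cfg$gru_layers, matrix(0, 1L, U), simplify = FALSE)
  out <- matrix(0, cfg$T, U)
  for (t in seq_len(cfg$T)) {
    Xt <- x_seq[t, , drop = FALSE]
    for (l in seq_len(cfg$gru_layers)) {
      g <- params$gru[[l]]
      gx <- Xt %*% g$W + rep(g$bx, each = 1L)
      gh <- Hs[[l]] %*% g$U + rep(g$bh, each = 1L)
      z <- sigmoid(gx[, zi, drop = FALSE] + gh[, zi, drop = FALSE])
      r <- sigmoid(gx[, ri, drop = FALSE] + gh[, ri, drop = FALSE])
      nn <- tanh(gx[, ni, drop = FALSE] + r * gh[, ni, drop = FALSE])
      Hs[[l]] <- (1 - z) * nn + z * Hs[[l]]
      Xt <- Hs[[l]]
    }
    out[t, ] <- Hs[[cfg$gru_layers]]
  }
  out
}

#' Regression head forward pass
#'
#' Flattened attention-gated RNN outputs through `fc_layers` ReLU layers
#' (dropout inactive at inference) and a single sigmoid output unit, giving
#' a distension ratio prediction strictly inside (0, 1).
#'
#' @param y_masked matrix `T x gru_units` (or its flattened vector).
#' @inheritParams cnn_forward
#' @return scalar prediction in (0, 1).
#' @export
head_forward <- function(y_masked, params, cfg = model_config()) {
  d <- model_dims(cfg)
  v <- if (is.matrix(y_masked)) as.vector(t(y_masked)) else as.numeric(y_masked)
  if (length(v) != d$head_in)
    stop(sprintf("head input must have %d entries", d$head_in), call. = FALSE)
  Hh <- matrix(v, 1L)
  for (i in seq_len(cfg$fc_layers))
    Hh <- relu(Hh %*% params$head$W[[i]] +
                 rep(params$head$b[[i]], each = 1L))
  as.numeric(sigmoid(Hh %*% params$head$Wout + params$head$bout))
}

#' Full forward pass for one swallow sample
#'
#' Per-chunk CNN features, elementwise CNN attention gating, GRU stack,
#' elementwise RNN attention gating, regression head.
#'
#' @param sample a [swallow_sample()].
#' @inheritParams cnn_forward
#' @return scalar prediction in (0, 1).
#' @export
forward_pass <- function(sample, params, cfg = model_config()) {
  stopifnot(inherits(sample, "ues_sample"))
  X <- array(sample$chunks, c(1L, dim(sample$chunks)))
  nn_forward(X, matrix(sample$mask, 1L), params, cfg)$pred
}
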