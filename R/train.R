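# Model fitting: Adam on mean squared error over minibatches, with the
# classic fitted-model object interface.

#' Mean squared error loss
#'
#' @param preds,truths equal-length numeric vectors.
#' @return scalar mean of squared differences.
#' @export
mse_loss <- function(preds, truths) {
  if (length(preds) == 0L) stop("empty batch", call. = FALSE)
  if (length(preds) != length(truths))
    stop("`preds` and `truths` must have equal length", call. = FALSE)
  mean((preds - truths)^2)
}

#' Absolute percentage error
#'
#' `|prediction - truth| * 100 / truth`, in percent. Vectorized; every truth
#' must be positive.
#'
#' @param prediction,truth numeric vectors (recycled to common length).
#' @return APE values in percent.
#' @export
ape <- function(prediction, truth) {
  if (any(truth <= 0))
    stop("APE undefined for non-positive ground truth", call. = FALSE)
  abs(prediction - truth) * 100 / truth
}

# Stack a list of ues_sample objects into dense arrays.
stack_samples <- function(samples, cfg) {
  N <- length(samples)
  if (N == 0L) stop("non-empty training set required", call. = FALSE)
  d1 <- dim(samples[[1]]$chunks)
  if (d1[1] != cfg$T || d1[2] != cfg$chunk_len || d1[3] != cfg$channels)
    stop(sprintf("sample chunks are %dx%dx%d but config expects %dx%dx%d",
                 d1[1], d1[2], d1[3], cfg$T, cfg$chunk_len, cfg$channels),
         call. = FALSE)
  X <- array(0, c(N, cfg$T, cfg$chunk_len, cfg$channels))
  masks <- matrix(0, N, cfg$T)
  y <- numeric(N)
  for (i in seq_len(N)) {
    X[i, , , ] <- samples[[i]]$chunks
    masks[i, ] <- samples[[i]]$mask
    y[i] <- samples[[i]]$target_ratio
  }
  list(X = X, masks = masks, y = y,
       ids = vapply(samples, `[[`, character(1), "id"))
}

#' Fit the attention-masked CNN-GRU distension regressor
#'
#' Trains the network on assembled swallow samples by minibatch Adam on the
#' mean squared error between predicted and ground-truth normalized
#' distension ratios. Initialization, shuffling and dropout are all driven
#' by `seed`, so two runs with identical inputs are bit-identical.
#'
#' @param samples list of [swallow_sample()] objects.
#' @param cfg a [model_config()].
#' @param epochs training epochs (defaults to `cfg$epochs`).
#' @param seed integer seed.
#' @param verbose print per-epoch progress.
#' @return An object of class `"uesnet"`: list with `params`, `cfg`,
#'   `history` (data.frame of per-epoch training `mse` and `mean_ape`),
#'   `seed`, `n` and `call`. Supports [predict()], [print()], [summary()],
#'   [coef()] and [plot()].
#' @examples
#' spec <- sim_spec(n_swallows = 8, fs_raw = 4000, duration_range = c(400, 900),
#'                  drift_amp = 0, ar_sd = 0, noise_sd = 0.01, seed = 7)
#' ds <- generate_dataset(spec)
#' sigs <- setNames(lapply(ds$swallows, `[[`, "recording"),
#'                  ds$manifest$swallow_id)
#' sams <- assemble(ds$manifest, signals = sigs)
#' cfg <- model_config(conv_filters = 2, attn_hidden = 8, gru_units = 8,
#'                     fc_units = 16, epochs = 2, batch_size = 4)
#' fit <- ues_fit(sams, cfg, seed = 1)
#' predict(fit, sams)
#' @export
ues_fit <- function(samples, cfg = model_config(), epochs = cfg$epochs,
                    seed = 1, verbose = FALSE) {
  st <- stack_samples(samples, cfg)
  N <- length(st$y)
  params <- init_params(cfg, seed)
  mstate <- map_leaves(function(p) p * 0, params)
  vstate <- map_leaves(function(p) p * 0, params)
  history <- data.frame(epoch = integer(0), mse = numeric(0),
                        mean_ape = numeric(0))
  step <- 0L
  with_seed(seed + 1L, {
    for (ep in seq_len(epochs)) {
      ord <- sample.int(N)
      ep_se <- 0; ep_ape <- 0
      for (b0 in seq(1L, N, by = cfg$batch_size)) {
        idx <- ord[b0:min(b0 + cfg$batch_size - 1L, N)]
        B <- length(idx)
        Xb <- st$X[idx, , , , drop = FALSE]
        mb <- st$masks[idx, , drop = FALSE]
        yb <- st$y[idx]
        fw <- nn_forward(Xb, mb, params, cfg, training = TRUE,
                         keep_cache = TRUE)
        if (any(!is.finite(fw$pred)))
          stop(sprintf("training diverged: non-finite prediction at epoch %d (lr=%g)",
                       ep, cfg$lr), call. = FALSE)
        dpred <- 2 * (fw$pred - yb) / B
        grads <- nn_backward(dpred, fw$cache, params, cfg)
        step <- step + 1L
        c1 <- 1 - cfg$beta1^step
        c2 <- 1 - cfg$beta2^step
        mstate <- map_leaves(function(m, g) cfg$beta1 * m + (1 - cfg$beta1) * g,
                             mstate, grads)
        vstate <- map_leaves(function(v, g) cfg$beta2 * v + (1 - cfg$beta2) * g^2,
                             vstate, grads)
        params <- map_leaves(function(p, m, v)
          p - cfg$lr * ((m / c1) / (sqrt(v / c2) + cfg$eps) +
                          cfg$weight_decay * p),
          params, mstate, vstate)
        ep_se <- ep_se + sum((fw$pred - yb)^2)
        ep_ape <- ep_ape + sum(ape(fw$pred, yb))
      }
      history[ep, ] <- list(ep, ep_se / N, ep_ape / N)
      if (verbose)
        message(sprintf("epoch %3d  mse %.5f  mean APE %.1f%%",
                        ep, ep_se / N, ep_ape / N))
    }
  })
  structure(list(params = params, cfg = cfg, history = history,
                 seed = as.integer(seed), n = N, ids = st$ids,
                 call = match.call()),
            class = "uesnet")
}

#' Predict distension ratios for new swallows
#'
#' @param object a fitted `"uesnet"` model.
#' @param newdata list of [swallow_sample()] objects (or a single one).
#' @param ... unused.
#' @return named numeric vector of predicted ratios in (0, 1).
#' @export
predict.uesnet <- function(object, newdata, ...) {
  if (inherits(newdata, "ues_sample")) newdata <- list(newdata)
  st <- stack_samples(newdata, object$cfg)
  N <- length(st$y)
  preds <- numeric(N)
  bs <- object$cfg$batch_size
  for (b0 in seq(1L, N, by = bs)) {
    idx <- b0:min(b0 + bs - 1L, N)
    preds[idx] <- nn_forward(st$X[idx, , , , drop = FALSE],
                             st$masks[idx, , drop = FALSE],
                             object$params, object$cfg)$pred
  }
  stats::setNames(preds, st$ids)
}

#' @export
print.uesnet <- function(x, ...) {
  h <- x$history[nrow(x$history), ]
  cat(sprintf("<uesnet> fitted on %d swallows, %d epochs, %s parameters\n",
              x$n, nrow(x$history), format(n_params(x$params), big.mark = ",")))
  cat(sprintf("  final training MSE %.5f, mean APE %.1f%%\n", h$mse,
              h$mean_ape))
  invisible(x)
}

#' @export
summary.uesnet <- function(object, ...) {
  cat("Attention-masked CNN-GRU distension regressor\n\n")
  print(object$cfg)
  cat(sprintf("\nFitted on %d swallows (seed %d), %d epochs, %s parameters\n",
              object$n, object$seed, nrow(object$history),
              format(n_params(object$params), big.mark = ",")))
  cat("\nTraining history (last 5 epochs):\n")
  print(utils::tail(object$history, 5), row.names = FALSE)
  invisible(object)
}

#' @export
coef.uesnet <- function(object, ...) object$params

#' Plot training history
#'
#' Two panels: training MSE and mean APE per epoch.
#'
#' @param x a fitted `"uesnet"`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.uesnet <- function(x, ...) {
  op <- graphics::par(mfrow = c(1, 2))
  on.exit(graphics::par(op))
  graphics::plot(x$history$epoch, x$history$mse, type = "l",
                 xlab = "epoch", ylab = "training MSE", ...)
  graphics::plot(x$history$epoch, x$history$mean_ape, type = "l",
                 xlab = "epoch", ylab = "training mean APE (%)", ...)
  invisible(x)
}
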