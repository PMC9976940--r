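test_that("cnn_forward matches a naive sliding-window implementation", {
  cfg <- tiny_config()
  p <- init_params(cfg, 4)
  set.seed(8)
  for (i in 1:3) {
    chunk <- matrix(rnorm(cfg$chunk_len * cfg$channels), cfg$chunk_len)
    expect_equal(cnn_forward(chunk, p, cfg), naive_cnn(chunk, p, cfg),
                 tolerance = 1e-6)
  }

  # default architecture: any valid chunk gives a 1296-long feature vector
  cfg_full <- model_config()
  pf <- init_params(cfg_full, 1)
  chunk <- matrix(rnorm(66 * 3), 66, 3)
  out <- cnn_forward(chunk, pf, cfg_full)
  expect_length(out, 1296L)
  expect_equal(out, naive_cnn(chunk, pf, cfg_full), tolerance = 1e-6)

  # all-zero parameters map any input to zero (ReLU(0) = 0)
  p0 <- uesnet:::map_leaves(function(x) x * 0, pf)
  expect_equal(max(abs(cnn_forward(chunk, p0, cfg_full))), 0)

  expect_error(cnn_forward(matrix(0, 10, 3), pf, cfg_full), "chunk must be")
})

test_that("attention generators gate in (0,1) and respond to the mask", {
  cfg <- model_config(attn_hidden = 16L)
  d <- model_dims(cfg)
  p <- init_params(cfg, 5)
  mask <- build_ues_mask(20, 40, cfg$T)
  at <- attention_forward(mask, p, cfg)
  expect_equal(dim(at$cnn), c(90L, 1296L))
  expect_equal(dim(at$rnn), c(90L, 64L))
  expect_true(all(at$cnn > 0 & at$cnn < 1))
  expect_true(all(at$rnn > 0 & at$rnn < 1))

  # zero generator weights give the sigmoid midpoint everywhere
  p0 <- p
  p0$att_c <- uesnet:::map_leaves(function(x) x * 0, p$att_c)
  at0 <- attention_forward(mask, p0, cfg)
  expect_equal(max(abs(at0$cnn - 0.5)), 0)

  # different masks give different gates (non-degeneracy over random params)
  at2 <- attention_forward(build_ues_mask(50, 70, cfg$T), p, cfg)
  expect_gt(max(abs(at$cnn - at2$cnn)), 1e-4)
  expect_error(attention_forward(mask[1:10], p, cfg), "length")
})

test_that("rnn_forward matches the GRU cell equations", {
  # single-step: hand-rolled gate equations through the stacked layers
  cfg1 <- tiny_config(T = 1L)
  d <- model_dims(cfg1)
  p <- init_params(cfg1, 6)
  set.seed(9)
  x <- matrix(rnorm(d$feat_dim), 1)
  h1 <- naive_gru_cell(x, numeric(cfg1$gru_units), p$gru[[1]], cfg1$gru_units)
  h2 <- naive_gru_cell(matrix(h1, 1), numeric(cfg1$gru_units), p$gru[[2]],
                       cfg1$gru_units)
  expect_equal(as.numeric(rnn_forward(x, p, cfg1)), h2, tolerance = 1e-6)

  # multi-step: naive recurrence oracle
  cfg <- tiny_config()
  p <- init_params(cfg, 6)
  xs <- matrix(rnorm(cfg$T * model_dims(cfg)$feat_dim), cfg$T)
  hs <- replicate(cfg$gru_layers, numeric(cfg$gru_units), simplify = FALSE)
  ref <- matrix(0, cfg$T, cfg$gru_units)
  for (t in seq_len(cfg$T)) {
    xin <- xs[t, , drop = FALSE]
    for (l in seq_len(cfg$gru_layers)) {
      hs[[l]] <- naive_gru_cell(xin, hs[[l]], p$gru[[l]], cfg$gru_units)
      xin <- matrix(hs[[l]], 1)
    }
    ref[t, ] <- hs[[cfg$gru_layers]]
  }
  expect_equal(rnn_forward(xs, p, cfg), ref, tolerance = 1e-6)

  # zero input, zero parameters: the GRU fixed point is zero
  p0 <- uesnet:::map_leaves(function(x) x * 0, p)
  out0 <- rnn_forward(matrix(0, cfg$T, model_dims(cfg)$feat_dim), p0, cfg)
  expect_equal(max(abs(out0)), 0)
  expect_equal(dim(out0), c(cfg$T, cfg$gru_units))
})

test_that("head_forward matches a brute-force affine/ReLU chain", {
  cfg <- tiny_config()
  d <- model_dims(cfg)
  p <- init_params(cfg, 7)
  set.seed(10)
  for (i in 1:3) {
    y <- matrix(rnorm(cfg$T * cfg$gru_units), cfg$T)
    v <- as.vector(t(y))
    got <- head_forward(y, p, cfg)
    expect_equal(got, naive_head(v, p), tolerance = 1e-6)
    expect_gt(got, 0); expect_lt(got, 1)
    # dropout is inactive at inference: repeated calls are identical
    expect_identical(got, head_forward(y, p, cfg))
  }
})

test_that("mse_loss and ape follow their formulas", {
  expect_equal(mse_loss(c(0.5), c(0.0)), 0.25)
  expect_equal(mse_loss(1:5 / 10, 1:5 / 10), 0)
  set.seed(12)
  a <- runif(50); b <- runif(50)
  expect_equal(mse_loss(a, b), sum((a - b)^2) / 50)
  expect_error(mse_loss(numeric(0), numeric(0)), "empty batch")

  expect_equal(ape(0.35, 0.45), abs(0.35 - 0.45) * 100 / 0.45)
  expect_equal(ape(0.4, 0.4), 0)
  expect_equal(ape(0, 0.7), 100)
  expect_error(ape(0.5, 0), "non-positive")
})

test_that("full forward pass is order-sensitive, finite and in (0,1)", {
  cfg <- tiny_config()
  p <- init_params(cfg, 11)
  set.seed(13)
  chunks <- array(rnorm(cfg$T * cfg$chunk_len * cfg$channels),
                  c(cfg$T, cfg$chunk_len, cfg$channels))
  mask <- c(0, 1, 1, 0)
  s <- swallow_sample(chunks, mask, 0.5, cfg$T, "a")
  pr <- forward_pass(s, p, cfg)
  expect_gt(pr, 0); expect_lt(pr, 1)

  # permuting two chunks inside the masked window changes the prediction
  chunks2 <- chunks
  chunks2[2, , ] <- chunks[3, , ]
  chunks2[3, , ] <- chunks[2, , ]
  s2 <- swallow_sample(chunks2, mask, 0.5, cfg$T, "b")
  expect_false(isTRUE(all.equal(pr, forward_pass(s2, p, cfg))))

  # forward pass stays finite for random inputs across 100 seeds
  preds <- sapply(1:100, function(sd) {
    set.seed(sd)
    ch <- array(rnorm(length(chunks), sd = 3), dim(chunks))
    forward_pass(swallow_sample(ch, mask, 0.5, cfg$T, "x"), p, cfg)
  })
  expect_true(all(is.finite(preds)))
})

test_that("analytic gradients match central finite differences", {
  ns <- asNamespace("uesnet")
  cfg <- tiny_config()
  set.seed(42)
  B <- 3L
  X <- array(rnorm(B * cfg$T * cfg$chunk_len * cfg$channels),
             c(B, cfg$T, cfg$chunk_len, cfg$channels))
  masks <- matrix(rbinom(B * cfg$T, 1, 0.5), B, cfg$T)
  y <- runif(B, 0.2, 0.8)
  p <- init_params(cfg, 9)
  # move to a generic point: zero-initialized biases put some ReLU
  # pre-activations exactly at the kink, where subgradient and one-sided
  # slopes legitimately differ
  p <- ns$map_leaves(function(x) x + rnorm(length(x), sd = 0.05), p)

  fw <- ns$nn_forward(X, masks, p, cfg, training = TRUE, keep_cache = TRUE)
  gr <- ns$nn_backward(2 * (fw$pred - y) / B, fw$cache, p, cfg)
  loss <- function(pp) mean((ns$nn_forward(X, masks, pp, cfg)$pred - y)^2)

  assign_in <- function(obj, pth, val) {
    if (length(pth) == 1L) obj[[pth[[1]]]] <- val
    else obj[[pth[[1]]]] <- assign_in(obj[[pth[[1]]]], pth[-1], val)
    obj
  }
  paths <- list("K1", "b1", "K2", "b2",
                c("att_c", "W1"), c("att_c", "W2"), c("att_c", "b2"),
                c("att_r", "W2"),
                list("gru", 1L, "W"), list("gru", 1L, "U"),
                list("gru", 2L, "bx"), list("gru", 2L, "bh"),
                list("head", "W", 1L), list("head", "b", 2L),
                list("head", "Wout"), list("head", "bout"))
  for (pth in paths) {
    pth <- as.list(pth)
    leaf <- p; g <- gr
    for (k in pth) { leaf <- leaf[[k]]; g <- g[[k]] }
    for (j in sample(length(leaf), min(2L, length(leaf)))) {
      h <- 1e-5
      tmp <- leaf; tmp[j] <- tmp[j] + h
      lp <- loss(assign_in(p, pth, tmp))
      tmp[j] <- leaf[j] - h
      lm <- loss(assign_in(p, pth, tmp))
      num <- (lp - lm) / (2 * h)
      expect_equal(g[j], num, tolerance = 1e-4,
                   label = paste(unlist(pth), collapse = "/"))
    }
  }
})

test_that("fitting is reproducible and reduces the loss", {
  cfg <- tiny_config(batch_size = 4L, lr = 5e-3)
  set.seed(20)
  sams <- lapply(1:12, function(i) {
    r <- runif(1, 0.2, 0.8)
    ch <- array(rnorm(cfg$T * cfg$chunk_len * cfg$channels, sd = r),
                c(cfg$T, cfg$chunk_len, cfg$channels))
    swallow_sample(ch, c(0, 1, 1, 0), r, cfg$T, paste0("s", i))
  })
  f1 <- ues_fit(sams, cfg, epochs = 5, seed = 2)
  expect_lt(f1$history$mse[5], f1$history$mse[1])

  f2 <- ues_fit(sams, cfg, epochs = 5, seed = 2)
  expect_identical(f1$params, f2$params)

  # serialization round-trip preserves predictions bit-exactly
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(f1, path)
  f3 <- readRDS(path)
  expect_identical(predict(f1, sams), predict(f3, sams))

  # a batch of identical samples yields identical predictions
  same <- lapply(1:4, function(i) { s <- sams[[1]]; s$id <- paste0("d", i); s })
  pr <- predict(f1, same)
  expect_equal(max(abs(pr - pr[1])), 0)
})
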