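rot2 <- function(p, th, center = c(0, 0)) {
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  as.numeric(R %*% (p - center)) + center
}

rigid_lm <- function(lm, th, shift = c(0, 0)) {
  pts <- c("c2_ai", "c3_as", "c3_ai", "c4_ai", "tracheal_notch",
           "ues_anterior", "ues_posterior")
  args <- lapply(pts, function(nm) rot2(lm[[nm]], th) + shift)
  names(args) <- pts
  do.call(landmark_set, c(args, list(frame_index = lm$frame_index)))
}

test_that("C2-C4 axis and C3 height follow Euclidean geometry", {
  lm <- generate_landmarks(0.4, 100)
  base <- list(c2_ai = c(0, 0), c3_as = c(0, 30), c3_ai = c(0, 43),
               c4_ai = c(0, 100), tracheal_notch = c(-25, 40),
               ues_anterior = c(-60, 50), ues_posterior = c(-20, 50))
  l0 <- do.call(landmark_set, base)
  ax <- c2c4_axis(l0)
  expect_equal(ax$length, 100)
  expect_equal(ax$direction, c(0, 1))

  # 3-4-5 triangle
  l345 <- do.call(landmark_set, modifyList(base, list(c4_ai = c(60, 80))))
  expect_equal(c2c4_axis(l345)$length, 100)

  # brute-force Euclidean oracle on random pairs
  set.seed(5)
  for (i in 1:10) {
    p <- runif(2, -50, 50); q <- runif(2, -50, 50)
    li <- do.call(landmark_set, modifyList(base, list(c2_ai = p, c4_ai = q)))
    expect_equal(c2c4_axis(li)$length, sqrt(sum((p - q)^2)))
  }

  expect_equal(c3_height(l0), 13)
  lrot <- rigid_lm(l0, pi / 6)
  expect_equal(c3_height(lrot), 13, tolerance = 1e-12)

  expect_error(do.call(landmark_set,
                       modifyList(base, list(c4_ai = c(0, 0)))),
               "pseudo-axis")
  expect_error(c3_height(do.call(landmark_set,
                                 modifyList(base, list(c3_as = c(0, 43))))),
               "degenerate")
})

test_that("anchored C3 segment and A-P axis are constructed correctly", {
  base <- list(c2_ai = c(0, 0), c3_as = c(0, 30), c3_ai = c(0, 43),
               c4_ai = c(0, 100), tracheal_notch = c(50, 50),
               ues_anterior = c(10, 50), ues_posterior = c(40, 50))
  l0 <- do.call(landmark_set, base)
  seg <- anchor_c3_segment(l0)
  expect_equal(seg$from, c(50, 50))
  expect_equal(seg$to, c(50, 63))

  # oblique axis: notch (50,50), height 10, direction (0.6, 0.8) -> (56, 58)
  lob <- do.call(landmark_set, modifyList(base, list(
    c4_ai = c(60, 80), c3_as = c(0, 30), c3_ai = c(6, 38))))
  segob <- anchor_c3_segment(lob)
  expect_equal(segob$to, c(56, 58))

  # segment length always equals the C3 height (random property)
  set.seed(6)
  for (i in 1:10) {
    li <- do.call(landmark_set, modifyList(base, list(
      c3_as = runif(2, 0, 60), c3_ai = runif(2, 0, 60),
      c4_ai = runif(2, 60, 120))))
    s <- anchor_c3_segment(li)
    expect_equal(sqrt(sum((s$to - s$from)^2)), c3_height(li),
                 tolerance = 1e-12)
  }

  ax <- c2c4_axis(l0)
  line0 <- ap_axis(seg, 0, ax$direction)
  expect_equal(line0$point, l0$tracheal_notch)
  expect_equal(abs(line0$direction), c(1, 0))
  expect_error(ap_axis(seg, 1.5, ax$direction), "outside its valid range")

  # orthogonality property over random axes
  for (i in 1:10) {
    v <- runif(2, -1, 1); v <- v / sqrt(sum(v^2))
    li <- ap_axis(seg, runif(1), v)
    expect_lt(abs(sum(li$direction * v)), 1e-12)
  }
})

test_that("distension measurement is a projection and rigid-motion invariant", {
  line <- list(point = c(0, 50), direction = c(1, 0))
  expect_equal(measure_distension(c(10, 50), c(40, 50), line), 30)
  expect_equal(measure_distension(c(10, 50), c(10, 50), line), 0)

  base <- list(c2_ai = c(0, 0), c3_as = c(0, 30), c3_ai = c(0, 43),
               c4_ai = c(0, 100), tracheal_notch = c(50, 50),
               ues_anterior = c(10, 50), ues_posterior = c(40, 50))
  l0 <- do.call(landmark_set, base)
  m0 <- measure_frame(l0)
  expect_equal(m0$distension_px, 30)

  # whole-scene rigid motion leaves the measurement unchanged
  l17 <- rigid_lm(l0, 17 * pi / 180, shift = c(12, -7))
  m17 <- measure_frame(l17)
  expect_equal(m17$distension_px, 30, tolerance = 1e-9)
  expect_equal(m17$normalized_ratio, m0$normalized_ratio, tolerance = 1e-12)
})

test_that("normalized maximal distension matches the worked protocol example", {
  # frame distensions 40, 45, 43 px over a 100 px C2-C4 segment -> 0.45
  expect_equal(normalized_max_distension(c(40, 45, 43), 100), 0.45)
  expect_equal(normalized_max_distension(c(0, 0, 0), 100), 0)
  expect_equal(normalized_max_distension(c(40, 45, 43), 100, method = "mean"),
               mean(c(40, 45, 43)) / 100)
  expect_error(normalized_max_distension(numeric(0), 100), "no measured")
  expect_error(normalized_max_distension(c(40), 0), "outside its valid range")

  # uniform scene scaling leaves the ratio unchanged
  base <- list(c2_ai = c(0, 0), c3_as = c(0, 30), c3_ai = c(0, 43),
               c4_ai = c(0, 100), tracheal_notch = c(50, 50),
               ues_anterior = c(10, 50), ues_posterior = c(40, 50))
  l0 <- do.call(landmark_set, base)
  l2 <- do.call(landmark_set, c(lapply(base, function(p) 2 * p),
                                list(frame_index = 0L)))
  expect_equal(measure_frame(l2)$normalized_ratio,
               measure_frame(l0)$normalized_ratio, tolerance = 1e-12)
})

test_that("landmark files round-trip and recover planted ratios", {
  series <- uesnet:::generate_landmark_series(0.52, 90, n_frames = 5,
                                              seed = 44)
  path <- withr::local_tempfile(fileext = ".txt")
  write_landmarks(series, path)
  back <- read_landmarks(path)
  expect_length(back, 5L)
  expect_equal(measure_landmarks(back)$ratio, 0.52, tolerance = 1e-9)
  expect_equal(back[[3]]$ues_anterior, series[[3]]$ues_anterior,
               tolerance = 1e-9)
})
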