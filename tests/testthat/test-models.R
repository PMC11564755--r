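test_that("parameter counting matches closed-form sums", {
  # single conv layer: 1 filter, kernel 3, 1 input map, bias -> 4
  l <- neoseiz:::layer_conv(3L, 1L, 1L)
  m <- neoseiz:::new_model("toy", list(l))
  expect_equal(count_parameters(m), 4L)

  # baseline: hand-computed layer-by-layer sum
  conv <- function(k, nin, nout) k * nin * nout + nout
  bn <- function(maps) 2L * maps
  feb1 <- conv(3, 1, 32) + conv(3, 32, 32) * 2 + 3 * bn(32)
  feb23 <- conv(3, 32, 32) * 3 + 3 * bn(32)
  cb <- conv(3, 32, 1)
  expect_equal(count_parameters(build_baseline()),
               feb1 + 2 * feb23 + cb)
})

test_that("the enhanced architecture meets its published constraints", {
  m <- build_enhanced()
  expect_equal(round(count_parameters(m) / 1000), 45)
  rf <- receptive_field(m)
  expect_gte(rf, 304); expect_lte(rf, 336)
  spec <- architecture_spec(m)
  expect_equal(sum(spec$kind == "residual-add"), 4L)   # 4 residual FEBs
  expect_equal(sum(spec$kind == "depthwise-conv1d"), 1L)
  dw <- spec[spec$kind == "depthwise-conv1d", ]
  expect_equal(dw$filters, 64); expect_equal(dw$kernel, 5)
  expect_false(any(spec$kind == "dense"))              # fully convolutional
})

test_that("models are fully convolutional and emit probabilities", {
  set.seed(1)
  m <- build_enhanced()
  for (len in c(320, 512, 1024)) {
    p <- neoseiz:::predict_examples(m, matrix(rnorm(len * 3), len, 3))
    expect_length(p, 3L)
    expect_true(all(p >= 0 & p <= 1))
  }
  expect_equal(count_parameters(m), count_parameters(build_enhanced()))
  expect_error(neoseiz:::predict_examples(m, matrix(0, 100, 2)),
               "receptive field")

  b <- build_baseline()
  p8 <- neoseiz:::predict_examples(b, matrix(rnorm(256), 256, 1))
  expect_true(p8 >= 0 && p8 <= 1)
})

test_that("inference is deterministic and batch-size invariant", {
  set.seed(2)
  m <- build_enhanced()
  x <- matrix(rnorm(512 * 20), 512, 20)
  p_batch <- neoseiz:::predict_examples(m, x, batch_size = 20L)
  p_loop <- vapply(seq_len(20), function(i)
    neoseiz:::predict_examples(m, x[, i, drop = FALSE], batch_size = 1L),
    numeric(1))
  expect_lt(max(abs(p_batch - p_loop)), 1e-5)

  z <- matrix(0, 512, 1)
  expect_identical(neoseiz:::predict_examples(m, z),
                   neoseiz:::predict_examples(m, z))
})

test_that("channels are scored independently and fused as configured", {
  set.seed(3)
  m <- build_enhanced()
  rec32 <- recording(matrix(rnorm(32 * 40 * 2), 2), 32)
  ds <- make_windows(rec32, NULL, preprocess_config())
  pw <- predict_windows(m, ds)
  expect_equal(dim(pw), c(25L, 2L))
  # duplicating a channel duplicates its probability row
  rec_dup <- recording(rec32$signal[c(1, 1, 2), ], 32)
  pw_dup <- predict_windows(m, make_windows(rec_dup, NULL,
                                            preprocess_config()))
  expect_equal(pw_dup[, 1], pw_dup[, 2])
  expect_equal(pw_dup[, 1], pw[, 1])

  expect_equal(aggregate_channels(matrix(c(0.4, 0.9), 1)), 0.65)
  expect_equal(aggregate_channels(matrix(c(0.2, 0.8), 1)), 0.5)
  expect_equal(aggregate_channels(matrix(0.7, 1, 1)), 0.7)
  set.seed(4); pm <- matrix(runif(30), 10)
  expect_true(all(aggregate_channels(pm) <=
                  aggregate_channels(pm, "max")))
  expect_error(aggregate_channels(matrix(numeric(), 1, 0)), "empty")
})

test_that("dense whole-record scoring tracks per-window scoring", {
  set.seed(5)
  m <- build_enhanced()
  r <- tiny_record(duration_s = 90, seed = 17)
  rec32 <- bandlimit_resample(r$recording)
  pd <- predict_windows_dense(m, rec32)
  ds <- make_windows(rec32, NULL, preprocess_config())
  pw <- predict_windows(m, ds)
  expect_equal(dim(pd), dim(pw))
  # away from record borders the two paths agree closely
  interior <- 17:(nrow(pd) - 16)
  expect_lt(max(abs(pd[interior, ] - pw[interior, ])), 0.05)
})

test_that("checkpoints round-trip through save_model/load_model", {
  set.seed(6)
  m <- build_enhanced()
  x <- matrix(rnorm(512 * 4), 512, 4)
  p0 <- neoseiz:::predict_examples(m, x)
  dir <- withr::local_tempdir()
  save_model(m, file.path(dir, "ckpt"))
  expect_true(file.exists(file.path(dir, "ckpt.json")))
  m2 <- load_model(file.path(dir, "ckpt"))
  expect_equal(neoseiz:::predict_examples(m2, x), p0)
})

test_that("gradients flow through the residual blocks", {
  set.seed(7)
  m <- build_enhanced()
  x <- array(rnorm(512 * 6), dim = c(512, 1, 6))
  p <- as.numeric(neoseiz:::nn_forward(m$layers, x, training = TRUE))
  dp <- weighted_bce_grad(rep(c(0, 1), 3), p)
  neoseiz:::nn_backward(m$layers, matrix(dp, 1))
  total <- 0
  neoseiz:::walk_layers(m$layers, function(l) {
    for (g in l$grads) {
      expect_true(all(is.finite(g)))
      total <<- total + sum(abs(g))
    }
  })
  expect_gt(total, 0)
})
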