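test_that("mixup forms convex combinations and conserves label mass", {
  set.seed(1)
  x <- matrix(rnorm(40), 4, 10); y <- rep(c(0, 1), 5)

  mb1 <- mixup_batch(x, y, lambda = 1)
  expect_equal(mb1$x, x); expect_equal(mb1$y, y)

  # antisymmetric pair with lambda = 1/2 cancels, labels average
  x2 <- cbind(c(1, 2), c(-1, -2)); y2 <- c(0, 1)
  set.seed(4)                                 # permutation swaps the pair
  repeat {
    mb <- mixup_batch(x2, y2, lambda = 0.5)
    if (!isTRUE(all.equal(mb$x, x2))) break
  }
  expect_equal(mb$x, matrix(0, 2, 2))
  expect_equal(mb$y, c(0.5, 0.5))

  set.seed(2)
  for (i in 1:20) {
    mb <- mixup_batch(x, y, alpha = 0.2)
    expect_equal(mean(mb$y), mean(y))
    expect_gte(mb$lambda, 0); expect_lte(mb$lambda, 1)
  }
  expect_error(mixup_batch(x, y, alpha = 0), "alpha")
})

test_that("amplitude rescaling scales examples and nothing else", {
  x <- matrix(1, 5, 8)
  expect_equal(rescale_amplitude(x, c(1, 1)), x)
  expect_equal(rescale_amplitude(x, c(2, 2)), 2 * x)
  expect_error(rescale_amplitude(x, c(0, 2)), "range")
  set.seed(3)
  g <- as.numeric(rescale_amplitude(matrix(1, 1, 1e4), c(0.5, 2)))
  expect_gt(suppressWarnings(
    stats::ks.test(g, "punif", 0.5, 2)$p.value), 0.01)
})

test_that("weighted cross-entropy matches closed forms", {
  expect_equal(weighted_bce(1, 0.5, w1 = 2, w0 = 1), 2 * log(2))
  # unweighted reduces to standard BCE
  y <- c(0, 1, 1, 0); p <- c(0.2, 0.7, 0.9, 0.4)
  expect_equal(weighted_bce(y, p),
               -mean(y * log(p) + (1 - y) * log(1 - p)))
  # calibrated predictions give the binary entropy; perfect ones -> 0
  expect_equal(weighted_bce(0.3, 0.3),
               -(0.3 * log(0.3) + 0.7 * log(0.7)))
  expect_lt(weighted_bce(c(0, 1), c(1e-9, 1 - 1e-9)), 1e-5)
  # inverse-frequency weights have mean example weight 1
  cw <- neoseiz:::derive_class_weights(c(rep(0, 90), rep(1, 10)))
  expect_equal(unname(cw["w0"] * 0.9 + cw["w1"] * 0.1), 1)
  expect_error(neoseiz:::derive_class_weights(rep(0, 10)), "both classes")
})

test_that("training separates an amplitude-coded toy problem", {
  ex <- separable_examples(n_per_class = 80, seed = 7)
  cfg <- train_config(batch_size = 64, max_epochs = 8,
                      plateau_patience = 8, auc_subsample = Inf)
  fit <- neoseiz:::train_examples("enhanced", ex$x, ex$y, cfg, seed = 1)
  expect_gte(max(fit$history$auc), 0.99)
  expect_equal(fit$checkpoint_epoch, which.max(fit$history$auc))
  expect_true(all(diff(fit$history$epoch) == 1))
  # loss decreases over the first epochs (optimizer wiring sanity)
  expect_lt(fit$history$loss[nrow(fit$history)], fit$history$loss[1])
})

test_that("training is deterministic under a fixed seed", {
  ex <- separable_examples(n_per_class = 40, seed = 9)
  cfg <- train_config(batch_size = 40, max_epochs = 2, auc_subsample = Inf)
  f1 <- neoseiz:::train_examples("enhanced", ex$x, ex$y, cfg, seed = 5)
  f2 <- neoseiz:::train_examples("enhanced", ex$x, ex$y, cfg, seed = 5)
  expect_identical(f1$history, f2$history)
  expect_identical(neoseiz:::get_weights(f1$model),
                   neoseiz:::get_weights(f2$model))
})

test_that("ensembles average member probabilities", {
  set.seed(8)
  rec32 <- recording(matrix(rnorm(32 * 40 * 2), 2), 32)
  ds <- make_windows(rec32, NULL, preprocess_config())
  m1 <- build_enhanced(); m2 <- build_enhanced()
  p1 <- predict_windows(m1, ds); p2 <- predict_windows(m2, ds)
  pe <- ensemble_predict(list(m1, m2), ds)
  expect_equal(pe, (p1 + p2) / 2)
  expect_equal(ensemble_predict(list(m1, m1, m1), ds), p1)
  # averaging cannot increase the spread across windows
  expect_lte(stats::var(as.numeric(pe)),
             max(stats::var(as.numeric(p1)), stats::var(as.numeric(p2))))
  expect_error(ensemble_predict(list(), ds), "empty")
})

test_that("optimizer configurations validate and expose the regimes", {
  expect_error(train_config(batch_size = 1), "Mixup")
  expect_error(train_config(rescale_range = c(0, 1)), "rescale")
  bc <- baseline_train_config()
  expect_equal(bc$batch_size, 300L)
  expect_equal(bc$optimizer, "sgd_nesterov")
  expect_equal(bc$lr, 0.001); expect_equal(bc$momentum, 0.9)
  tc <- train_config()
  expect_equal(tc$batch_size, 128L)
  expect_equal(tc$optimizer, "radam")
  expect_equal(tc$lr, 1e-3)
  expect_equal(c(tc$beta1, tc$beta2), c(0.9, 0.999))
  expect_equal(tc$n_seeds, 3L)
})
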