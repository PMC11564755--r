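test_that("preprocess config validates its band edges", {
  expect_error(preprocess_config(hp_hz = 13, lp_hz = 12.8), "hp_hz")
  expect_error(preprocess_config(lp_hz = 20, fs_target = 32), "hp_hz")
  expect_error(preprocess_config(window_s = 16.3), "integer")
})

test_that("band-limiting passes 2 Hz, rejects 40 Hz and DC", {
  pc <- preprocess_config()
  for (fs in c(256, 200)) {
    t <- seq_len(fs * 30) / fs
    sine <- recording(matrix(sin(2 * pi * 2 * t), 1), fs)
    out <- bandlimit_resample(sine, pc)
    expect_equal(out$fs, 32)
    expect_equal(ncol(out$signal), 30 * 32)   # duration preserved
    rms_ratio <- sqrt(mean(out$signal^2)) / sqrt(mean(sine$signal^2))
    expect_lt(abs(rms_ratio - 1), 0.05)
  }
  t <- seq_len(256 * 30) / 256
  s40 <- bandlimit_resample(recording(matrix(sin(2 * pi * 40 * t), 1),
                                      256), pc)
  expect_lt(sqrt(mean(s40$signal^2)) / sqrt(0.5), 0.05)
  # high-pass kills DC away from the filter's edge transients
  dc <- bandlimit_resample(recording(matrix(rep(5, 256 * 30), 1), 256),
                           pc)
  inner <- as.numeric(dc$signal)[100:860]
  expect_lt(max(abs(inner)), 0.05)
  expect_error(bandlimit_resample(recording(matrix(0, 1, 100), 20), pc),
               "Nyquist")
})

test_that("filtering and resampling commute with amplitude scaling", {
  r <- tiny_record(duration_s = 60, seed = 4)$recording
  pc <- preprocess_config()
  a <- bandlimit_resample(r, pc)
  r2 <- r; r2$signal <- 2.5 * r2$signal
  b <- bandlimit_resample(r2, pc)
  # zero-phase IIR filtering near the 0.5 Hz pole amplifies rounding
  # noise, so linearity holds to ~1e-6 rather than machine precision
  expect_equal(b$signal, 2.5 * a$signal, tolerance = 1e-5)
})

test_that("windowing yields one start per second and exact bookkeeping", {
  pc <- preprocess_config()
  r <- tiny_record(duration_s = 60, seed = 6)
  rec32 <- bandlimit_resample(r$recording, pc)
  ds <- make_windows(rec32, r$annotations, pc)
  expect_equal(dim(ds$x), c(512, 8, 45))      # 60 - 16 + 1 positions
  expect_equal(ds$window_start_s, 0:44)
  # window content matches direct slicing
  expect_equal(ds$x[, 3, 11], rec32$signal[3, (10 * 32 + 1):(10 * 32 + 512)])

  short <- recording(matrix(rnorm(16 * 32), 1), 32)
  expect_equal(dim(make_windows(short, NULL, pc)$x)[3], 1L)
  expect_error(make_windows(recording(matrix(0, 1, 15 * 32), 32), NULL,
                            pc), "shorter")
})

test_that("window labels follow the majority rule", {
  pc <- preprocess_config()
  expect_equal(label_window(rep(1L, 30), 0, pc), 1L)
  expect_equal(label_window(rep(0L, 30), 5, pc), 0L)
  # exactly 8 of 16 seizure seconds counts as seizure
  m <- c(rep(1L, 8), rep(0L, 22))
  expect_equal(label_window(m, 0, pc), 1L)
  m7 <- c(rep(1L, 7), rep(0L, 23))
  expect_equal(label_window(m7, 0, pc), 0L)

  rec32 <- recording(matrix(rnorm(32 * 40), 2), 32)
  all1 <- annotation_track(mask = rep(1L, 40), duration_s = 40)
  all0 <- annotation_track(mask = rep(0L, 40), duration_s = 40)
  expect_true(all(make_windows(rec32, all1, pc)$labels == 1L))
  expect_true(all(make_windows(rec32, all0, pc)$labels == 0L))
})

test_that("flattening keeps per-channel example bookkeeping", {
  pc <- preprocess_config()
  rec32 <- recording(matrix(rnorm(32 * 30 * 3), 3), 32)
  ds <- make_windows(rec32, NULL, pc)
  ex <- flatten_examples(ds)
  expect_equal(ncol(ex$x), dim(ds$x)[3] * 3)
  expect_equal(ex$x[, 5], ds$x[, 2, 2])       # channel-fastest ordering
  expect_equal(ex$window_index[5], 2L)
  expect_equal(ex$channel_index[5], 2L)

  set.seed(1)
  th <- flatten_examples(ds, window_stride = 4, channels_per_window = 2)
  expect_equal(ncol(th$x), length(seq(1, dim(ds$x)[3], 4)) * 2)
  expect_true(all(th$channel_index %in% 1:3))
})

test_that("combining datasets concatenates windows in order", {
  pc <- preprocess_config()
  mk <- function(id) {
    r <- recording(matrix(rnorm(32 * 20 * 2), 2), 32, patient_id = id)
    make_windows(r, NULL, pc)
  }
  a <- mk("p1"); b <- mk("p2")
  both <- combine_windows(list(a, b))
  expect_equal(dim(both$x)[3], 10L)
  expect_equal(both$patient_id, rep(c("p1", "p2"), each = 5))
  expect_equal(both$x[, , 6], b$x[, , 1])
})
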