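test_that("recording constructor enforces its invariants", {
  rec <- recording(matrix(1:20 / 10, 2, 10), fs = 5,
                   channel_labels = c("a", "b"))
  expect_equal(rec$duration_s, 2)
  expect_error(recording(matrix(0, 2, 10), fs = 0), "fs")
  expect_error(recording(matrix(0, 2, 10), fs = -1), "fs")
  expect_error(recording(matrix(0, 2, 10), fs = 5, channel_labels = "a"),
               "label")
})

test_that("bipolar montage is the samplewise anode-cathode difference", {
  # identical electrodes give an all-zero derived channel
  sig <- rbind(F4 = c(1, 2, 3), C4 = c(1, 2, 3))
  rec <- recording(sig, 10, c("F4", "C4"))
  out <- derive_bipolar_montage(rec, cbind("F4", "C4"))
  expect_equal(as.numeric(out$signal), c(0, 0, 0))
  expect_equal(out$channel_labels, "F4-C4")

  # two-electrode toy
  rec2 <- recording(rbind(c(1, 2), c(0.5, 1)), 10, c("F4", "C4"))
  out2 <- derive_bipolar_montage(rec2, cbind("F4", "C4"))
  expect_equal(as.numeric(out2$signal), c(0.5, 1.0))

  expect_error(derive_bipolar_montage(rec2, cbind("F4", "Cz")), "Cz")
})

test_that("default montage matches elementwise subtraction on 19 electrodes", {
  set.seed(1)
  labs <- c("Fp1", "Fp2", "F3", "F4", "F7", "F8", "C3", "C4", "Cz", "P3",
            "P4", "T3", "T4", "T5", "T6", "O1", "O2", "Fz", "Pz")
  rec <- recording(matrix(rnorm(19 * 100), 19, 100), 256, labs)
  out <- derive_bipolar_montage(rec)
  pairs <- neonatal_bipolar_pairs()
  expect_equal(nrow(out$signal), 8L)
  for (i in seq_len(8)) {
    expect_equal(out$signal[i, ],
                 rec$signal[pairs[i, 1], ] - rec$signal[pairs[i, 2], ],
                 ignore_attr = TRUE)
  }
  # linearity: derive(a * rec) = a * derive(rec)
  rec3 <- rec; rec3$signal <- 3 * rec3$signal
  expect_equal(derive_bipolar_montage(rec3)$signal, 3 * out$signal)
})

test_that("events and masks round-trip losslessly at 1 s resolution", {
  m <- events_to_mask(data.frame(onset_s = 10, offset_s = 20), 30)
  expect_equal(sum(m), 10)
  expect_equal(which(m == 1L), 11:20)       # seconds 10..19, 1-based index

  expect_equal(events_to_mask(data.frame(onset_s = numeric(),
                                         offset_s = numeric()), 25),
               integer(25))

  set.seed(42)
  for (rep in 1:50) {
    k <- sample(1:8, 1)
    on <- sort(sample(0:200, k))
    ev <- merge_events(data.frame(onset_s = on,
                                  offset_s = on + sample(1:20, k, TRUE)))
    ev <- ev[ev$offset_s <= 240, , drop = FALSE]
    if (!nrow(ev)) next
    back <- mask_to_events(events_to_mask(ev, 240))
    expect_equal(back, ev, ignore_attr = TRUE)
  }
  expect_error(events_to_mask(data.frame(onset_s = 1, offset_s = 3), -1),
               "negative")
})

test_that("annotation track keeps mask and events consistent", {
  tr <- annotation_track(events = data.frame(onset_s = c(5, 40),
                                             offset_s = c(15, 45)),
                         duration_s = 60, patient_id = "p1")
  expect_equal(sum(tr$mask), 15)
  expect_equal(nrow(tr$events), 2L)
  # overlapping events are merged by the constructor
  tr2 <- annotation_track(events = data.frame(onset_s = c(5, 10),
                                              offset_s = c(12, 20)),
                          duration_s = 30)
  expect_equal(tr2$events, data.frame(onset_s = 5, offset_s = 20))
  expect_error(annotation_track(events = data.frame(onset_s = 5,
                                                    offset_s = 99),
                                duration_s = 60), "within")
})

test_that("EDF write-then-read recovers the signal within quantization", {
  rec <- tiny_record(duration_s = 60, seed = 9)$recording
  path <- withr::local_tempfile(fileext = ".edf")
  write_edf(rec, path)
  back <- read_edf(path)
  expect_equal(back$fs, rec$fs)
  expect_equal(ncol(back$signal), 60 * 256)
  expect_equal(back$channel_labels, rec$channel_labels)
  step <- edf_quantization_step(2000)
  expect_lt(max(abs(back$signal - rec$signal)), step)
  expect_equal(back$patient_id, rec$patient_id)
})

test_that("recording readers reject malformed input", {
  path <- withr::local_tempfile(fileext = ".rds")
  saveRDS(list(signal = matrix(0, 2, 10), fs = 0,
               channel_labels = c("a", "b"), patient_id = "x"), path)
  expect_error(read_recording(path), "fs")
  expect_error(suppressWarnings(
    read_edf(withr::local_tempfile(fileext = ".edf"))))
})

test_that("annotation CSV and mask files round-trip", {
  tr <- annotation_track(events = data.frame(onset_s = c(10, 100),
                                             offset_s = c(30, 160)),
                         duration_s = 300, patient_id = "baby1")
  csv <- withr::local_tempfile(fileext = ".csv")
  write_annotations(tr, csv)
  back <- read_annotations(csv, duration_s = 300)
  expect_equal(back$events, tr$events)
  expect_equal(back$mask, tr$mask)
  expect_equal(back$patient_id, "baby1")

  mf <- withr::local_tempfile(fileext = ".txt")
  write_mask(tr, mf)
  back2 <- read_mask(mf)
  expect_equal(back2$mask, tr$mask)
  expect_equal(back2$events, tr$events)
})
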