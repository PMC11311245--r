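test_that("dataset container round-trips bit-exactly and handles edge cases", {
  f1 <- toy_frame(64, 8, seed = 1, frame_index = 0L)
  f2 <- toy_frame(64, 8, seed = 2, frame_index = 1L, label = NA_integer_,
                  phantom_id = "calib", mode = "stable")
  ds <- rf_dataset(list(f1, f2), provenance = "unit test")
  path <- withr::local_tempfile(fileext = ".rfh5")
  write_rfh5(ds, path)
  back <- read_rfh5(path)
  expect_length(back$frames, 2L)
  expect_identical(back$frames[[1]]$samples, f1$samples)
  expect_identical(back$frames[[2]]$samples, f2$samples)
  expect_identical(back$frames[[1]]$meta, f1$meta)
  expect_identical(back$frames[[2]]$meta, f2$meta)
  expect_identical(back$provenance, "unit test")

  # determinism of the byte layout
  path2 <- withr::local_tempfile(fileext = ".rfh5")
  write_rfh5(ds, path2)
  expect_identical(readBin(path, "raw", file.size(path)),
                   readBin(path2, "raw", file.size(path2)))

  # empty container round-trips without error
  pe <- withr::local_tempfile(fileext = ".rfh5")
  write_rfh5(rf_dataset(), pe)
  expect_length(read_rfh5(pe)$frames, 0L)

  # corrupt/missing-field containers give format errors naming the problem
  expect_error(read_rfh5(withr::local_tempfile()), "no such file")
  pc <- withr::local_tempfile()
  writeBin(charToRaw("NOTRFH5!"), pc)
  expect_error(read_rfh5(pc), "magic")
  bad <- toy_frame(8, 2)
  bad$samples[1] <- NaN
  expect_error(write_rfh5(rf_dataset(list(bad)), withr::local_tempfile()),
               "non-finite")
})

test_that("frame constructor enforces metadata and sample invariants", {
  expect_error(rf_frame(matrix(Inf, 2, 2), "A", "p", 40e6, "stable", 0),
               "non-finite")
  expect_error(rf_frame(matrix(0, 2, 2), "A", "p", -1, "stable", 0),
               "sampling_rate")
  expect_error(rf_frame(matrix(0, 2, 2), "A", "p", 40e6, "stable", 0,
                        class_label = 3L), "class_label")
  expect_error(rf_dataset(list(toy_frame(8, 2, rate = 40e6),
                               toy_frame(8, 2, rate = 50e6))),
               "sampling_rate")
})

test_that("rational resampling converts 50 MHz frames onto the 40 MHz grid", {
  f <- toy_frame(2600, 4, seed = 3, rate = 50e6)
  g <- resample_frame(f, 4, 5)
  expect_identical(nrow(g$samples), 2080L)            # ceil(2600 * 4/5)
  expect_equal(g$meta$sampling_rate, 40e6)
  expect_identical(ncol(g$samples), 4L)

  expect_error(resample_frame(f, 0, 5), "positive")
  expect_error(resample_frame(f, 2, 4), "coprime")
})

test_that("resampler passes DC exactly in steady state", {
  f <- rf_frame(matrix(1, 600, 3), "B", "c", 50e6, "stable", 0)
  g <- resample_frame(f, 4, 5)
  n <- nrow(g$samples)
  # polyphase branches are normalized, so away from the zero-padded edges a
  # constant column stays constant to machine precision
  expect_lt(max(abs(g$samples[30:(n - 30), ] - 1)), 1e-12)
})

test_that("resampled pure tone keeps its physical frequency", {
  t <- (0:2599) / 50e6
  f <- rf_frame(matrix(cos(2 * pi * 5e6 * t), 2600, 1), "B", "c", 50e6,
                "stable", 0)
  g <- resample_frame(f, 4, 5)
  spec <- abs(stats::fft(g$samples[, 1]))^2
  fgrid <- (seq_len(2080) - 1) * 40e6 / 2080
  peak <- fgrid[which.max(spec[1:1040])]
  expect_lt(abs(peak - 5e6), 40e6 / 2080 + 1e-9)
})

test_that("band-limited signals survive a down-up round trip", {
  set.seed(11)
  x <- matrix(rnorm(2080 * 3), 2080, 3)
  # band-limit to 0.8x the lower Nyquist (16 MHz at 40 MHz)
  x <- apply(x, 2, function(col) {
    X <- stats::fft(col)
    fr <- (seq_along(X) - 1) / length(X) * 40e6
    fr <- pmin(fr, 40e6 - fr)
    X[fr > 16e6] <- 0
    Re(stats::fft(X, inverse = TRUE)) / length(X)
  })
  f <- rf_frame(x, "A", "c", 40e6, "stable", 0)
  rt <- resample_frame(resample_frame(f, 5, 4), 4, 5)
  err <- sqrt(sum((rt$samples - x)^2) / sum(x^2))
  expect_lt(err, 1e-2)
  # in-band energy is preserved within filter ripple
  expect_equal(sum(rt$samples^2), sum(x^2), tolerance = 1e-2)
})

test_that("uniform quantization respects level count and error bound", {
  f <- toy_frame(128, 4, seed = 5)
  q2 <- quantize_frame(f, 2)
  expect_lte(length(unique(as.vector(q2$samples))), 4L)
  expect_identical(q2$meta$bit_depth, 2L)

  q16 <- quantize_frame(f, 16)
  step <- (max(f$samples) - min(f$samples)) / (2^16 - 1)
  expect_lte(max(abs(q16$samples - f$samples)), step / 2 + 1e-12)
  # already-gridded data is unchanged
  expect_equal(quantize_frame(q16, 16)$samples, q16$samples, tolerance = 1e-12)

  expect_error(quantize_frame(f, 1), "bits")
  expect_error(quantize_frame(f, 40), "bits")
})
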