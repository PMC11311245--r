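mk_spec <- function(power, fs = 40e6) {
  structure(list(power = power,
                 freq = seq(0, fs / 2, length.out = ncol(power)),
                 n_source_patches = rep(10L, nrow(power)),
                 sampling_rate = fs), class = "depth_spectra")
}

test_that("raw transfer magnitude is the square-root power ratio", {
  set.seed(5)
  pw <- matrix(abs(rnorm(9 * 101, 5)), 9, 101)
  a <- mk_spec(pw)
  # identical machine pair: unity gain everywhere
  tf <- estimate_transfer_magnitude(a, a)
  expect_true(all(abs(tf$gamma_raw - 1) < 1e-12))

  # scaling the test RF by c scales power by c^2 and the gain by c
  b <- mk_spec(pw * 2.5^2)
  tf2 <- estimate_transfer_magnitude(a, b)
  expect_equal(tf2$gamma_raw, matrix(2.5, 9, 101), tolerance = 1e-12)

  # the reverse direction is the exact reciprocal
  tf_bwd <- estimate_transfer_magnitude(a, b, "test_to_train")
  expect_equal(tf_bwd$gamma_raw, 1 / tf2$gamma_raw, tolerance = 1e-14)

  expect_error(estimate_transfer_magnitude(a, mk_spec(pw[, 1:50])), "mismatch")
})

test_that("Wiener regularization obeys the limit conventions", {
  w <- m2mqus:::wiener_gain
  expect_equal(w(1, Inf), 1)            # high SNR leaves the gain unchanged
  expect_equal(w(2, 1), 0.4)            # (1/2) / (1/4 + 1)
  expect_equal(w(1, 0), 0)              # floor bin: pure denoising
  expect_equal(w(0, 5), 0)
  expect_equal(w(3, Inf), 3)

  # monotone in SNR for fixed gain, rising from 0 to |Gamma|
  for (g in c(0.25, 1, 2, 7)) {
    snrs <- 10^seq(-3, 6, length.out = 80)
    vals <- w(rep(g, 80), snrs)
    expect_true(all(diff(vals) > 0))
    expect_lt(vals[1], 0.05 * g)
    expect_equal(vals[80], g, tolerance = 1e-4)
  }

  pw <- matrix(1, 2, 5)
  tf <- estimate_transfer_magnitude(mk_spec(pw), mk_spec(pw))
  snr <- estimate_snr_profile(mk_spec(matrix(c(1, 2, 3, 4, 5), 2, 5, byrow = TRUE)),
                              mk_spec(matrix(c(1, 2, 3, 4, 5), 2, 5, byrow = TRUE)))
  bad <- snr; bad$snr[1, 1] <- -1
  expect_error(wiener_regularize(tf, bad), "negative")
})

test_that("zone-matched filtering is exact for unit gain and shapes spectra", {
  set.seed(6)
  d <- array(rnorm(200 * 26 * 45), c(200, 26, 45))
  p <- toy_patch_set(d, zone = rep(0:8, 5))

  unit_tf <- structure(list(gamma_raw = matrix(1, 9, 101),
                            gamma_wiener = matrix(1, 9, 101),
                            direction = "train_to_test",
                            freq = seq(0, 20e6, length.out = 101),
                            n_zones = 9L), class = "m2m_tf")
  out <- apply_transfer(p, unit_tf)
  expect_lt(max(abs(out$data - p$data)) / max(abs(p$data)), 1e-10)
  expect_identical(out$info, p$info)

  # white noise filtered by a gain G(f): output power per bin ~ G^2 x input
  gain <- 0.4 + 1.2 * exp(-((unit_tf$freq - 8e6) / 3e6)^2)
  tf2 <- unit_tf
  tf2$gamma_wiener <- matrix(gain, 9, 101, byrow = TRUE)
  set.seed(7)
  big <- array(rnorm(200 * 26 * 450), c(200, 26, 450))
  pb <- toy_patch_set(big, zone = rep(0:8, 50))
  fb <- apply_transfer(pb, tf2)
  sin_ <- average_power_spectra(pb, window = "rect")
  sout <- average_power_spectra(fb, window = "rect")
  ratio <- colMeans(sout$power) / colMeans(sin_$power)
  expect_equal(ratio[2:100], gain[2:100]^2, tolerance = 0.06)

  # unregularized transfer functions cannot be applied
  raw <- unit_tf; raw$gamma_wiener <- NULL
  expect_error(apply_transfer(p, raw), "regularized")
  # zones outside the transfer function range are rejected
  p10 <- p; p10$info$zone[1] <- 12L
  expect_error(apply_transfer(p10, tf2), "zone")
})

test_that("both directions share one SNR profile and compose to at most unity", {
  set.seed(8)
  base <- matrix(abs(rnorm(9 * 101, 10, 2)), 9, 101)
  ratio <- matrix(runif(9 * 101, 0.5, 2), 9, 101)
  bi <- build_bidirectional(mk_spec(base), mk_spec(base * ratio))
  expect_identical(bi$forward$direction, "train_to_test")
  expect_identical(bi$backward$direction, "test_to_train")
  expect_equal(bi$backward$gamma_raw, 1 / bi$forward$gamma_raw, tolerance = 1e-12)

  # Wiener-regularized round trip never amplifies: g_fwd * g_bwd <= 1,
  # approaching 1 as SNR grows (checked over a (gain, SNR) grid)
  for (snr in c(0.1, 1, 10, 1e4, 1e8)) {
    for (g in c(0.2, 0.9, 1, 3, 10)) {
      prod <- m2mqus:::wiener_gain(g, snr) * m2mqus:::wiener_gain(1 / g, snr)
      expect_lte(prod, 1 + 1e-12)
    }
    if (snr >= 1e8)
      expect_equal(m2mqus:::wiener_gain(2, snr) * m2mqus:::wiener_gain(0.5, snr),
                   1, tolerance = 1e-6)
  }

  # identical spectra: unit raw gain, and Wiener shrinkage 1/(1 + 1/SNR)
  # becomes negligible once the SNR is large
  fmhz <- seq(0, 20, length.out = 101)
  shaped <- outer(rep(1, 9), 1e3 * exp(-((fmhz - 8) / 3)^2) + 0.01)
  bi2 <- build_bidirectional(mk_spec(shaped), mk_spec(shaped))
  hi <- bi2$snr$snr > 1e3
  expect_true(any(hi))
  expect_lt(max(abs(bi2$forward$gamma_wiener[hi] - 1)), 2e-3)
  expect_lt(max(abs(bi2$backward$gamma_wiener[hi] - 1)), 2e-3)
})
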