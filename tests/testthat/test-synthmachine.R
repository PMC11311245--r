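test_that("profile constructors validate physical parameters", {
  expect_error(machine_profile(pulse_center = 30e6, sampling_rate = 40e6),
               "pulse_center")
  expect_error(machine_profile(noise_floor = -1), "noise_floor")
  expect_error(phantom_profile(scatterer_density = -1), "density")
  expect_error(phantom_profile(attenuation_slope = -0.1), "attenuation")
})

test_that("frame simulation is deterministic and physically sensible", {
  m <- tiny_machines()
  ph <- phantom_profile("p", scatterer_density = 10, powerlaw_exponent = 0.2,
                        bump_amp = 0, attenuation_slope = 0.05, sos = 1540)

  f1 <- simulate_frame(m$train, ph, seed = 5, n_lateral = 32L)
  f2 <- simulate_frame(m$train, ph, seed = 5, n_lateral = 32L)
  expect_identical(f1$samples, f2$samples)
  f3 <- simulate_frame(m$train, ph, seed = 6, n_lateral = 32L)
  expect_false(identical(f1$samples, f3$samples))

  # empty medium at zero noise: an all-zero frame
  quiet <- machine_profile("q", 9e6, 0.8, 40e6, n_axial = 800L,
                           noise_floor = 0)
  empty <- phantom_profile("e", scatterer_density = 0, attenuation_slope = 0)
  f0 <- simulate_frame(quiet, empty, seed = 1, n_lateral = 8L)
  expect_true(all(f0$samples == 0))

  # with a flat spectral signature and weak attenuation, the shallow-zone
  # spectrum peaks at the pulse center
  g <- tiny_grid()
  ph_flat <- phantom_profile("f", scatterer_density = 10,
                             powerlaw_exponent = 0, bump_amp = 0,
                             attenuation_slope = 0.05, sos = 1540)
  acc <- NULL
  for (i in 1:40) {
    fr <- simulate_frame(m$train, ph_flat, seed = 100 + i, n_lateral = 32L)
    sp <- average_power_spectra(extract_patches(fr, g), 9)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
  }
  freq <- (0:100) * 40e6 / 200
  peak_shallow <- freq[which.max(acc[1, ])]
  # the 80% fractional bandwidth makes the spectral top flat over ~1 MHz, so
  # the argmax carries a few bins of speckle jitter around the pulse center
  expect_lte(abs(peak_shallow - m$train$pulse_center), 3 * 40e6 / 200)

  # attenuation drags the spectral centroid down with depth
  ph_att <- phantom_profile("a", scatterer_density = 10, powerlaw_exponent = 0.2,
                            bump_amp = 0, attenuation_slope = 1.2, sos = 1540)
  acc2 <- NULL
  for (i in 1:40) {
    fr <- simulate_frame(m$train, ph_att, seed = 200 + i, n_lateral = 32L)
    sp <- average_power_spectra(extract_patches(fr, g), 9)
    acc2 <- if (is.null(acc2)) sp$power else acc2 + sp$power
  }
  centroid <- function(p) sum(freq * p) / sum(p)
  cents <- apply(acc2, 1, centroid)
  expect_lt(cents[9], cents[1])
  expect_lt(mean(diff(cents)), 0)
})

test_that("expected zone spectra match the analytic product model", {
  m <- tiny_machines(noise = 0.01)$train
  ph <- phantom_profile("p", scatterer_density = 12, powerlaw_exponent = 0.6,
                        bump_center = 6e6, bump_width = 1.5e6, bump_amp = 0.5,
                        attenuation_slope = 0.4, sos = 1540)
  g <- tiny_grid()
  nfr <- 120
  acc <- NULL
  for (i in seq_len(nfr)) {
    fr <- simulate_frame(m, ph, seed = 300 + i, n_lateral = 32L)
    sp <- average_power_spectra(extract_patches(fr, g), 9)
    acc <- if (is.null(acc)) sp$power else acc + sp$power
  }
  acc <- acc / nfr
  freq <- (0:100) * 40e6 / 200

  lambda_sample <- ph$scatterer_density * 1000 * 1540 / 2 / 40e6
  # the simulator's depth response is blockwise (2.5 us blocks); the expected
  # patch spectrum averages |S|^2 over the rows of the patch with the
  # spectral window's squared weights
  w2 <- (0.5 * (1 - cos(2 * pi * (0:199) / 199)))^2
  block <- round(2.5e-6 * 40e6)
  band <- which(m2mqus:::pulse_spectrum(m, freq) > 0.3)
  for (z in c(1, 5, 9)) {
    rows <- g$axial_skip + (z - 1) * g$axial_step + seq_len(g$patch_axial)
    blocks <- ceiling(rows / block)
    s2 <- rep(0, length(freq))
    for (b in unique(blocks)) {
      depth_b <- (((b - 1) * block + 1 + min(b * block, m$n_axial)) / 2 - 1) /
        40e6 * 1540 / 2
      sm <- m$gain * m2mqus:::focal_profile(m, depth_b) *
        m2mqus:::pulse_spectrum(m, freq) *
        m2mqus:::attenuation_amplitude(ph$attenuation_slope, freq, depth_b)
      s2 <- s2 + sm^2 * sum(w2[blocks == b]) / sum(w2)
    }
    expected <- lambda_sample * s2 * m2mqus:::tissue_signature(ph, freq)^2 +
      m$noise_floor^2
    expect_equal(mean(acc[z, band] / expected[band]), 1, tolerance = 0.05)
  }
})

test_that("stable calibration shares one speckle realization across machines", {
  m <- tiny_machines(noise = 0)
  calib <- phantom_profile("c", scatterer_density = 12, powerlaw_exponent = 0.3,
                           bump_amp = 0, attenuation_slope = 0.4, sos = 1545)
  # identical machines, zero noise: identical frames
  pair <- simulate_calibration_pair(m$train, m$train, calib, n_frames = 2,
                                    mode = "stable", seed = 4, n_lateral = 16L)
  expect_identical(pair$train$frames[[1]]$samples, pair$test$frames[[1]]$samples)

  # gain doubling scales the frame exactly at zero noise
  m2 <- m$train; m2$gain <- m$train$gain * 2; m2$machine_id <- "x2"
  pair2 <- simulate_calibration_pair(m$train, m2, calib, n_frames = 1,
                                     mode = "stable", seed = 4, n_lateral = 16L)
  expect_equal(pair2$test$frames[[1]]$samples,
               2 * pair2$train$frames[[1]]$samples, tolerance = 1e-10)

  # free-hand frames across machines are uncorrelated
  m3 <- tiny_machines(noise = 0.002)
  pairs <- simulate_calibration_pair(m3$train, m3$train, calib, n_frames = 30,
                                     mode = "freehand", seed = 8, n_lateral = 16L)
  cors <- vapply(seq_len(30), function(i) {
    stats::cor(as.vector(pairs$train$frames[[i]]$samples),
               as.vector(pairs$test$frames[[i]]$samples))
  }, numeric(1))
  expect_lt(abs(mean(cors)), 0.05)
})

test_that("the analytic transfer oracle matches its closed form", {
  m <- default_machines()
  # identical machines: all ones
  expect_equal(true_transfer_magnitude(m$train, m$train, 4),
               rep(1, 101))
  # pure gain ratio with identical pulses
  m2 <- m$train; m2$gain <- 3 * m$train$gain
  expect_equal(true_transfer_magnitude(m$train, m2, 0),
               rep(3, 101))
  # Gaussian pulses with different centers: log-ratio is quadratic in f
  freq <- (0:100) * 40e6 / 200
  tru <- true_transfer_magnitude(m$train, m$test, 2)
  s_a <- m$train$fractional_bandwidth * m$train$pulse_center / 2.355
  s_b <- m$test$fractional_bandwidth * m$test$pulse_center / 2.355
  row_c <- 540 + 2 * 100 + 100
  depth <- row_c / 40e6 * 1545 / 2
  lr <- log(tru) -
    log(m$test$gain * m2mqus:::focal_profile(m$test, depth) /
          (m$train$gain * m2mqus:::focal_profile(m$train, depth)))
  quad <- -(freq - m$test$pulse_center)^2 / (2 * s_b^2) +
    (freq - m$train$pulse_center)^2 / (2 * s_a^2)
  expect_equal(lr, quad, tolerance = 1e-10)
})
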