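# Small builders shared across the test files.  Everything is generated in
# code; no fixture files.

toy_frame <- function(n_axial = 2080L, n_lateral = 256L, seed = 1L,
                      machine_id = "A", phantom_id = "t1", rate = 40e6,
                      label = 1L, mode = "freehand", frame_index = 0L) {
  set.seed(seed)
  rf_frame(matrix(rnorm(n_axial * n_lateral), n_axial, n_lateral),
           machine_id = machine_id, phantom_id = phantom_id,
           sampling_rate = rate, acquisition_mode = mode,
           frame_index = frame_index, class_label = label)
}

# Hand-made patch_set without going through frames: data [pa x pl x n].
toy_patch_set <- function(data, zone = NULL, label = NULL, rate = 40e6,
                          grid = patch_grid()) {
  n <- dim(data)[3L]
  if (is.null(zone)) zone <- rep_len(0:8, n)
  if (is.null(label)) label <- rep_len(c(0L, 1L), n)
  structure(list(
    data = data,
    info = data.frame(zone = as.integer(zone), class_label = as.integer(label),
                      machine_id = "A", phantom_id = "t",
                      frame_index = 0L, lateral_pos = 0L),
    grid = grid, sampling_rate = rate), class = "patch_set")
}

# Two toy spectral classes on the standard 200 x 26 patch geometry:
# narrowband tones at distinct frequencies plus white noise.
toy_class_patches <- function(n_per_class, f0 = 5e6, f1 = 7e6, noise_sd = 0.7,
                              rate = 40e6, seed = 42L) {
  set.seed(seed)
  n <- 2L * n_per_class
  data <- array(0, c(200, 26, n))
  t <- (0:199) / rate
  for (i in seq_len(n)) {
    cls <- as.integer(i > n_per_class)
    f <- if (cls == 0L) f0 else f1
    ph <- matrix(runif(26, 0, 2 * pi), 200, 26, byrow = TRUE)
    data[, , i] <- cos(2 * pi * f * t + ph) +
      matrix(rnorm(200 * 26, sd = noise_sd), 200, 26)
  }
  toy_patch_set(data, zone = (seq_len(n) - 1L) %% 9L,
                label = rep(c(0L, 1L), each = n_per_class))
}

# Scaled-down virtual machines for simulator-heavy tests.
tiny_machines <- function(noise = 0.005) {
  list(train = machine_profile("tinyA", pulse_center = 9e6,
                               fractional_bandwidth = 0.8,
                               sampling_rate = 40e6, n_axial = 800L,
                               gain = 1, noise_floor = noise,
                               focal_depth = 0.007, focal_gain = 0.8,
                               focal_width = 0.004),
       test = machine_profile("tinyB", pulse_center = 5e6,
                              fractional_bandwidth = 1.2,
                              sampling_rate = 50e6, n_axial = 1000L,
                              gain = 2, noise_floor = noise,
                              focal_depth = 0.007, focal_gain = 0.5,
                              focal_width = 0.006))
}

tiny_grid <- function() patch_grid(axial_skip = 100L, patch_axial = 200L,
                                   patch_lateral = 8L, axial_step = 60L,
                                   lateral_step = 8L, n_axial_positions = 9L,
                                   n_lateral_positions = 4L)
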