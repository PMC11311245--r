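#' Virtual ultrasound machine profile
#'
#' Parameterizes the system response of a virtual scanner: a Gaussian
#' transmit pulse (amplitude spectrum
#' `exp(-(f - pulse_center)^2 / (2 sigma^2))` with
#' `sigma = fractional_bandwidth * pulse_center / 2.355`, i.e. the
#' fractional bandwidth is FWHM relative to the center), an overall linear
#' gain, a depth-dependent focal gain profile
#' `1 + focal_gain * exp(-((z - focal_depth) / focal_width)^2)`, additive
#' white electronic noise, a native sampling rate and a digitization depth.
#'
#' The package defaults mimic an asymmetric scanner pair: the training
#' machine pulses at 9 MHz and samples at 40 MHz; the testing machine pulses
#' at 5 MHz, samples at 50 MHz (so its frames are rate-converted by 4/5
#' before entering the shared pipeline) and applies a different gain and
#' focal profile.  See [default_machines()].
#'
#' @param machine_id Identifier string.
#' @param pulse_center Pulse center frequency (Hz), `< sampling_rate / 2`.
#' @param fractional_bandwidth FWHM bandwidth / center frequency.
#' @param sampling_rate Native RF sampling rate (Hz).
#' @param n_axial Axial samples per frame at the native rate.
#' @param gain Overall linear amplitude gain.
#' @param noise_floor Standard deviation of the additive white noise, in the
#'   amplitude units of the (unit-variance-scatterer) tissue model.
#' @param focal_depth,focal_gain,focal_width Focal gain profile parameters
#'   (m, linear, m).
#' @param bit_depth Digitization bits applied to each simulated frame.
#' @return An object of class `machine_profile`.
#' @export
machine_profile <- function(machine_id = "trainscan", pulse_center = 9e6,
                            fractional_bandwidth = 0.80, sampling_rate = 40e6,
                            n_axial = 2080L, gain = 1, noise_floor = 0.005,
                            focal_depth = 0.02, focal_gain = 0.8,
                            focal_width = 0.008, bit_depth = 16L) {
  if (pulse_center <= 0 || pulse_center >= sampling_rate / 2)
    stop("need 0 < pulse_center < sampling_rate / 2")
  if (fractional_bandwidth <= 0) stop("fractional_bandwidth must be > 0")
  if (noise_floor < 0) stop("noise_floor must be >= 0")
  structure(list(machine_id = as.character(machine_id),
                 pulse_center = pulse_center,
                 fractional_bandwidth = fractional_bandwidth,
                 sampling_rate = sampling_rate, n_axial = as.integer(n_axial),
                 gain = gain, noise_floor = noise_floor,
                 focal_depth = focal_depth, focal_gain = focal_gain,
                 focal_width = focal_width, bit_depth = as.integer(bit_depth)),
            class = "machine_profile")
}

#' @rdname machine_profile
#' @return `default_machines()` returns `list(train =, test =)` with the
#'   package's canonical asymmetric machine pair.
#' @export
default_machines <- function() {
  list(train = machine_profile("trainscan", pulse_center = 9e6,
                               fractional_bandwidth = 0.80,
                               sampling_rate = 40e6, n_axial = 2080L,
                               gain = 1, noise_floor = 0.005,
                               focal_gain = 0.8, focal_width = 0.008),
       test = machine_profile("testscan", pulse_center = 5e6,
                              fractional_bandwidth = 1.20,
                              sampling_rate = 50e6, n_axial = 2600L,
                              gain = 2, noise_floor = 0.005,
                              focal_gain = 0.5, focal_width = 0.012))
}

#' Virtual phantom profile
#'
#' The tissue signal: randomly placed point scatterers (Poisson count at
#' `scatterer_density` per mm of depth per scan line, standard-normal
#' amplitudes) colored by a parametric spectral signature -- a power law
#' `(f / 5 MHz)^(powerlaw_exponent / 2)` in amplitude times an optional
#' Gaussian bump `1 + bump_amp * exp(-(f - bump_center)^2 / (2 bump_width^2))`
#' emulating bead-size resonance -- and attenuated with depth at
#' `attenuation_slope` dB per cm per MHz (amplitude factor
#' `10^(-slope * f[MHz] * depth[cm] / 20)`).
#'
#' @param phantom_id Identifier string.
#' @param scatterer_density Expected scatterers per mm of depth per line.
#' @param powerlaw_exponent Power-law exponent of the backscatter power
#'   spectrum.
#' @param bump_center,bump_width,bump_amp Gaussian bump parameters (Hz, Hz,
#'   linear; `bump_amp = 0` disables it).
#' @param attenuation_slope dB cm^-1 MHz^-1, `>= 0`.
#' @param sos Speed of sound, m/s.
#' @param class_label 0/1 for classification phantoms, `NA` for calibration
#'   phantoms.
#' @return An object of class `phantom_profile`.
#' @export
phantom_profile <- function(phantom_id = "calib1", scatterer_density = 12,
                            powerlaw_exponent = 0.3, bump_center = 6e6,
                            bump_width = 1.2e6, bump_amp = 0,
                            attenuation_slope = 0.7, sos = 1545,
                            class_label = NA_integer_) {
  if (scatterer_density < 0) stop("scatterer_density must be >= 0")
  if (attenuation_slope < 0) stop("attenuation_slope must be >= 0")
  structure(list(phantom_id = as.character(phantom_id),
                 scatterer_density = scatterer_density,
                 powerlaw_exponent = powerlaw_exponent,
                 bump_center = bump_center, bump_width = bump_width,
                 bump_amp = bump_amp, attenuation_slope = attenuation_slope,
                 sos = sos, class_label = as.integer(class_label)),
            class = "phantom_profile")
}

#' @rdname phantom_profile
#' @return `default_phantoms()` returns `list(class0 =, class1 =, calib =)`:
#'   two classification phantoms differing in spectral tilt, bead-resonance
#'   bump and attenuation, plus a uniform calibration phantom.
#' @export
default_phantoms <- function() {
  list(class0 = phantom_profile("tissue0", scatterer_density = 10,
                                powerlaw_exponent = 0.4, bump_center = 5.5e6,
                                bump_width = 1.2e6, bump_amp = 0.6,
                                attenuation_slope = 0.3, sos = 1540,
                                class_label = 0L),
       class1 = phantom_profile("tissue1", scatterer_density = 10,
                                powerlaw_exponent = 1.0, bump_center = 7.5e6,
                                bump_width = 1.2e6, bump_amp = 0.6,
                                attenuation_slope = 0.3, sos = 1539,
                                class_label = 1L),
       calib = phantom_profile("calib1", scatterer_density = 12,
                               powerlaw_exponent = 0.3, bump_amp = 0,
                               attenuation_slope = 0.7, sos = 1545))
}

# Machine pulse amplitude spectrum (no gain/focal factors).
pulse_spectrum <- function(machine, f) {
  sigma <- machine$fractional_bandwidth * machine$pulse_center / 2.355
  exp(-(f - machine$pulse_center)^2 / (2 * sigma^2))
}

focal_profile <- function(machine, depth) {
  1 + machine$focal_gain * exp(-((depth - machine$focal_depth) / machine$focal_width)^2)
}

attenuation_amplitude <- function(slope_db_cm_mhz, f_hz, depth_m) {
  10^(-(slope_db_cm_mhz * (f_hz / 1e6) * (depth_m * 100)) / 20)
}

tissue_signature <- function(phantom, f) {
  amp <- (f / 5e6)^(phantom$powerlaw_exponent / 2)
  if (phantom$bump_amp != 0)
    amp <- amp * (1 + phantom$bump_amp *
                    exp(-(f - phantom$bump_center)^2 / (2 * phantom$bump_width^2)))
  amp
}

# Scatterer field drawn in echo-time coordinates, machine-independent, so a
# stable acquisition can share one realization across machines.
draw_scatterers <- function(phantom, duration, n_lateral, seed) {
  with_seed(seed, {
    depth_mm <- duration * phantom$sos / 2 * 1000
    counts <- stats::rpois(n_lateral, phantom$scatterer_density * depth_mm)
    total <- sum(counts)
    list(line = rep.int(seq_len(n_lateral), counts),
         time = stats::runif(total, 0, duration),
         amp = stats::rnorm(total))
  })
}

# Mirror a one-sided amplitude response onto the full FFT grid (even length).
full_gain <- function(one_sided, n) c(one_sided, one_sided[seq(n %/% 2L, 2L)])

#' Simulate one RF frame
#'
#' Implements the product model of the echo spectrum -- system response
#' times tissue signal: per scan line, a seeded scatterer sequence is drawn
#' from the phantom, colored (zero-phase) by the phantom's spectral
#' signature, convolved blockwise with a depth-varying pulse whose spectrum
#' is the machine's Gaussian pulse scaled by the focal gain profile and the
#' phantom's attenuation at the block's center depth (blocks of 2.5 us of
#' echo time, piecewise-stationary), then overlaid with white noise at the
#' machine's noise floor and quantized to its bit depth.  Deterministic
#' under `(seed, reflectivity_seed)`.
#'
#' @param machine A [machine_profile()].
#' @param phantom A [phantom_profile()].
#' @param seed Seed for the noise realization.
#' @param reflectivity_seed Seed for the scatterer realization (defaults to
#'   `seed`); share it across machines to emulate a clamped-transducer
#'   acquisition.
#' @param n_lateral Number of scan lines.
#' @param frame_index,acquisition_mode Metadata for the returned frame.
#' @param scatterers Optionally a pre-drawn scatterer field (internal use by
#'   [simulate_calibration_pair()]).
#' @return An [rf_frame()] of `machine$n_axial x n_lateral` samples at the
#'   machine's native rate.
#' @export
simulate_frame <- function(machine, phantom, seed, reflectivity_seed = seed,
                           n_lateral = 256L, frame_index = 0L,
                           acquisition_mode = "freehand", scatterers = NULL) {
  stopifnot(inherits(machine, "machine_profile"), inherits(phantom, "phantom_profile"))
  n <- machine$n_axial
  fs <- machine$sampling_rate
  duration <- n / fs
  if (is.null(scatterers))
    scatterers <- draw_scatterers(phantom, duration, n_lateral, reflectivity_seed)
  clean <- clean_rf(machine, phantom, scatterers, n_lateral)
  noisy <- clean + with_seed(seed, {
    if (machine$noise_floor > 0)
      matrix(stats::rnorm(n * n_lateral, sd = machine$noise_floor), n, n_lateral)
    else matrix(0, n, n_lateral)
  })
  f <- rf_frame(noisy, machine_id = machine$machine_id,
                phantom_id = phantom$phantom_id, sampling_rate = fs,
                acquisition_mode = acquisition_mode, frame_index = frame_index,
                class_label = phantom$class_label, bit_depth = machine$bit_depth)
  quantize_frame(f, machine$bit_depth)
}

# Noise-free RF field for a scatterer realization: tissue coloring on the
# whole line, then blockwise depth-varying system filtering.
clean_rf <- function(machine, phantom, scatterers, n_lateral) {
  n <- machine$n_axial
  fs <- machine$sampling_rate

  # Bin scatterers onto the native time grid.  Amplitudes are normalized by
  # the sampling interval (referenced to a 40 MHz grid) so that the same
  # physical scatterer field yields the same continuous-time echo waveform
  # regardless of the machine's native rate.
  r <- matrix(0, n, n_lateral)
  idx <- pmin(pmax(round(scatterers$time * fs) + 1, 1), n)
  lin <- (scatterers$line - 1L) * n + idx
  amp <- scatterers$amp * (fs / 4e7)
  while (length(lin)) {                # accumulate colliding bins
    first <- !duplicated(lin)
    r[lin[first]] <- r[lin[first]] + amp[first]
    lin <- lin[!first]; amp <- amp[!first]
  }

  # blockwise depth-varying response: machine system response times the
  # phantom's (depth-independent) spectral signature, zero-phase per block
  block <- max(16L, round(2.5e-6 * fs))
  pad <- round(1.6e-6 * fs)
  lseg <- block + 2L * pad
  if (lseg %% 2L == 1L) { pad <- pad + 1L; lseg <- lseg + 1L }
  fseg <- (seq_len(lseg %/% 2L + 1L) - 1L) * fs / lseg
  tsig <- tissue_signature(phantom, fseg)
  rp <- rbind(matrix(0, pad, n_lateral), r, matrix(0, pad, n_lateral))
  out <- matrix(0, n, n_lateral)
  n_blocks <- ceiling(n / block)
  for (b in seq_len(n_blocks)) {
    r0 <- (b - 1L) * block + 1L
    r1 <- min(b * block, n)
    depth <- ((r0 + r1) / 2 - 1) / fs * phantom$sos / 2
    gain <- machine$gain * focal_profile(machine, depth) *
      pulse_spectrum(machine, fseg) * tsig *
      attenuation_amplitude(phantom$attenuation_slope, fseg, depth)
    last <- min(r0 + lseg - 1L, nrow(rp))
    seg <- rp[r0:last, , drop = FALSE]
    if (nrow(seg) < lseg) seg <- rbind(seg, matrix(0, lseg - nrow(seg), n_lateral))
    nkeep <- r1 - r0 + 1L
    y <- Re(stats::mvfft(stats::mvfft(seg) * full_gain(gain, lseg), inverse = TRUE)) / lseg
    out[r0:r1, ] <- y[pad + seq_len(nkeep), , drop = FALSE]
  }
  out
}

#' Simulate a two-machine calibration acquisition
#'
#' Stable mode emulates a clamped transducer moved between machines: a single
#' scatterer realization (one calibration view) is shared by both machines
#' and all frames, which differ only in electronic noise.  Free-hand mode
#' draws an independent realization for every frame on every machine.
#'
#' @param machine_a,machine_b [machine_profile()]s (training and testing
#'   machine).
#' @param phantom The calibration [phantom_profile()].
#' @param n_frames Frames per machine.
#' @param mode `"stable"` or `"freehand"`.
#' @param seed Integer seed.
#' @param n_lateral Scan lines per frame.
#' @return List with [rf_dataset()]s `train` and `test` at each machine's
#'   native rate.
#' @export
simulate_calibration_pair <- function(machine_a, machine_b, phantom,
                                      n_frames = 10L, mode = c("stable", "freehand"),
                                      seed = 1L, n_lateral = 256L) {
  mode <- match.arg(mode)
  one <- function(machine, stream) {
    frames <- vector("list", n_frames)
    if (mode == "stable") {
      sc <- draw_scatterers(phantom, machine$n_axial / machine$sampling_rate,
                            n_lateral, derive_seed(seed, 0L))
      clean <- clean_rf(machine, phantom, sc, n_lateral)
      for (i in seq_len(n_frames)) {
        noisy <- clean + with_seed(derive_seed(seed, stream * 1000L + i), {
          matrix(stats::rnorm(length(clean), sd = machine$noise_floor),
                 nrow(clean), ncol(clean))
        })
        f <- rf_frame(noisy, machine$machine_id, phantom$phantom_id,
                      machine$sampling_rate, "stable", i - 1L,
                      bit_depth = machine$bit_depth)
        frames[[i]] <- quantize_frame(f, machine$bit_depth)
      }
    } else {
      for (i in seq_len(n_frames)) {
        frames[[i]] <- simulate_frame(
          machine, phantom, seed = derive_seed(seed, stream * 1000L + i),
          reflectivity_seed = derive_seed(seed, stream * 100000L + i),
          n_lateral = n_lateral, frame_index = i - 1L,
          acquisition_mode = "freehand")
      }
    }
    rf_dataset(frames, provenance = sprintf("simulated %s calibration, %s",
                                            mode, machine$machine_id))
  }
  list(train = one(machine_a, 1L), test = one(machine_b, 2L))
}

#' Analytic transfer-function magnitude between two virtual machines
#'
#' The oracle for [estimate_transfer_magnitude()]: the ratio of the two
#' machines' system responses `|S_b(z, f) / S_a(z, f)|` evaluated at the
#' center depth of an axial zone on the patch frequency grid.  Phantom
#' factors (tissue signature, attenuation) are common to both machines
#' during calibration and cancel.
#'
#' @param machine_a,machine_b [machine_profile()]s.
#' @param zone Axial zone index (0-based).
#' @param grid The [patch_grid()] defining zone geometry (on the training
#'   machine's output grid).
#' @param sampling_rate Sampling rate of the shared frequency grid (defaults
#'   to machine_a's).
#' @param sos Speed of sound used to map samples to depth.
#' @return Numeric vector of `patch_axial / 2 + 1` gain values.
#' @export
true_transfer_magnitude <- function(machine_a, machine_b, zone,
                                    grid = patch_grid(),
                                    sampling_rate = machine_a$sampling_rate,
                                    sos = 1545) {
  pa <- grid$patch_axial
  f <- (seq_len(pa %/% 2L + 1L) - 1L) * sampling_rate / pa
  row_c <- grid$axial_skip + zone * grid$axial_step + pa / 2
  depth <- row_c / sampling_rate * sos / 2
  s_a <- machine_a$gain * focal_profile(machine_a, depth) * pulse_spectrum(machine_a, f)
  s_b <- machine_b$gain * focal_profile(machine_b, depth) * pulse_spectrum(machine_b, f)
  s_b / s_a
}
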