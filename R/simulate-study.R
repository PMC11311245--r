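#' Study configuration for the synthetic two-machine benchmark
#'
#' Sizes and seeds for [simulate_study()].  The defaults are the package's
#' desk-scale study conditions: 100 free-hand frames per classification
#' phantom per machine, a 10-frame stable calibration acquisition (one
#' clamped view), a 100-frame free-hand calibration acquisition, and 25
#' adaptation frames per phantom from the testing machine (for the
#' fine-tuning and threshold baselines).
#'
#' @param n_frames Classification frames per phantom per machine.
#' @param n_adapt_frames Adaptation frames per phantom (testing machine).
#' @param n_calib_stable,n_calib_freehand Calibration frames per machine.
#' @param n_lateral Scan lines per frame.
#' @param machines `list(train =, test =)` of [machine_profile()]s.
#' @param phantoms `list(class0 =, class1 =, calib =)` of
#'   [phantom_profile()]s.
#' @param grid A [patch_grid()].
#' @param seed Master seed; all realizations derive from it.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_frames = 100L, n_adapt_frames = 25L,
                       n_calib_stable = 10L, n_calib_freehand = 100L,
                       n_lateral = 256L, machines = default_machines(),
                       phantoms = default_phantoms(), grid = patch_grid(),
                       seed = 1L) {
  structure(list(n_frames = as.integer(n_frames),
                 n_adapt_frames = as.integer(n_adapt_frames),
                 n_calib_stable = as.integer(n_calib_stable),
                 n_calib_freehand = as.integer(n_calib_freehand),
                 n_lateral = as.integer(n_lateral), machines = machines,
                 phantoms = phantoms, grid = grid, seed = as.integer(seed)),
            class = "sim_config")
}

# Resample a frame to the target rate if needed (reduced rational ratio).
conform_rate <- function(frame, target_rate) {
  if (isTRUE(all.equal(frame$meta$sampling_rate, target_rate))) return(frame)
  ud <- rate_ratio(target_rate, frame$meta$sampling_rate)
  resample_frame(frame, ud[1L], ud[2L])
}

# Stream frames of one machine/several phantoms directly into a patch_set,
# so full frame datasets never sit in memory.
simulate_domain_patches <- function(machine, phantoms, n_frames, grid, seed,
                                    target_rate, n_lateral = 256L,
                                    acquisition_mode = "freehand") {
  sets <- list()
  k <- 0L
  for (ph in phantoms) {
    for (i in seq_len(n_frames)) {
      k <- k + 1L
      fr <- simulate_frame(machine, ph,
                           seed = derive_seed(seed, 2L * k),
                           reflectivity_seed = derive_seed(seed, 2L * k + 1L),
                           n_lateral = n_lateral, frame_index = i - 1L,
                           acquisition_mode = acquisition_mode)
      fr <- conform_rate(fr, target_rate)
      sets[[k]] <- extract_patches(fr, grid)
    }
  }
  do.call(rbind_patches, sets)
}

# Streamed per-zone periodogram accumulation for calibration acquisitions.
accumulate_spectra <- function(acc, patches, n_zones) {
  sp <- average_power_spectra(patches, n_zones)
  if (is.null(acc)) {
    sp$power <- sp$power * sp$n_source_patches
    return(sp)
  }
  acc$power <- acc$power + sp$power * sp$n_source_patches
  acc$n_source_patches <- acc$n_source_patches + sp$n_source_patches
  acc
}

finalize_spectra <- function(acc) {
  acc$power <- acc$power / acc$n_source_patches
  acc
}

#' Depth spectra of a simulated two-machine calibration acquisition
#'
#' Streams a calibration acquisition (stable or free-hand) through
#' resampling and patch extraction, accumulating the per-zone averaged power
#' spectra of both machines without holding the frames.
#'
#' @inheritParams simulate_calibration_pair
#' @param grid A [patch_grid()].
#' @return List with `depth_spectra` elements `train` and `test`, plus
#'   `mode` and `n_frames`.
#' @export
calibration_spectra <- function(machine_a, machine_b, phantom, n_frames,
                                mode = c("stable", "freehand"), seed = 1L,
                                grid = patch_grid(), n_lateral = 256L) {
  mode <- match.arg(mode)
  target_rate <- machine_a$sampling_rate
  n_zones <- grid$n_axial_positions
  one <- function(machine, stream) {
    acc <- NULL
    clean <- NULL
    if (mode == "stable") {
      sc <- draw_scatterers(phantom, machine$n_axial / machine$sampling_rate,
                            n_lateral, derive_seed(seed, 0L))
      clean <- clean_rf(machine, phantom, sc, n_lateral)
    }
    for (i in seq_len(n_frames)) {
      if (mode == "stable") {
        noisy <- clean + with_seed(derive_seed(seed, stream * 1000L + i), {
          matrix(stats::rnorm(length(clean), sd = machine$noise_floor),
                 nrow(clean), ncol(clean))
        })
        fr <- quantize_frame(rf_frame(noisy, machine$machine_id,
                                      phantom$phantom_id, machine$sampling_rate,
                                      "stable", i - 1L,
                                      bit_depth = machine$bit_depth),
                             machine$bit_depth)
      } else {
        fr <- simulate_frame(machine, phantom,
                             seed = derive_seed(seed, stream * 1000L + i),
                             reflectivity_seed = derive_seed(seed, stream * 100000L + i),
                             n_lateral = n_lateral, frame_index = i - 1L,
                             acquisition_mode = "freehand")
      }
      fr <- conform_rate(fr, target_rate)
      acc <- accumulate_spectra(acc, extract_patches(fr, grid), n_zones)
    }
    finalize_spectra(acc)
  }
  list(train = one(machine_a, 1L), test = one(machine_b, 2L),
       mode = mode, n_frames = n_frames)
}

#' Simulate the full two-machine classification study
#'
#' Generates everything the experiment workflows need: classification
#' patches for both machines and both tissue classes (free-hand, class
#' balanced), adaptation patches from the testing machine, and stable plus
#' free-hand calibration acquisitions of the uniform calibration phantom
#' reduced to depth spectra.  All testing-machine data are rate-converted to
#' the training machine's grid before patch extraction.
#'
#' @param config A [sim_config()].
#' @param out_dir If non-`NULL`, additionally writes small `.rfh5` datasets
#'   of the calibration acquisitions there (for interoperability; intended
#'   for small configurations).
#' @return A list of class `m2m_study` with `train`, `test`, `adapt`
#'   (`patch_set`s), `calib` (list `stable`, `freehand` of
#'   [calibration_spectra()] results), `machines`, `phantoms`, `grid`,
#'   `config`.
#' @export
simulate_study <- function(config = sim_config(), out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  mA <- config$machines$train; mB <- config$machines$test
  classes <- config$phantoms[c("class0", "class1")]
  rate <- mA$sampling_rate
  g <- config$grid
  train <- simulate_domain_patches(mA, classes, config$n_frames, g,
                                   derive_seed(config$seed, 11L), rate,
                                   config$n_lateral)
  test <- simulate_domain_patches(mB, classes, config$n_frames, g,
                                  derive_seed(config$seed, 22L), rate,
                                  config$n_lateral)
  adapt <- simulate_domain_patches(mB, classes, config$n_adapt_frames, g,
                                   derive_seed(config$seed, 33L), rate,
                                   config$n_lateral)
  calib <- list(
    stable = calibration_spectra(mA, mB, config$phantoms$calib,
                                 config$n_calib_stable, "stable",
                                 derive_seed(config$seed, 44L), g,
                                 config$n_lateral),
    freehand = calibration_spectra(mA, mB, config$phantoms$calib,
                                   config$n_calib_freehand, "freehand",
                                   derive_seed(config$seed, 55L), g,
                                   config$n_lateral))
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    pair <- simulate_calibration_pair(mA, mB, config$phantoms$calib,
                                      n_frames = min(config$n_calib_stable, 10L),
                                      mode = "stable",
                                      seed = derive_seed(config$seed, 44L),
                                      n_lateral = config$n_lateral)
    write_rfh5(pair$train, file.path(out_dir, "calib_stable_train.rfh5"))
    write_rfh5(pair$test, file.path(out_dir, "calib_stable_test.rfh5"))
  }
  structure(list(train = train, test = test, adapt = adapt, calib = calib,
                 machines = config$machines, phantoms = config$phantoms,
                 grid = g, config = config),
            class = "m2m_study")
}

#' @export
print.m2m_study <- function(x, ...) {
  cat(sprintf("<m2m_study> train %d / test %d / adapt %d patches; calibration: stable %d + freehand %d frames\n",
              n_patches(x$train), n_patches(x$test), n_patches(x$adapt),
              x$calib$stable$n_frames, x$calib$freehand$n_frames))
  invisible(x)
}
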