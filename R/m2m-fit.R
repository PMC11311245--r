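#' Fit a machine-to-machine calibration from phantom acquisitions
#'
#' The top-level estimator.  Takes the same calibration phantom imaged on the
#' training and the testing machine, brings both onto one sampling grid
#' (resampling the test acquisition by the reduced rational rate ratio when
#' needed), extracts depth-stratified patches, averages per-zone power
#' spectra, and returns the depth-resolved transfer function in both
#' directions together with its SNR profile, each direction
#' Wiener-regularized.
#'
#' @param calib_train,calib_test [rf_dataset()]s (or ready `patch_set`s) of
#'   the calibration phantom on the two machines.
#' @param grid A [patch_grid()] defining the depth zones.
#' @param n_zones Number of axial zones; defaults to the grid's axial
#'   positions.
#' @return An object of class `m2m_calibration`: list with `forward` and
#'   `backward` [estimate_transfer_magnitude()] objects (`gamma_wiener`
#'   filled), `snr`, `freq`, and `provenance`.  Methods: `print`, `summary`,
#'   `plot`, `predict` (applies the calibration to a `patch_set`).
#' @examples
#' \donttest{
#' A <- machine_profile("A"); B <- machine_profile("B")
#' pair <- simulate_calibration_pair(A, B, phantom_profile("calib"),
#'                                   n_frames = 4, mode = "stable", seed = 1)
#' cal <- m2m_transfer(pair$train, pair$test)
#' print(cal)
#' }
#' @export
m2m_transfer <- function(calib_train, calib_test, grid = patch_grid(),
                         n_zones = grid$n_axial_positions) {
  as_patches <- function(x, rate_ref = NULL) {
    if (inherits(x, "patch_set")) return(x)
    if (!inherits(x, "rf_dataset")) stop("inputs must be rf_dataset or patch_set")
    if (!is.null(rate_ref)) {
      rate <- dataset_rate(x)
      if (!isTRUE(all.equal(rate, rate_ref))) {
        ud <- rate_ratio(rate_ref, rate)
        x <- resample_dataset(x, ud[1L], ud[2L])
      }
    }
    extract_patches(x, grid)
  }
  ptr <- as_patches(calib_train)
  pte <- as_patches(calib_test, rate_ref = ptr$sampling_rate)
  if (!isTRUE(all.equal(ptr$sampling_rate, pte$sampling_rate)))
    stop("calibration acquisitions must share one sampling rate")
  str_ <- average_power_spectra(ptr, n_zones)
  ste <- average_power_spectra(pte, n_zones)
  bi <- build_bidirectional(str_, ste)
  structure(list(forward = bi$forward, backward = bi$backward, snr = bi$snr,
                 freq = str_$freq,
                 provenance = list(
                   phantom_id = ptr$info$phantom_id[1L],
                   acquisition_mode = "unknown",
                   machines = c(train = ptr$info$machine_id[1L],
                                test = pte$info$machine_id[1L]),
                   n_patches = c(train = n_patches(ptr), test = n_patches(pte)))),
            class = "m2m_calibration")
}

# Reduced integer up/down factors turning `from` Hz into `to` Hz.
rate_ratio <- function(to, from) {
  up <- round(to); down <- round(from)
  g <- gcd_num(up, down)
  c(as.integer(up / g), as.integer(down / g))
}

gcd_num <- function(a, b) if (b < 0.5) a else gcd_num(b, a %% b)

#' @export
print.m2m_calibration <- function(x, ...) {
  cat(sprintf("<m2m_calibration> %s -> %s, phantom %s\n",
              x$provenance$machines[["train"]], x$provenance$machines[["test"]],
              x$provenance$phantom_id))
  cat(sprintf("  %d zones x %d frequency bins (0 - %.1f MHz)\n",
              x$forward$n_zones, length(x$freq), max(x$freq) / 1e6))
  hi <- x$snr$snr > 10
  cat(sprintf("  bins with SNR > 10: %.0f%%; median |Gamma| there: %.3f\n",
              100 * mean(hi),
              stats::median(x$forward$gamma_wiener[hi])))
  invisible(x)
}

#' @export
summary.m2m_calibration <- function(object, ...) {
  hi <- object$snr$snr > 10
  out <- list(
    machines = object$provenance$machines,
    n_zones = object$forward$n_zones,
    n_bins = length(object$freq),
    frac_high_snr = mean(hi),
    gamma_range_high_snr = range(object$forward$gamma_wiener[hi]),
    per_zone_floor = cbind(train = object$snr$noise_floor_train,
                           test = object$snr$noise_floor_test))
  class(out) <- "summary.m2m_calibration"
  out
}

#' @export
print.summary.m2m_calibration <- function(x, ...) {
  cat(sprintf("M2M calibration %s -> %s: %d zones, %d bins, %.0f%% bins SNR > 10\n",
              x$machines[["train"]], x$machines[["test"]], x$n_zones, x$n_bins,
              100 * x$frac_high_snr))
  cat(sprintf("forward gain in high-SNR band: %.3f - %.3f\n",
              x$gamma_range_high_snr[1], x$gamma_range_high_snr[2]))
  invisible(x)
}

#' @export
#' @param object,newdata,direction `predict` applies the fitted calibration
#'   to a `patch_set` in the given direction.
#' @rdname m2m_transfer
predict.m2m_calibration <- function(object, newdata,
                                    direction = c("train_to_test", "test_to_train"),
                                    ...) {
  apply_transfer(newdata, object, direction = match.arg(direction))
}

#' @export
plot.m2m_calibration <- function(x, which = c("gain", "snr"), ...) {
  which <- match.arg(which)
  f <- x$freq / 1e6
  if (which == "gain") {
    graphics::matplot(f, t(x$forward$gamma_wiener), type = "l", lty = 1,
                      xlab = "frequency (MHz)", ylab = "regularized |Gamma|",
                      main = "M2M transfer function by depth zone", ...)
  } else {
    graphics::matplot(f, t(pmax(x$snr$snr, 1e-3)), type = "l", lty = 1, log = "y",
                      xlab = "frequency (MHz)", ylab = "SNR",
                      main = "calibration SNR by depth zone", ...)
    graphics::abline(h = 10, lty = 2)
  }
  invisible(x)
}
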