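#' Depth-resolved average power spectra of a patch collection
#'
#' For every axial zone, each patch column (a `patch_axial`-sample RF segment)
#' is turned into a one-sided periodogram -- no zero-padding,
#' `n_fft = patch_axial`, normalized as `|FFT|^2 / (n_fft * mean(w^2))` so
#' white noise of variance `s^2` has expected power `s^2` in every bin --
#' and the periodograms are averaged arithmetically over columns, patches and
#' frames of that zone.  The default Hann taper keeps sidelobe leakage from
#' the pulse peak out of the low-power band edges, where leakage otherwise
#' biases spectral ratios of steep spectra by several percent; a rectangular
#' window is available for diagnostic use.
#'
#' @param patches A `patch_set` covering every zone `0 .. n_zones - 1`.
#' @param n_zones Number of axial zones (default 9).
#' @param window Taper applied to each column: `"hann"` (default) or
#'   `"rect"`.
#' @return An object of class `depth_spectra`: `power`
#'   (`n_zones x n_freq_bins`), `freq` (Hz, `0 .. Fs/2`),
#'   `n_source_patches` (per zone), `sampling_rate`.
#' @export
average_power_spectra <- function(patches, n_zones = 9L,
                                  window = c("hann", "rect")) {
  stopifnot(inherits(patches, "patch_set"))
  window <- match.arg(window)
  pa <- dim(patches$data)[1L]
  nb <- pa %/% 2L + 1L
  w <- if (window == "hann")
    0.5 * (1 - cos(2 * pi * (seq_len(pa) - 1L) / (pa - 1L)))
  else rep(1, pa)
  wnorm <- mean(w^2)
  zones <- seq_len(n_zones) - 1L
  missing <- setdiff(zones, unique(patches$info$zone))
  if (length(missing))
    stop("zones with no patches: ", paste(missing, collapse = ", "))
  power <- matrix(0, n_zones, nb)
  nsrc <- integer(n_zones)
  for (z in zones) {
    idx <- which(patches$info$zone == z)
    x <- patches$data[, , idx, drop = FALSE]
    dim(x) <- c(pa, length(x) / pa)
    pf <- abs(stats::mvfft(x * w))^2 / (pa * wnorm)
    power[z + 1L, ] <- rowMeans(pf[seq_len(nb), , drop = FALSE])
    nsrc[z + 1L] <- length(idx)
  }
  fs <- patches$sampling_rate
  structure(list(power = power,
                 freq = (seq_len(nb) - 1L) * fs / pa,
                 n_source_patches = nsrc,
                 sampling_rate = fs),
            class = "depth_spectra")
}

#' Per-zone, per-bin SNR from the noise floor of two calibration spectra
#'
#' For each domain and zone, the noise floor is the minimum of the averaged
#' power spectrum over frequency bins (the spectral minimum falls outside the
#' transducer band and is taken to represent noise-only energy).  The SNR in
#' bin `f` is `(power(f) - floor) / floor`, and the combined profile is the
#' elementwise minimum of the two domains, so it is zero at each zone's floor
#' bin.
#'
#' @param spec_train,spec_test `depth_spectra` of the same calibration
#'   phantom on the training and testing machines (matching frequency grids).
#' @return An object of class `snr_profile` with matrices `snr_train`,
#'   `snr_test`, `snr` and per-zone vectors `noise_floor_train`,
#'   `noise_floor_test`.
#' @export
estimate_snr_profile <- function(spec_train, spec_test) {
  check_matching_spectra(spec_train, spec_test)
  floor_of <- function(p) apply(p, 1L, min)
  snr_of <- function(p, fl) {
    if (any(fl <= 0)) stop("degenerate spectrum: zero noise floor")
    sweep(sweep(p, 1L, fl, "-"), 1L, fl, "/")
  }
  ftr <- floor_of(spec_train$power); fte <- floor_of(spec_test$power)
  str_ <- snr_of(spec_train$power, ftr)
  ste <- snr_of(spec_test$power, fte)
  structure(list(snr_train = str_, snr_test = ste,
                 snr = pmin(str_, ste),
                 noise_floor_train = ftr, noise_floor_test = fte,
                 freq = spec_train$freq),
            class = "snr_profile")
}

check_matching_spectra <- function(a, b) {
  stopifnot(inherits(a, "depth_spectra"), inherits(b, "depth_spectra"))
  if (!isTRUE(all.equal(a$freq, b$freq)) || !identical(dim(a$power), dim(b$power)))
    stop("spectra have mismatching frequency grids or zone counts")
  invisible(TRUE)
}
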