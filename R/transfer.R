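#' Estimate the raw M2M transfer-function magnitude
#'
#' The machine-to-machine transfer function is the ratio of the two machines'
#' system responses, observed through a shared calibration phantom: the
#' tissue factor cancels in the ratio of the averaged power spectra, leaving
#' `|Gamma|(z, f) = sqrt(P_test(z, f) / P_train(z, f))` per axial zone for
#' the train-to-test direction (the reciprocal for test-to-train).  The
#' magnitude is estimated zone by zone; the division is floored at
#' `1e-12 * max(denominator)` so degenerate bins cannot produce infinities.
#'
#' @param spec_train,spec_test `depth_spectra` of the same calibration
#'   phantom acquired on the two machines.
#' @param direction `"train_to_test"` or `"test_to_train"`.
#' @return An object of class `m2m_tf` with `gamma_raw`
#'   (`n_zones x n_freq_bins`), `gamma_wiener` (`NULL` until
#'   [wiener_regularize()] is applied), `direction`, `freq`.
#' @seealso [wiener_regularize()], [apply_transfer()], [build_bidirectional()]
#' @export
estimate_transfer_magnitude <- function(spec_train, spec_test,
                                        direction = c("train_to_test", "test_to_train")) {
  check_matching_spectra(spec_train, spec_test)
  direction <- match.arg(direction)
  g <- sqrt(guarded_ratio(spec_test$power, spec_train$power))
  if (direction == "test_to_train") g <- guarded_reciprocal(g)
  structure(list(gamma_raw = g, gamma_wiener = NULL, direction = direction,
                 freq = spec_train$freq, n_zones = nrow(g)),
            class = "m2m_tf")
}

guarded_ratio <- function(num, den) {
  eps <- 1e-12 * max(den)
  if (eps == 0) stop("degenerate spectrum: all-zero denominator")
  num / pmax(den, eps)
}

guarded_reciprocal <- function(g) {
  eps <- 1e-12 * max(g)
  out <- g
  out[] <- ifelse(g > eps, 1 / g, 0)
  out
}

#' Wiener-inspired SNR regularization of a transfer function
#'
#' Damps the spectral gain where the calibration SNR is poor:
#' `Gamma_W = |Gamma|^-1 / (|Gamma|^-2 + SNR^-1)`, evaluated per zone and
#' frequency bin with the limit conventions `SNR -> Inf => Gamma_W = |Gamma|`
#' (high-SNR bins pass unchanged), `SNR = 0 => Gamma_W = 0` and
#' `|Gamma| = 0 => Gamma_W = 0` (low-SNR bins are denoised to zero gain
#' rather than amplified).
#'
#' @param tf An `m2m_tf` from [estimate_transfer_magnitude()].
#' @param snr An `snr_profile` from [estimate_snr_profile()].
#' @return The `m2m_tf` with `gamma_wiener` filled in.
#' @export
wiener_regularize <- function(tf, snr) {
  stopifnot(inherits(tf, "m2m_tf"), inherits(snr, "snr_profile"))
  if (!identical(dim(tf$gamma_raw), dim(snr$snr)))
    stop("transfer function and SNR profile shapes differ")
  if (any(snr$snr < 0)) stop("negative SNR values")
  tf$gamma_wiener <- wiener_gain(tf$gamma_raw, snr$snr)
  tf
}

# Gamma_W = g * snr / (snr + g^2) with the documented limit conventions.
wiener_gain <- function(g, snr) {
  out <- g * snr / (snr + g^2)
  out[snr == 0 | g == 0] <- 0
  out[is.infinite(snr)] <- g[is.infinite(snr)]
  out[!is.finite(out)] <- 0
  out
}

#' Apply a transfer function to RF patches
#'
#' Filters each patch with the gain matched to its axial zone: per column,
#' forward real FFT, multiplication of the complex spectrum by the real
#' regularized gain (zero-phase), inverse FFT.  Filtering with a gain of one
#' everywhere is the identity to numerical precision.  Labels and zones are
#' preserved.
#'
#' @param patches A `patch_set` whose patch height equals the transfer
#'   function's FFT length.
#' @param tf An `m2m_tf` with `gamma_wiener` present (see
#'   [wiener_regularize()]), or an [m2m_transfer()] fit together with
#'   `direction`.
#' @param direction Direction to apply when `tf` is an `m2m_calibration`.
#' @return The filtered `patch_set`.
#' @export
apply_transfer <- function(patches, tf,
                           direction = c("train_to_test", "test_to_train")) {
  if (inherits(tf, "m2m_calibration")) {
    direction <- match.arg(direction)
    tf <- if (direction == "train_to_test") tf$forward else tf$backward
  }
  stopifnot(inherits(patches, "patch_set"), inherits(tf, "m2m_tf"))
  if (is.null(tf$gamma_wiener))
    stop("transfer function has not been regularized; run wiener_regularize() first")
  pa <- dim(patches$data)[1L]
  nb <- pa %/% 2L + 1L
  if (ncol(tf$gamma_wiener) != nb)
    stop("patch axial length does not match the transfer function grid")
  bad <- setdiff(unique(patches$info$zone), seq_len(tf$n_zones) - 1L)
  if (length(bad))
    stop("patch zones outside transfer function range: ", paste(bad, collapse = ", "))
  for (z in unique(patches$info$zone)) {
    gain <- tf$gamma_wiener[z + 1L, ]
    # full-length symmetric gain for a real zero-phase filter (pa even)
    gfull <- c(gain, gain[seq(nb - 1L, 2L)])
    idx <- which(patches$info$zone == z)
    x <- patches$data[, , idx, drop = FALSE]
    d3 <- dim(x)[3L]
    dim(x) <- c(pa, length(x) / pa)
    y <- Re(stats::mvfft(stats::mvfft(x) * gfull, inverse = TRUE)) / pa
    dim(y) <- c(pa, dim(patches$data)[2L], d3)
    patches$data[, , idx] <- y
  }
  patches
}

#' Estimate both transfer directions with one shared SNR profile
#'
#' @inheritParams estimate_transfer_magnitude
#' @return List with `forward` (train-to-test `m2m_tf`), `backward`
#'   (test-to-train, the exact reciprocal of the raw forward magnitude), and
#'   the shared `snr_profile`; both directions are independently
#'   Wiener-regularized.
#' @export
build_bidirectional <- function(spec_train, spec_test) {
  snr <- estimate_snr_profile(spec_train, spec_test)
  fwd <- estimate_transfer_magnitude(spec_train, spec_test, "train_to_test")
  bwd <- fwd
  bwd$gamma_raw <- guarded_reciprocal(fwd$gamma_raw)
  bwd$direction <- "test_to_train"
  list(forward = wiener_regularize(fwd, snr),
       backward = wiener_regularize(bwd, snr),
       snr = snr)
}
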