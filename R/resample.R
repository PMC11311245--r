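#' Rational sampling-rate conversion of RF frames
#'
#' Converts the axial sampling rate of a frame by the rational factor
#' `up/down` (e.g. `up = 4, down = 5` converts 50 MHz acquisitions to the
#' 40 MHz grid shared by both machine domains).  The converter is a polyphase
#' anti-aliasing FIR: the signal is zero-stuffed by `up`, filtered with a
#' Kaiser-windowed sinc low-pass (cutoff `min(pi/up, pi/down)` at the
#' intermediate rate, `24 * max(up, down) + 1` taps, beta = 5, polyphase
#' branches normalized to unit DC gain), group-delay compensated so output
#' sample 1 aligns with input sample 1, and decimated by `down`.  The lateral
#' dimension is untouched.
#'
#' @param frame An [rf_frame()].
#' @param up,down Coprime positive integers: interpolation and decimation
#'   factors.
#' @return An [rf_frame()] with `ceiling(n_axial * up / down)` axial samples
#'   and `sampling_rate * up / down`.
#' @examples
#' f <- rf_frame(matrix(rnorm(2600 * 4), 2600, 4), "B", "calib", 50e6, "stable", 0)
#' g <- resample_frame(f, 4, 5)
#' nrow(g$samples)          # 2080
#' g$meta$sampling_rate     # 40e6
#' @export
resample_frame <- function(frame, up, down) {
  stopifnot(inherits(frame, "rf_frame"))
  up <- as.integer(up); down <- as.integer(down)
  if (is.na(up) || is.na(down) || up <= 0L || down <= 0L)
    stop("`up` and `down` must be positive integers")
  if (gcd_int(up, down) != 1L)
    stop("`up` and `down` must be coprime")
  x <- frame$samples
  n <- nrow(x)
  if (up == 1L && down == 1L) return(frame)

  h <- resample_kernel(up, down)
  n_out <- as.integer(ceiling(n * up / down))
  y <- polyphase_resample(x, h, up, down, n_out)

  out <- frame
  out$samples <- y
  out$meta$sampling_rate <- frame$meta$sampling_rate * up / down
  out
}

#' @rdname resample_frame
#' @param ds An [rf_dataset()].
#' @export
resample_dataset <- function(ds, up, down) {
  stopifnot(inherits(ds, "rf_dataset"))
  ds$frames <- lapply(ds$frames, resample_frame, up = up, down = down)
  ds
}

gcd_int <- function(a, b) if (b == 0L) a else gcd_int(b, a %% b)

# Kaiser window via the modified Bessel function of order zero.
kaiser_window <- function(n, beta) {
  m <- (n - 1) / 2
  k <- seq_len(n) - 1
  besselI(beta * sqrt(pmax(0, 1 - ((k - m) / m)^2)), 0) / besselI(beta, 0)
}

# Windowed-sinc anti-alias low-pass for a rational up/down converter.
# Cutoff min(pi/up, pi/down) at the upsampled rate; each polyphase branch is
# normalized to unit sum so a constant input passes through exactly.
resample_kernel <- function(up, down, taps = 24L * max(up, down) + 1L, beta = 5) {
  m <- (taps - 1) / 2
  k <- seq_len(taps) - 1 - m
  fc <- 1 / (2 * max(up, down))       # cycles/sample at intermediate rate
  h <- 2 * fc * sinc(2 * fc * k) * kaiser_window(taps, beta)
  # unit DC gain per polyphase branch
  phase <- ((seq_len(taps) - 1L) %% up)
  for (p in unique(phase)) {
    s <- sum(h[phase == p])
    if (abs(s) > .Machine$double.eps) h[phase == p] <- h[phase == p] / s
  }
  h
}

sinc <- function(x) ifelse(x == 0, 1, sin(pi * x) / (pi * x))

#' Uniform requantization of a frame
#'
#' Re-digitizes the samples to `2^bits` uniform levels spanning the frame's
#' min-max range, emulating acquisition bit depth.  The maximum quantization
#' error is half of one step.
#'
#' @param frame An [rf_frame()].
#' @param bits Integer in `[2, 32]`.
#' @return An [rf_frame()] with quantized samples and updated
#'   `meta$bit_depth`.
#' @export
quantize_frame <- function(frame, bits) {
  stopifnot(inherits(frame, "rf_frame"))
  bits <- as.integer(bits)
  if (is.na(bits) || bits < 2L || bits > 32L)
    stop("`bits` must be an integer in [2, 32]")
  x <- frame$samples
  lo <- min(x); hi <- max(x)
  if (hi > lo) {
    step <- (hi - lo) / (2^bits - 1)
    x <- lo + round((x - lo) / step) * step
  }
  out <- frame
  out$samples <- x
  out$meta$bit_depth <- bits
  out
}
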