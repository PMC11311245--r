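#' RF frame and dataset containers
#'
#' An `rf_frame` is one post-beamformed radio-frequency (RF) image: a numeric
#' matrix of `n_axial x n_lateral` samples (axial index 1 at the transducer
#' face, stored column-major with the axial dimension fastest) together with
#' its acquisition metadata.  An `rf_dataset` is an ordered collection of
#' frames sharing a sampling rate, the unit the rest of the pipeline operates
#' on.
#'
#' @param samples Numeric matrix, axial samples in rows, scan lines in
#'   columns.  All values must be finite.
#' @param machine_id,phantom_id Character scalars identifying the scanner and
#'   the imaged phantom.
#' @param sampling_rate Axial sampling rate in Hz (> 0).
#' @param acquisition_mode `"stable"` (clamped transducer, shared speckle
#'   realization across machines) or `"freehand"` (independent realizations).
#' @param frame_index Non-negative integer, unique within
#'   `(machine_id, phantom_id, acquisition_mode)`.
#' @param class_label Integer 0/1 for classification phantoms, or `NA` for
#'   calibration phantoms (which carry no class).
#' @param transducer_id Optional character scalar.
#' @param bit_depth Digitization depth in bits (default 16).
#'
#' @return `rf_frame()` returns an object of class `rf_frame`: a list with
#'   elements `samples` (the matrix) and `meta` (a named list).
#' @examples
#' f <- rf_frame(matrix(rnorm(64), 16, 4), machine_id = "A", phantom_id = "calib",
#'               sampling_rate = 40e6, acquisition_mode = "stable", frame_index = 0)
#' dim(f$samples)
#' @export
rf_frame <- function(samples, machine_id, phantom_id, sampling_rate,
                     acquisition_mode = c("freehand", "stable"),
                     frame_index = 0L, class_label = NA_integer_,
                     transducer_id = NA_character_, bit_depth = 16L) {
  if (!is.matrix(samples) || !is.numeric(samples))
    stop("`samples` must be a numeric matrix (axial x lateral)")
  if (!all(is.finite(samples)))
    stop("`samples` contains non-finite values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L || sampling_rate <= 0)
    stop("`sampling_rate` must be a positive scalar (Hz)")
  acquisition_mode <- match.arg(acquisition_mode)
  if (frame_index < 0) stop("`frame_index` must be >= 0")
  if (!is.na(class_label) && !(class_label %in% c(0L, 1L)))
    stop("`class_label` must be 0, 1 or NA")
  storage.mode(samples) <- "double"
  structure(list(
    samples = samples,
    meta = list(
      machine_id = as.character(machine_id),
      transducer_id = as.character(transducer_id),
      phantom_id = as.character(phantom_id),
      class_label = as.integer(class_label),
      sampling_rate = as.double(sampling_rate),
      acquisition_mode = acquisition_mode,
      frame_index = as.integer(frame_index),
      bit_depth = as.integer(bit_depth)
    )
  ), class = "rf_frame")
}

#' @rdname rf_frame
#' @param frames List of `rf_frame` objects (all with the same sampling rate).
#' @param provenance Free-text provenance string.
#' @param format_version Container format version string.
#' @export
rf_dataset <- function(frames = list(), provenance = "", format_version = "1.0") {
  if (!all(vapply(frames, inherits, logical(1), "rf_frame")))
    stop("all elements of `frames` must be rf_frame objects")
  if (length(frames) > 1L) {
    fs <- vapply(frames, function(f) f$meta$sampling_rate, numeric(1))
    if (length(unique(fs)) != 1L)
      stop("all frames in a dataset must share one sampling_rate")
  }
  structure(list(frames = frames,
                 provenance = as.character(provenance),
                 format_version = as.character(format_version)),
            class = "rf_dataset")
}

#' @export
print.rf_frame <- function(x, ...) {
  cat(sprintf("<rf_frame> %d x %d samples, machine %s, phantom %s, %.1f MHz, %s, frame %d\n",
              nrow(x$samples), ncol(x$samples), x$meta$machine_id, x$meta$phantom_id,
              x$meta$sampling_rate / 1e6, x$meta$acquisition_mode, x$meta$frame_index))
  invisible(x)
}

#' @export
print.rf_dataset <- function(x, ...) {
  cat(sprintf("<rf_dataset> %d frames", length(x$frames)))
  if (length(x$frames)) {
    f <- x$frames[[1L]]
    cat(sprintf(", %d x %d, %.1f MHz", nrow(f$samples), ncol(f$samples),
                f$meta$sampling_rate / 1e6))
  }
  cat("\n")
  invisible(x)
}

#' @export
length.rf_dataset <- function(x) length(x$frames)

# Sampling rate shared by the frames of a dataset.
dataset_rate <- function(ds) {
  if (!length(ds$frames)) stop("empty dataset has no sampling rate")
  ds$frames[[1L]]$meta$sampling_rate
}
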