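#' Read and write RF dataset containers
#'
#' RF datasets are stored in a single self-contained `.rfh5` container with a
#' hierarchical per-frame layout: one record per frame holding the 2-D sample
#' array plus its metadata attributes.  The byte layout is an 8-byte magic
#' string, an 8-byte little-endian header length, a UTF-8 JSON header (format
#' version, provenance, one metadata entry per frame with its payload offset),
#' and a payload of little-endian IEEE-754 float64 sample arrays stored
#' column-major (axial fastest).  The layout is deterministic for a fixed
#' dataset and format version, and round-trips are bit-exact.
#'
#' @param path File path.
#' @param ds An [rf_dataset()].
#' @return `read_rfh5()` returns an [rf_dataset()]; `write_rfh5()` returns
#'   `path` invisibly.
#' @examples
#' f <- rf_frame(matrix(rnorm(40), 10, 4), "A", "calib", 40e6, "stable", 0)
#' p <- tempfile(fileext = ".rfh5")
#' write_rfh5(rf_dataset(list(f)), p)
#' ds <- read_rfh5(p)
#' identical(ds$frames[[1]]$samples, f$samples)
#' @export
write_rfh5 <- function(ds, path) {
  stopifnot(inherits(ds, "rf_dataset"))
  for (f in ds$frames) {
    if (!all(is.finite(f$samples)))
      stop("frame ", f$meta$frame_index, " contains non-finite samples; refusing to write")
  }
  metas <- lapply(seq_along(ds$frames), function(i) {
    f <- ds$frames[[i]]
    m <- f$meta
    list(machine_id = m$machine_id,
         transducer_id = m$transducer_id,
         phantom_id = m$phantom_id,
         class_label = if (is.na(m$class_label)) NULL else m$class_label,
         sampling_rate = m$sampling_rate,
         acquisition_mode = m$acquisition_mode,
         frame_index = m$frame_index,
         bit_depth = m$bit_depth,
         n_axial = nrow(f$samples),
         n_lateral = ncol(f$samples))
  })
  header <- jsonlite::toJSON(list(format_version = ds$format_version,
                                  provenance = ds$provenance,
                                  n_frames = length(ds$frames),
                                  frames = metas),
                             auto_unbox = TRUE, digits = NA, null = "null",
                             na = "null")
  hraw <- charToRaw(as.character(header))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw("RFH5CONT"), con)
  writeBin(as.double(length(hraw)), con, size = 8, endian = "little")
  writeBin(hraw, con)
  for (f in ds$frames)
    writeBin(as.vector(f$samples), con, size = 8, endian = "little")
  invisible(path)
}

#' @rdname write_rfh5
#' @export
read_rfh5 <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 8L))
  if (!identical(magic, "RFH5CONT"))
    stop("not an .rfh5 container (bad magic): ", path)
  hlen <- readBin(con, "double", 1L, size = 8, endian = "little")
  if (!length(hlen) || !is.finite(hlen) || hlen <= 0)
    stop("corrupt container: missing header")
  header <- jsonlite::fromJSON(rawToChar(readBin(con, "raw", as.integer(hlen))),
                               simplifyVector = FALSE)
  for (field in c("format_version", "n_frames", "frames"))
    if (is.null(header[[field]])) stop("corrupt container: missing field '", field, "'")
  frames <- vector("list", header$n_frames)
  for (i in seq_len(header$n_frames)) {
    m <- header$frames[[i]]
    for (field in c("machine_id", "phantom_id", "sampling_rate",
                    "acquisition_mode", "frame_index", "n_axial", "n_lateral"))
      if (is.null(m[[field]])) stop("corrupt container: frame ", i,
                                    " missing field '", field, "'")
    vals <- readBin(con, "double", m$n_axial * m$n_lateral, size = 8,
                    endian = "little")
    if (length(vals) != m$n_axial * m$n_lateral)
      stop("corrupt container: truncated payload at frame ", i)
    frames[[i]] <- rf_frame(matrix(vals, m$n_axial, m$n_lateral),
                            machine_id = m$machine_id,
                            phantom_id = m$phantom_id,
                            sampling_rate = m$sampling_rate,
                            acquisition_mode = m$acquisition_mode,
                            frame_index = m$frame_index,
                            class_label = if (is.null(m$class_label)) NA_integer_ else m$class_label,
                            transducer_id = if (is.null(m$transducer_id)) NA_character_ else m$transducer_id,
                            bit_depth = if (is.null(m$bit_depth)) 16L else m$bit_depth)
  }
  rf_dataset(frames,
             provenance = if (is.null(header$provenance)) "" else header$provenance,
             format_version = header$format_version)
}
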