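#' Depth-stratified patch-extraction grid
#'
#' The classification unit is a `patch_axial x patch_lateral` RF sub-array.
#' Patches tile each frame on a fixed grid: the first `axial_skip` samples
#' (the near field) are omitted, successive axial positions advance by
#' `axial_step` samples (so consecutive depth zones overlap when
#' `axial_step < patch_axial`), and lateral positions advance by
#' `lateral_step` scan lines starting at line 1.  With the defaults a
#' 2080 x 256 frame yields 9 x 9 = 81 patches of 200 x 26 samples, and each
#' patch carries its axial-zone identity 0-8 (0 = shallowest).
#'
#' @param axial_skip Axial samples omitted at the top of the frame.
#' @param patch_axial,patch_lateral Patch height (samples) and width (lines).
#' @param axial_step,lateral_step Grid strides.
#' @param n_axial_positions,n_lateral_positions Grid size.
#' @return An object of class `patch_grid`.
#' @export
patch_grid <- function(axial_skip = 540L, patch_axial = 200L, patch_lateral = 26L,
                       axial_step = 100L, lateral_step = 26L,
                       n_axial_positions = 9L, n_lateral_positions = 9L) {
  g <- lapply(list(axial_skip = axial_skip, patch_axial = patch_axial,
                   patch_lateral = patch_lateral, axial_step = axial_step,
                   lateral_step = lateral_step,
                   n_axial_positions = n_axial_positions,
                   n_lateral_positions = n_lateral_positions), as.integer)
  if (any(vapply(g, function(v) is.na(v) || v <= 0L, logical(1))))
    stop("all patch_grid fields must be positive integers")
  structure(g, class = "patch_grid")
}

grid_required_axial <- function(g) g$axial_skip + (g$n_axial_positions - 1L) * g$axial_step + g$patch_axial
grid_required_lateral <- function(g) (g$n_lateral_positions - 1L) * g$lateral_step + g$patch_lateral

#' Extract depth-stratified patches from frames
#'
#' Patch `(i, j)` (0-based grid positions) covers axial rows
#' `axial_skip + i * axial_step + (1 : patch_axial)` and lateral columns
#' `j * lateral_step + (1 : patch_lateral)`; its axial zone is `i` and its
#' class label is copied from the frame metadata.
#'
#' @param x An [rf_frame()] or [rf_dataset()].
#' @param grid A [patch_grid()].
#' @return A `patch_set`: list with `data` (array
#'   `patch_axial x patch_lateral x n`), `info` (data frame with columns
#'   `zone`, `class_label`, `machine_id`, `phantom_id`, `frame_index`,
#'   `lateral_pos`), the `grid`, and `sampling_rate`.
#' @examples
#' f <- rf_frame(matrix(rnorm(2080 * 256), 2080, 256), "A", "c1", 40e6,
#'               "freehand", 0, class_label = 1L)
#' p <- extract_patches(f, patch_grid())
#' n_patches(p)  # 81
#' @export
extract_patches <- function(x, grid = patch_grid()) {
  stopifnot(inherits(grid, "patch_grid"))
  frames <- if (inherits(x, "rf_frame")) list(x)
            else if (inherits(x, "rf_dataset")) x$frames
            else stop("`x` must be an rf_frame or rf_dataset")
  if (!length(frames)) stop("no frames to extract from")
  pa <- grid$patch_axial; pl <- grid$patch_lateral
  na <- grid$n_axial_positions; nl <- grid$n_lateral_positions
  per_frame <- na * nl
  n <- length(frames) * per_frame
  data <- array(0, c(pa, pl, n))
  zone <- integer(n); lateral <- integer(n); label <- integer(n)
  machine <- character(n); phantom <- character(n); findex <- integer(n)
  k <- 0L
  for (f in frames) {
    req_a <- grid_required_axial(grid); req_l <- grid_required_lateral(grid)
    if (nrow(f$samples) < req_a || ncol(f$samples) < req_l)
      stop(sprintf("frame %d x %d too small for grid needing %d x %d",
                   nrow(f$samples), ncol(f$samples), req_a, req_l))
    for (j in seq_len(nl) - 1L) {
      cols <- j * grid$lateral_step + seq_len(pl)
      for (i in seq_len(na) - 1L) {
        rows <- grid$axial_skip + i * grid$axial_step + seq_len(pa)
        k <- k + 1L
        data[, , k] <- f$samples[rows, cols]
        zone[k] <- i; lateral[k] <- j
        label[k] <- f$meta$class_label
        machine[k] <- f$meta$machine_id
        phantom[k] <- f$meta$phantom_id
        findex[k] <- f$meta$frame_index
      }
    }
  }
  structure(list(
    data = data,
    info = data.frame(zone = zone, class_label = label, machine_id = machine,
                      phantom_id = phantom, frame_index = findex,
                      lateral_pos = lateral, stringsAsFactors = FALSE),
    grid = grid,
    sampling_rate = frames[[1L]]$meta$sampling_rate
  ), class = "patch_set")
}

#' @rdname extract_patches
#' @param p A `patch_set`.
#' @export
n_patches <- function(p) dim(p$data)[3L]

#' @export
print.patch_set <- function(x, ...) {
  cat(sprintf("<patch_set> %d patches of %d x %d, zones %d-%d",
              n_patches(x), dim(x$data)[1L], dim(x$data)[2L],
              min(x$info$zone), max(x$info$zone)))
  if (!all(is.na(x$info$class_label)))
    cat(sprintf(", classes {%s}", paste(sort(unique(x$info$class_label)), collapse = ",")))
  cat("\n")
  invisible(x)
}

# Select a subset of patches by index, keeping metadata aligned.
subset_patches <- function(p, idx) {
  p$data <- p$data[, , idx, drop = FALSE]
  p$info <- p$info[idx, , drop = FALSE]
  rownames(p$info) <- NULL
  p
}

# Concatenate patch sets with identical geometry.
rbind_patches <- function(...) {
  ps <- list(...)
  out <- ps[[1L]]
  out$data <- array(unlist(lapply(ps, function(p) p$data), use.names = FALSE),
                    c(dim(out$data)[1:2], sum(vapply(ps, n_patches, integer(1)))))
  out$info <- do.call(rbind, lapply(ps, function(p) p$info))
  rownames(out$info) <- NULL
  out
}

#' Patch-level z-score normalization statistics
#'
#' Computes the elementwise mean patch and standard-deviation patch
#' (population convention, divide by N) over a patch collection.  Standard
#' deviations are floored at `1e-12` times the mean absolute amplitude of the
#' collection so that degenerate elements cannot blow up the division.
#'
#' @param patches A `patch_set` with at least 2 patches.
#' @param source_tag Which domain the statistics describe: `"train"`,
#'   `"calibrated"` (train-to-test transformed) or `"test"`.
#' @return An object of class `zscore_stats` with `mean_patch`, `std_patch`,
#'   `n_source_patches`, `source_tag`.
#' @export
compute_zscore_stats <- function(patches, source_tag = c("train", "calibrated", "test")) {
  stopifnot(inherits(patches, "patch_set"))
  source_tag <- match.arg(source_tag)
  n <- n_patches(patches)
  if (n < 2L) stop("need at least 2 patches to compute statistics")
  m <- rowMeans(patches$data, dims = 2L)
  v <- rowMeans(patches$data^2, dims = 2L) - m^2
  eps <- 1e-12 * mean(abs(patches$data))
  if (eps == 0) eps <- 1e-12
  s <- pmax(sqrt(pmax(v, 0)), eps)
  structure(list(mean_patch = m, std_patch = s, n_source_patches = n,
                 source_tag = source_tag), class = "zscore_stats")
}

#' @rdname compute_zscore_stats
#' @param stats A `zscore_stats` object.
#' @return `apply_zscore()` returns the normalized `patch_set` (labels and
#'   zones untouched).
#' @export
apply_zscore <- function(patches, stats) {
  stopifnot(inherits(patches, "patch_set"), inherits(stats, "zscore_stats"))
  if (!identical(dim(patches$data)[1:2], dim(stats$mean_patch)))
    stop("patch shape does not match normalization statistics")
  patches$data <- (patches$data - as.vector(stats$mean_patch)) /
    as.vector(stats$std_patch)
  patches
}

#' Stratified train/validation split
#'
#' Uniform random partition at `ratio` (train : validation), stratified by
#' `(class_label, axial_zone)` so both sets represent every class-depth cell
#' whenever the cell counts allow.  Reproducible under `seed`.
#'
#' @param patches A `patch_set` (>= 5 patches).
#' @param ratio Train fraction as `c(train, val)` parts; default `c(4, 1)`.
#' @param seed Integer seed.
#' @return List with elements `train` and `val`, both `patch_set`s.
#' @export
split_train_val <- function(patches, ratio = c(4, 1), seed = 1L) {
  stopifnot(inherits(patches, "patch_set"))
  tr_idx <- split_indices(patches$info, ratio, seed)
  list(train = subset_patches(patches, tr_idx),
       val = subset_patches(patches, setdiff(seq_len(n_patches(patches)), tr_idx)))
}

# Stratified split as sorted training indices (shared by split_train_val and
# the training loop, which subsets batches without copying the full set).
split_indices <- function(info, ratio = c(4, 1), seed = 1L) {
  n <- nrow(info)
  if (n < 5L) stop("need at least 5 patches to split")
  p_train <- ratio[1L] / sum(ratio)
  cell <- interaction(addNA(factor(info$class_label)),
                      factor(info$zone), drop = TRUE)
  tr_idx <- with_seed(seed, {
    unlist(lapply(split(seq_len(n), cell), function(ix) {
      m <- length(ix)
      k <- round(m * p_train)
      if (m >= 2L) k <- min(max(k, 1L), m - 1L)
      sample(ix, k)
    }), use.names = FALSE)
  })
  sort(tr_idx)
}
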