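#' Boolean mask on a voxel grid
#'
#' @param grid a [volume_grid()].
#' @param member logical (or 0/1) array with dim equal to `grid$shape`, or a
#'   vector of that length.
#' @return A `brain_mask` with elements `grid` and `member` (logical array).
#' @seealso [mask_from_indices()] to build a mask from linear voxel indices.
#' @export
brain_mask <- function(grid, member) {
  member <- as.logical(member)
  if (length(member) != n_voxels(grid)) {
    stop("'member' length does not match grid")
  }
  member[is.na(member)] <- FALSE
  dim(member) <- grid$shape
  structure(list(grid = grid, member = member), class = "brain_mask")
}

#' @export
print.brain_mask <- function(x, ...) {
  cat("brain_mask on", format(x$grid), "-", sum(x$member), "voxels\n")
  invisible(x)
}

#' Build a mask from 1-based linear voxel indices
#'
#' @param grid a [volume_grid()].
#' @param idx integer vector of linear voxel indices (may be empty).
#' @return A `brain_mask`.
#' @export
mask_from_indices <- function(grid, idx) {
  idx <- as.integer(idx)
  if (length(idx) && (min(idx) < 1L || max(idx) > n_voxels(grid))) {
    stop("linear indices out of range")
  }
  m <- logical(n_voxels(grid))
  m[idx] <- TRUE
  brain_mask(grid, m)
}

mask_indices <- function(mask) which(mask$member)

mask_size <- function(mask) sum(mask$member)

#' Mask set algebra
#'
#' Union, intersection and difference of masks on a shared grid.
#' @param a,b `brain_mask` objects on the same grid.
#' @return A `brain_mask`.
#' @export
mask_union <- function(a, b) {
  stopifnot_same_grid(a$grid, b$grid)
  brain_mask(a$grid, a$member | b$member)
}

#' @rdname mask_union
#' @export
mask_intersect <- function(a, b) {
  stopifnot_same_grid(a$grid, b$grid)
  brain_mask(a$grid, a$member & b$member)
}

#' @rdname mask_union
#' @export
mask_difference <- function(a, b) {
  stopifnot_same_grid(a$grid, b$grid)
  brain_mask(a$grid, a$member & !b$member)
}

#' Per-voxel scalar values on a grid
#'
#' Holds float values (functional connectivity, sulcal depth,
#' distance-to-scalp, E-field magnitude...) together with a validity mask.
#' Voxels outside `valid` are undefined, not zero: their stored value is `NA`.
#'
#' @param grid a [volume_grid()].
#' @param value numeric array (dim = `grid$shape`) or vector of matching length.
#' @param valid optional `brain_mask` of defined voxels; defaults to the
#'   finite entries of `value`.
#' @return A `scalar_map`.
#' @export
scalar_map <- function(grid, value, valid = NULL) {
  value <- as.numeric(value)
  if (length(value) != n_voxels(grid)) stop("'value' length does not match grid")
  dim(value) <- grid$shape
  if (is.null(valid)) {
    valid <- brain_mask(grid, is.finite(value))
  } else {
    stopifnot_same_grid(grid, valid$grid)
  }
  value[!valid$member] <- NA_real_
  structure(list(grid = grid, value = value, valid = valid),
            class = "scalar_map")
}

#' @export
print.scalar_map <- function(x, ...) {
  v <- x$value[x$valid$member]
  cat("scalar_map on", format(x$grid), "-", length(v), "valid voxels",
      if (length(v)) sprintf("[%.3g, %.3g]", min(v), max(v)) else "", "\n")
  invisible(x)
}

#' Integer label volume (0 = background)
#'
#' @param grid a [volume_grid()].
#' @param label integer array (dim = `grid$shape`) or vector of matching
#'   length; non-negative, 0 meaning background. Float input is accepted only
#'   if exactly integer-valued.
#' @return A `label_map`.
#' @export
label_map <- function(grid, label) {
  if (is.double(label) && any(label != round(label), na.rm = TRUE)) {
    stop("label volume contains non-integer values")
  }
  label <- as.integer(label)
  if (length(label) != n_voxels(grid)) stop("'label' length does not match grid")
  label[is.na(label)] <- 0L
  if (any(label < 0L)) stop("labels must be non-negative")
  dim(label) <- grid$shape
  structure(list(grid = grid, label = label), class = "label_map")
}

#' @export
print.label_map <- function(x, ...) {
  labs <- setdiff(sort(unique(as.vector(x$label))), 0L)
  cat("label_map on", format(x$grid), "-", length(labs), "labels\n")
  invisible(x)
}

#' 4D resting-state time-series volume
#'
#' Frames are stored as a T x n_voxels matrix (`series`), column j holding the
#' time course of the voxel with linear index j. Voxels outside `valid` or
#' with zero temporal variance are flagged.
#'
#' @param grid a [volume_grid()].
#' @param series either a 4D array with dim `c(grid$shape, T)` or a T x
#'   n_voxels matrix.
#' @param valid optional `brain_mask` of voxels carrying signal.
#' @return A `timeseries_volume` with `grid`, `series`, `n_frames`, `valid`.
#' @export
timeseries_volume <- function(grid, series, valid = NULL) {
  if (length(dim(series)) == 4L) {
    d <- dim(series)
    if (!all(d[1:3] == grid$shape)) stop("4D array does not match grid shape")
    series <- t(matrix(series, nrow = prod(d[1:3]), ncol = d[4]))
  }
  series <- as.matrix(series)
  if (ncol(series) != n_voxels(grid)) stop("'series' columns do not match grid")
  if (nrow(series) < 3L) stop("at least 3 frames are required for correlation")
  if (is.null(valid)) {
    valid <- brain_mask(grid, colSums(!is.finite(series)) == 0L)
  } else {
    stopifnot_same_grid(grid, valid$grid)
  }
  structure(list(grid = grid, series = series, n_frames = nrow(series),
                 valid = valid),
            class = "timeseries_volume")
}

#' @export
print.timeseries_volume <- function(x, ...) {
  cat("timeseries_volume on", format(x$grid), "-", x$n_frames, "frames,",
      mask_size(x$valid), "valid voxels\n")
  invisible(x)
}
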