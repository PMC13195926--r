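#' Voxel grid with a world-coordinate affine
#'
#' A `volume_grid` ties a 3D voxel lattice to world coordinates in
#' millimetres through a 4x4 affine, exactly as a NIfTI header does.
#' Every map, mask and target in this package lives on such a grid, and
#' operations refuse to mix objects from different grids.
#'
#' Voxel indices are 1-based (R convention); the affine follows the NIfTI
#' convention of mapping 0-based indices to world mm, so
#' `world = affine %*% c(i - 1, j - 1, k - 1, 1)`. Grids are typically
#' RAS-oriented but any invertible affine is accepted.
#'
#' @param shape integer vector of length 3, voxels per axis.
#' @param affine 4x4 numeric matrix mapping 0-based voxel indices to world
#'   millimetres. Defaults to identity (1 mm isotropic voxels at the origin).
#' @return An object of class `volume_grid` with elements `shape`, `affine`
#'   and derived `voxel_size` (mm per axis).
#' @examples
#' g <- volume_grid(c(10, 10, 10), diag(c(2, 2, 2, 1)))
#' g$voxel_size
#' @export
volume_grid <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  if (length(shape) != 3L || any(shape < 1L)) {
    stop("'shape' must be 3 positive integers")
  }
  affine <- as.matrix(affine)
  if (!all(dim(affine) == c(4L, 4L))) stop("'affine' must be a 4x4 matrix")
  det_a <- det(affine)
  if (!is.finite(det_a) || abs(det_a) < .Machine$double.eps * 100) {
    stop("'affine' must be invertible")
  }
  voxel_size <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(voxel_size <= 0)) stop("voxel sizes must be strictly positive")
  structure(
    list(shape = shape, affine = affine, voxel_size = voxel_size,
         inv_affine = solve(affine)),
    class = "volume_grid"
  )
}

#' @export
print.volume_grid <- function(x, ...) {
  cat("volume_grid:", paste(x$shape, collapse = " x "),
      "voxels;", paste(signif(x$voxel_size, 4), collapse = " x "), "mm\n")
  invisible(x)
}

#' @export
format.volume_grid <- function(x, ...) {
  paste0(paste(x$shape, collapse = "x"), " @ ",
         paste(signif(x$voxel_size, 3), collapse = "x"), "mm")
}

same_grid <- function(a, b, tol = 1e-6) {
  identical(a$shape, b$shape) && max(abs(a$affine - b$affine)) <= tol
}

stopifnot_same_grid <- function(a, b) {
  if (!same_grid(a, b)) {
    stop("objects live on different grids (",
         format(a), " vs ", format(b), ")")
  }
}

n_voxels <- function(grid) prod(grid$shape)

#' Convert voxel indices to world millimetres
#'
#' @param grid a [volume_grid()].
#' @param voxel n x 3 matrix (or length-3 vector) of 1-based voxel indices;
#'   fractional indices are allowed (e.g. centroids).
#' @return n x 3 matrix of world coordinates in mm.
#' @export
voxel_to_world <- function(grid, voxel) {
  v <- rbind3(voxel)
  h <- cbind(v - 1, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' Convert world millimetres to (fractional) voxel indices
#'
#' @inheritParams voxel_to_world
#' @param world n x 3 matrix (or length-3 vector) of world coordinates, mm.
#' @return n x 3 matrix of 1-based fractional voxel indices.
#' @export
world_to_voxel <- function(grid, world) {
  w <- rbind3(world)
  h <- cbind(w, 1) %*% t(grid$inv_affine)
  h[, 1:3, drop = FALSE] + 1
}

rbind3 <- function(x) {
  if (is.null(dim(x))) matrix(as.numeric(x), nrow = 1L) else {
    storage.mode(x) <- "double"
    x
  }
}

## linear index <-> (i,j,k) subscripts, both 1-based
lin_to_sub <- function(grid, lin) {
  arrayInd(as.integer(lin), .dim = grid$shape)
}

sub_to_lin <- function(grid, sub) {
  sub <- rbind3(sub)
  s <- grid$shape
  as.integer((sub[, 3] - 1) * s[1] * s[2] + (sub[, 2] - 1) * s[1] + sub[, 1])
}

## world coordinates of voxel centers given linear indices
lin_to_world <- function(grid, lin) {
  voxel_to_world(grid, lin_to_sub(grid, lin))
}

in_bounds <- function(grid, sub) {
  sub <- rbind3(sub)
  sub[, 1] >= 1 & sub[, 1] <= grid$shape[1] &
    sub[, 2] >= 1 & sub[, 2] <= grid$shape[2] &
    sub[, 3] >= 1 & sub[, 3] <= grid$shape[3]
}

#' Stimulation-target point
#'
#' A `target_point` records a location in world mm together with the nearest
#' voxel index on its grid and free-form provenance metadata (algorithm,
#' session, threshold settings).
#'
#' @param grid a [volume_grid()].
#' @param world_mm length-3 numeric, world coordinates in mm.
#' @param meta named list of provenance fields.
#' @return A `target_point` with `world_mm`, `voxel_index` (1-based, nearest
#'   voxel) and `meta`.
#' @export
target_point <- function(grid, world_mm, meta = list()) {
  world_mm <- as.numeric(world_mm)
  if (length(world_mm) != 3L || !all(is.finite(world_mm))) {
    stop("'world_mm' must be 3 finite numbers")
  }
  vox <- round(world_to_voxel(grid, world_mm)[1, ])
  vox <- pmin(pmax(vox, 1), grid$shape)  # clamp to grid
  structure(
    list(world_mm = world_mm, voxel_index = as.integer(vox),
         grid = grid, meta = meta),
    class = "target_point"
  )
}

#' @export
print.target_point <- function(x, ...) {
  cat(sprintf("target_point (%.2f, %.2f, %.2f) mm [voxel %d %d %d]%s\n",
              x$world_mm[1], x$world_mm[2], x$world_mm[3],
              x$voxel_index[1], x$voxel_index[2], x$voxel_index[3],
              if (length(x$meta$algorithm)) paste0(" <", x$meta$algorithm, ">") else ""))
  invisible(x)
}

target_distance <- function(a, b) {
  sqrt(sum((a$world_mm - b$world_mm)^2))
}
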