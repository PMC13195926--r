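#' Spherical mask in world coordinates
#'
#' A voxel is included iff the Euclidean distance from its world-mm center to
#' `center_mm` is at most `radius_mm`. With radius 0 the mask contains at most
#' the voxel whose center coincides with `center_mm`. This is the primitive
#' behind the DLPFC mask (union of four 20-mm spheres at canonical MNI
#' stimulation sites) and the 10-mm subgenual seed sphere.
#'
#' @param grid a [volume_grid()].
#' @param center_mm length-3 world coordinates, mm.
#' @param radius_mm non-negative radius, mm.
#' @return A [brain_mask()].
#' @export
sphere_mask <- function(grid, center_mm, radius_mm) {
  if (radius_mm < 0) stop("'radius_mm' must be non-negative")
  center_mm <- as.numeric(center_mm)
  ## restrict the candidate set to the voxel bounding box of the sphere
  cv <- world_to_voxel(grid, center_mm)[1, ]
  half <- radius_mm / grid$voxel_size + 1.5
  lo <- pmax(ceiling(cv - half), 1)
  hi <- pmin(floor(cv + half), grid$shape)
  if (any(lo > hi)) {
    warning("sphere lies entirely outside the grid; empty mask")
    return(brain_mask(grid, logical(n_voxels(grid))))
  }
  sub <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  w <- voxel_to_world(grid, sub)
  d2 <- (w[, 1] - center_mm[1])^2 + (w[, 2] - center_mm[2])^2 +
    (w[, 3] - center_mm[3])^2
  keep <- d2 <= radius_mm^2 + 1e-9
  if (!any(keep)) {
    warning("sphere_mask: no voxel centers within radius; empty mask")
  }
  mask_from_indices(grid, sub_to_lin(grid, sub[keep, , drop = FALSE]))
}

#' Percentile (nearest-rank) threshold within an ROI
#'
#' Retains the top `percent`% of ROI voxels with the lowest
#' (`direction = "lowest"`) or highest (`direction = "highest"`) map values.
#' This is the thresholding dialect of the targeting algorithms: "top x%
#' closest to the gyral crown" (lowest sulcal depth / distance-to-scalp) and
#' "top x% most negatively correlated" (lowest FC).
#'
#' Exactly `ceiling(percent/100 * N)` voxels are retained, where N is the
#' number of defined ROI voxels. Ties at the cutoff are broken by a
#' deterministic total order: value first, then linear voxel index. Masks are
#' therefore nested in `percent`.
#'
#' @param map a [scalar_map()].
#' @param roi a [brain_mask()] on the same grid.
#' @param percent in (0, 100].
#' @param direction `"lowest"` or `"highest"`.
#' @return A [brain_mask()] of the retained voxels.
#' @export
percentile_threshold <- function(map, roi, percent,
                                 direction = c("lowest", "highest")) {
  direction <- match.arg(direction)
  stopifnot_same_grid(map$grid, roi$grid)
  if (!is.numeric(percent) || length(percent) != 1L ||
      percent <= 0 || percent > 100) {
    stop("'percent' must be a single value in (0, 100]")
  }
  idx <- which(roi$member & map$valid$member)
  if (!length(idx)) stop("empty ROI")
  ## tiny slack so e.g. 1.3% of 1000 is exactly 13, not ceiling(13 + 2e-15)
  k <- as.integer(ceiling(percent * length(idx) / 100 - 1e-9))
  k <- max(k, 1L)
  v <- map$value[idx]
  if (direction == "highest") v <- -v
  ord <- order(v, idx)           # value, then voxel index: deterministic
  mask_from_indices(map$grid, idx[ord[seq_len(k)]])
}

## relative neighbor offsets for 6/18/26 connectivity
connectivity_offsets <- function(connectivity) {
  if (!connectivity %in% c(6L, 18L, 26L)) {
    stop("'connectivity' must be 6, 18 or 26")
  }
  off <- as.matrix(expand.grid(di = -1:1, dj = -1:1, dk = -1:1))
  ord <- rowSums(abs(off))
  keep <- switch(as.character(connectivity),
                 "6"  = ord == 1,
                 "18" = ord >= 1 & ord <= 2,
                 "26" = ord >= 1)
  off[keep, , drop = FALSE]
}

#' Connected components of a mask
#'
#' Labels maximal connected voxel sets under a 6-, 18- or 26-neighborhood.
#' Labels 1..K are assigned by decreasing component size, with ties broken by
#' the lowest linear voxel index contained in the component. Background is 0.
#'
#' @param mask a [brain_mask()].
#' @param connectivity 6 (faces), 18 (+edges) or 26 (+corners; default).
#' @return A [label_map()].
#' @export
connected_components <- function(mask, connectivity = 26L) {
  grid <- mask$grid
  idx <- mask_indices(mask)
  lab <- integer(n_voxels(grid))
  if (length(idx)) {
    off <- connectivity_offsets(connectivity)
    ## half the offsets suffice for an undirected adjacency
    off <- off[seq_len(nrow(off) / 2), , drop = FALSE]
    sub <- lin_to_sub(grid, idx)
    pos <- integer(n_voxels(grid))      # linear index -> rank among mask voxels
    pos[idx] <- seq_along(idx)
    edges <- vector("list", nrow(off))
    for (r in seq_len(nrow(off))) {
      nb <- sweep(sub, 2, off[r, ], `+`)
      ok <- in_bounds(grid, nb)
      nb_lin <- sub_to_lin(grid, nb[ok, , drop = FALSE])
      hit <- pos[nb_lin] > 0L
      edges[[r]] <- cbind(pos[idx[ok]][hit], pos[nb_lin[hit]])
    }
    edges <- do.call(rbind, edges)
    g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
    if (!is.null(edges) && nrow(edges)) {
      g <- igraph::add_edges(g, t(edges))
    }
    comp <- igraph::components(g)$membership
    ## canonical label order: decreasing size, then lowest voxel index
    size <- tabulate(comp)
    first <- vapply(seq_along(size), function(c) min(idx[comp == c]), 1L)
    rank <- order(-size, first)
    relabel <- integer(length(size))
    relabel[rank] <- seq_along(size)
    lab[idx] <- relabel[comp]
  }
  label_map(grid, lab)
}

component_voxels <- function(labels, label) {
  which(labels$label == as.integer(label))
}

#' Centroid of a labeled component
#'
#' The unweighted arithmetic mean of the world coordinates of the member
#' voxel centers. For non-convex (e.g. C-shaped) components the centroid can
#' lie outside the component; set `snap_to_component = TRUE` to move it to
#' the nearest member voxel center.
#'
#' @param labels a [label_map()].
#' @param label positive integer label present in `labels`.
#' @param snap_to_component snap the centroid to the closest member voxel
#'   center (default `FALSE`).
#' @param meta provenance list stored on the returned point.
#' @return A [target_point()].
#' @export
component_centroid <- function(labels, label, snap_to_component = FALSE,
                               meta = list()) {
  idx <- component_voxels(labels, label)
  if (!length(idx)) stop("label ", label, " not present")
  w <- lin_to_world(labels$grid, idx)
  ctr <- colMeans(w)
  if (snap_to_component) {
    d2 <- (w[, 1] - ctr[1])^2 + (w[, 2] - ctr[2])^2 + (w[, 3] - ctr[3])^2
    ctr <- w[which.min(d2), ]
  }
  target_point(labels$grid, ctr, meta = meta)
}

## mask voxels with at least one in-grid non-member neighbor
boundary_indices <- function(mask, connectivity = 6L) {
  grid <- mask$grid
  idx <- mask_indices(mask)
  if (!length(idx)) return(integer(0))
  off <- connectivity_offsets(connectivity)
  sub <- lin_to_sub(grid, idx)
  on_boundary <- logical(length(idx))
  for (r in seq_len(nrow(off))) {
    nb <- sweep(sub, 2, off[r, ], `+`)
    ok <- in_bounds(grid, nb)
    out <- logical(length(idx))
    out[ok] <- !mask$member[sub_to_lin(grid, nb[ok, , drop = FALSE])]
    on_boundary <- on_boundary | out
  }
  idx[on_boundary]
}

#' Exterior boundary of a mask
#'
#' Member voxels having at least one in-grid non-member neighbor. For a
#' head mask this is the scalp surface; for a brain mask, the brain surface
#' used to place cone-algorithm seed points. The default face (6-)
#' neighborhood yields a one-voxel-thin surface layer; a 26-neighborhood
#' boundary is thicker along diagonals, which degrades surface-distance
#' accuracy.
#'
#' @param mask a [brain_mask()].
#' @param connectivity 6 (default), 18 or 26.
#' @return A [brain_mask()] of boundary voxels.
#' @export
mask_boundary <- function(mask, connectivity = 6L) {
  mask_from_indices(mask$grid, boundary_indices(mask, connectivity))
}

#' Distance from gray-matter voxels to the scalp
#'
#' For each gray voxel, the exact Euclidean distance in mm from its center to
#' the nearest scalp-surface voxel center, where the scalp surface is the
#' exterior face-connected boundary of the head mask (see [mask_boundary()]).
#' The result is defined on `gray` only. The distance is Euclidean
#' (straight-line), not geodesic.
#'
#' @param gray gray-matter [brain_mask()].
#' @param head head (scalp-filling) [brain_mask()] on the same grid; `gray`
#'   is expected to be a subset (violations are tolerated with a warning).
#' @return A [scalar_map()] of distances in mm, valid on `gray`.
#' @export
distance_to_scalp <- function(gray, head) {
  stopifnot_same_grid(gray$grid, head$grid)
  grid <- gray$grid
  n_out <- sum(gray$member & !head$member)
  if (n_out > 0L) {
    warning(n_out, " gray voxels lie outside the head mask")
  }
  surf <- boundary_indices(head)
  if (!length(surf)) {
    stop("head mask has no boundary (fills the whole grid?)")
  }
  gidx <- mask_indices(gray)
  val <- rep(NA_real_, n_voxels(grid))
  if (length(gidx)) {
    gw <- lin_to_world(grid, gidx)
    sw <- lin_to_world(grid, surf)
    ## chunked exact nearest-surface-point search
    s2 <- rowSums(sw^2)
    chunk <- max(1L, floor(2e6 / length(surf)))
    for (start in seq(1L, length(gidx), by = chunk)) {
      sel <- start:min(start + chunk - 1L, length(gidx))
      gsub <- gw[sel, , drop = FALSE]
      d2 <- outer(rowSums(gsub^2), s2, `+`) - 2 * gsub %*% t(sw)
      val[gidx[sel]] <- sqrt(pmax(apply(d2, 1, min), 0))
    }
  }
  scalar_map(grid, val, valid = gray)
}
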