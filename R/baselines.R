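#' Connectome-guided cluster target
#'
#' Baseline algorithm: threshold the seed-FC map within the stimulation mask
#' (retaining the top `fc_percent`% most favorable voxels), label connected
#' components, and return the centroid of the largest component. Ties on
#' component size are broken by the lowest contained voxel index (the
#' canonical component ordering), so the choice is deterministic. Nothing
#' restricts the target to lie near the scalp.
#'
#' An absolute-correlation cutoff can be used instead of a retention
#' percentile via `absolute_r`: voxels with FC <= `absolute_r` (direction
#' negative) or >= `absolute_r` (positive) are retained.
#'
#' @param fc seed-FC [scalar_map()].
#' @param mask stimulation-region [brain_mask()].
#' @param fc_percent retention percentage in (0, 100].
#' @param direction `"negative"` (anticorrelation, depression) or
#'   `"positive"`.
#' @param connectivity component neighborhood (default 26).
#' @param absolute_r optional absolute correlation cutoff overriding
#'   `fc_percent`.
#' @return A [target_point()] with `meta$algorithm = "cluster"`.
#' @export
cluster_target <- function(fc, mask, fc_percent = 10,
                           direction = c("negative", "positive"),
                           connectivity = 26L, absolute_r = NULL) {
  direction <- match.arg(direction)
  if (is.null(absolute_r)) {
    thr <- percentile_threshold(fc, mask, fc_percent,
                                direction = if (direction == "negative")
                                  "lowest" else "highest")
  } else {
    keep <- mask$member & fc$valid$member &
      (if (direction == "negative") fc$value <= absolute_r
       else fc$value >= absolute_r)
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) stop("no voxels survive the absolute FC cutoff")
    thr <- brain_mask(fc$grid, keep)
  }
  labs <- connected_components(thr, connectivity = connectivity)
  if (max(labs$label) == 0L) stop("empty threshold mask")
  out <- component_centroid(labs, 1L,
                            meta = list(algorithm = "cluster",
                                        fc_percent = fc_percent,
                                        direction = direction))
  out
}

#' Leave-one-individual-out cluster threshold selection
#'
#' The cluster baseline needs an FC threshold; it is chosen per individual by
#' leave-one-out cross-validation. For each held-out subject and each
#' candidate threshold, cluster targets are derived for every *other* subject
#' from their training FC maps, each target's inter-session seed FC is
#' evaluated on that subject's held-out data, and the threshold with the most
#' favorable mean evaluation FC (most negative for the depression direction)
#' is assigned to the held-out subject. Thresholds at which some training
#' subject yields no valid target are skipped (with a message).
#'
#' @param subjects list of at least 2 subjects, each a list with elements
#'   `fc_train` ([scalar_map()] used to derive the cluster target),
#'   `ts_eval` ([timeseries_volume()]) and `seed_eval` ([seed_timecourse()])
#'   for evaluation, and `mask` ([brain_mask()]).
#' @param candidate_percents thresholds to search over.
#' @param direction `"negative"` or `"positive"` (favorable FC extreme).
#' @param seed_radius_mm radius of the evaluation seed region, mm.
#' @param connectivity component neighborhood.
#' @return Numeric vector: the selected threshold for each subject.
#' @export
loocv_cluster_threshold <- function(subjects,
                                    candidate_percents = seq(5, 100, by = 5),
                                    direction = c("negative", "positive"),
                                    seed_radius_mm = 5, connectivity = 26L) {
  direction <- match.arg(direction)
  n <- length(subjects)
  if (n < 2L) stop("at least 2 subjects are required")
  ## evaluation FC of subject j's target at threshold p, cached
  eval_fc <- matrix(NA_real_, nrow = n, ncol = length(candidate_percents))
  for (j in seq_len(n)) {
    s <- subjects[[j]]
    for (k in seq_along(candidate_percents)) {
      r <- tryCatch({
        tgt <- cluster_target(s$fc_train, s$mask, candidate_percents[k],
                              direction = direction,
                              connectivity = connectivity)
        target_seed_fc(tgt, radius_mm = seed_radius_mm,
                       ts = s$ts_eval, seed = s$seed_eval)
      }, error = function(e) {
        message("subject ", j, ", threshold ", candidate_percents[k],
                "%: skipped (", conditionMessage(e), ")")
        NA_real_
      })
      eval_fc[j, k] <- r
    }
  }
  sign <- if (direction == "negative") 1 else -1
  vapply(seq_len(n), function(i) {
    train <- eval_fc[-i, , drop = FALSE]
    mean_fc <- colMeans(train)           # NA if any training subject failed
    score <- sign * mean_fc
    if (all(is.na(score))) stop("no threshold valid for all training subjects")
    candidate_percents[which.min(score)] # which.min drops NAs; ties -> first
  }, numeric(1))
}

#' Brain-surface seed points for the cone algorithm
#'
#' Extracts the mask voxels on the exterior boundary of the brain (adjacent
#' to non-brain tissue) and thins them so no two retained points are closer
#' than `spacing_mm`, by greedy farthest-point selection starting from the
#' lowest voxel index. With `spacing_mm = 0` all surface voxels are retained.
#'
#' @param mask stimulation-region [brain_mask()] (e.g. the DLPFC mask
#'   restricted to brain).
#' @param brain whole-brain [brain_mask()] defining the surface.
#' @param spacing_mm minimum pairwise spacing of retained points (default 4).
#' @return List of [target_point()]s (possibly empty, with a warning).
#' @export
surface_seeds <- function(mask, brain, spacing_mm = 4) {
  stopifnot_same_grid(mask$grid, brain$grid)
  surf <- boundary_indices(brain)
  idx <- sort(intersect(surf, mask_indices(mask)))
  if (!length(idx)) {
    warning("mask contains no brain-surface voxels")
    return(list())
  }
  w <- lin_to_world(mask$grid, idx)
  if (spacing_mm > 0 && length(idx) > 1L) {
    sel <- 1L                                # lowest voxel index first
    mind <- sqrt(colSums((t(w) - w[1L, ])^2))
    repeat {
      far <- which.max(mind)                 # ties -> lowest index
      if (mind[far] < spacing_mm) break
      sel <- c(sel, far)
      mind <- pmin(mind, sqrt(colSums((t(w) - w[far, ])^2)))
    }
    sel <- sort(sel)
    idx <- idx[sel]
    w <- w[sel, , drop = FALSE]
  }
  lapply(seq_along(idx), function(i) {
    target_point(mask$grid, w[i, ], meta = list(role = "cone_seed"))
  })
}

#' Cone weighting kernel
#'
#' The cone baseline scores each surface seed by a distance-weighted average
#' of the FC map inside a 12-mm sphere, emulating the linear decay of
#' stimulation effects with distance seen in animal metabolic data. The
#' documented shell radii are 2, 4, 7, 9 and 12 mm. Two weight profiles are
#' provided: `"linear"` (default) decays linearly from a peak at the center
#' to zero at the outer radius; `"shells"` is piecewise-constant per shell,
#' decreasing linearly with shell number. Realized voxel weights within the
#' outer sphere are normalized to a mean of one on whatever grid the kernel
#' is applied to.
#'
#' @param radii_mm increasing shell radii; the last is the support radius.
#' @param profile `"linear"` or `"shells"`.
#' @return A `cone_kernel`.
#' @export
cone_kernel <- function(radii_mm = c(2, 4, 7, 9, 12),
                        profile = c("linear", "shells")) {
  profile <- match.arg(profile)
  radii_mm <- as.numeric(radii_mm)
  if (any(radii_mm <= 0) || any(diff(radii_mm) <= 0)) {
    stop("'radii_mm' must be positive and strictly increasing")
  }
  r_max <- radii_mm[length(radii_mm)]
  weight_at <- if (profile == "linear") {
    function(d) pmax(0, 1 - d / r_max)
  } else {
    n_sh <- length(radii_mm)
    function(d) {
      shell <- findInterval(d, radii_mm, left.open = TRUE) + 1L
      w <- pmax(0, 1 - (shell - 1) / n_sh)
      w[d > r_max] <- 0
      w
    }
  }
  structure(list(radii_mm = radii_mm, r_max = r_max, profile = profile,
                 weight_at = weight_at),
            class = "cone_kernel")
}

#' Realized, mean-one-normalized cone weights around a point
#'
#' @param kernel a [cone_kernel()].
#' @param grid a [volume_grid()].
#' @param center_mm sphere center, world mm.
#' @return List with `idx` (linear voxel indices within the outer radius) and
#'   `w` (weights with mean exactly 1).
#' @export
realize_cone_weights <- function(kernel, grid, center_mm) {
  sph <- sphere_mask(grid, center_mm, kernel$r_max)
  idx <- mask_indices(sph)
  if (!length(idx)) return(list(idx = integer(0), w = numeric(0)))
  wc <- lin_to_world(grid, idx)
  d <- sqrt(colSums((t(wc) - as.numeric(center_mm))^2))
  w <- kernel$weight_at(d)
  list(idx = idx, w = w / mean(w))
}

#' Cone target
#'
#' Baseline algorithm favoring scalp proximity by construction: every
#' brain-surface seed point is scored by the cone-weighted average of the
#' seed-FC map within the kernel's outer sphere, and the seed with the most
#' favorable score (most negative for direction `"negative"`) wins. Seeds
#' whose sphere contains no valid FC voxel are skipped with a message; ties
#' go to the first seed in canonical (lowest-voxel-index) order.
#'
#' @param fc seed-FC [scalar_map()].
#' @param seeds list of [target_point()]s from [surface_seeds()].
#' @param kernel a [cone_kernel()].
#' @param direction `"negative"` or `"positive"`.
#' @return The winning [target_point()], `meta$algorithm = "cone"`,
#'   `meta$score` the cone-weighted FC.
#' @export
cone_target <- function(fc, seeds, kernel = cone_kernel(),
                        direction = c("negative", "positive")) {
  direction <- match.arg(direction)
  if (!length(seeds)) stop("no seed points supplied")
  scores <- rep(NA_real_, length(seeds))
  for (i in seq_along(seeds)) {
    rw <- realize_cone_weights(kernel, fc$grid, seeds[[i]]$world_mm)
    ok <- fc$valid$member[rw$idx]
    if (!any(ok)) {
      message("cone seed ", i, ": no valid FC voxels within ",
              kernel$r_max, " mm; skipped")
      next
    }
    v <- fc$value[rw$idx[ok]]
    w <- rw$w[ok]
    scores[i] <- sum(w * v) / sum(w)
  }
  if (all(is.na(scores))) stop("every cone seed was skipped")
  s <- if (direction == "negative") scores else -scores
  best <- which.min(s)                      # NA-dropping, first-wins ties
  out <- seeds[[best]]
  out$meta <- list(algorithm = "cone", score = scores[best],
                   direction = direction, profile = kernel$profile)
  out
}
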