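#' Threshold sweep for the tree-based algorithm
#'
#' Defines the two threshold sweeps of the tree-based consensus algorithm:
#' the near-scalp sweep over sulcal-depth (or distance-to-scalp) percentiles,
#' and the seed-FC percentile sweep. Defaults are depth 5..10% in steps of
#' 1% and FC 5..100% in steps of 5%, the ranges used for every application
#' of the algorithm (depression and anxiosomatic alike — there is essentially
#' nothing to tune).
#'
#' `fc_direction = "negative"` retains the most negatively correlated voxels
#' (depression: anticorrelation with the subgenual seed); `"positive"`
#' retains the most positively correlated ones (anxiosomatic circuit).
#'
#' @param depth_percents strictly increasing values in (0, 100].
#' @param fc_percents strictly increasing values in (0, 100]; iterated
#'   stringent-to-lenient so tree leaves are built first.
#' @param fc_direction `"negative"` or `"positive"`.
#' @return A `threshold_grid`.
#' @export
threshold_grid <- function(depth_percents = 5:10,
                           fc_percents = seq(5, 100, by = 5),
                           fc_direction = c("negative", "positive")) {
  fc_direction <- match.arg(fc_direction)
  check_percents <- function(p, what) {
    if (!length(p) || any(p <= 0 | p > 100) || any(diff(p) <= 0)) {
      stop("'", what, "' must be strictly increasing within (0, 100]")
    }
  }
  check_percents(depth_percents, "depth_percents")
  check_percents(fc_percents, "fc_percents")
  structure(list(depth_percents = as.numeric(depth_percents),
                 fc_percents = as.numeric(fc_percents),
                 fc_direction = fc_direction),
            class = "threshold_grid")
}

fc_threshold_direction <- function(grid_spec) {
  if (grid_spec$fc_direction == "negative") "lowest" else "highest"
}

#' Personalized network ROI within an anatomical mask
#'
#' Phase 1 of the tree-based algorithm: the voxels of the individual-specific
#' parcellation belonging to the target networks (for depression, the dorsal
#' attention and salience/ventral attention networks), intersected with the
#' anatomical stimulation mask (e.g. the DLPFC sphere-union mask).
#'
#' @param parcellation a [label_map()] of individual network labels.
#' @param target_networks non-empty integer set of network labels.
#' @param anatomical_mask a [brain_mask()].
#' @return A [brain_mask()]; errors if empty (degenerate subject).
#' @export
personalized_roi <- function(parcellation, target_networks, anatomical_mask) {
  stopifnot_same_grid(parcellation$grid, anatomical_mask$grid)
  if (!length(target_networks)) stop("'target_networks' must be non-empty")
  member <- (parcellation$label %in% as.integer(target_networks)) &
    anatomical_mask$member
  if (!any(member)) stop("no target-network voxels in mask")
  brain_mask(parcellation$grid, member)
}

## node bookkeeping for one depth threshold's trees
new_node <- function(id, fc_percent, depth_percent, voxels, centroid) {
  list(id = id, fc_percent = fc_percent, depth_percent = depth_percent,
       voxels = voxels, centroid = centroid,
       children = integer(0), parent = NA_integer_)
}

#' Build candidate-target trees over the threshold sweep
#'
#' Phase 2 of the tree-based algorithm. For each depth percentile d, the ROI
#' is restricted to its top-d% near-scalp voxels. Sweeping the FC percentile
#' from stringent to lenient, the surviving voxels are labeled into connected
#' components and each component's centroid becomes a tree node; a lenient
#' node is the parent of every stricter node whose component it contains
#' (components only grow under nested thresholds, so containment is exact
#' subset containment, checked via a representative voxel). Merging
#' components yield parents with several children; fresh components entering
#' at a lenient level start new leaves; multiple roots per depth threshold
#' are possible.
#'
#' Candidate targets are the leaves plus the parents with at least two
#' children, deduplicated across depth thresholds within `dedup_tol_mm` so a
#' centroid rediscovered at several depth thresholds does not get extra votes
#' in the consensus.
#'
#' @param fc seed-FC [scalar_map()].
#' @param depth sulcal-depth or distance-to-scalp [scalar_map()]
#'   (smaller = closer to scalp / gyral crown).
#' @param roi personalized [brain_mask()] (Phase 1 output).
#' @param grid_spec a [threshold_grid()].
#' @param connectivity component neighborhood, 6/18/26 (default 26).
#' @param dedup_tol_mm candidates closer than this are considered duplicates
#'   (default half the smallest voxel edge).
#' @return A `candidate_forest`: list with `trees` (per depth percent, a list
#'   of node records), `candidates` (list of [target_point()]) and
#'   `candidate_info` (data.frame with per-candidate provenance).
#' @export
build_forest <- function(fc, depth, roi, grid_spec = threshold_grid(),
                         connectivity = 26L, dedup_tol_mm = NULL) {
  stopifnot_same_grid(fc$grid, roi$grid)
  stopifnot_same_grid(depth$grid, roi$grid)
  grid <- roi$grid
  if (is.null(dedup_tol_mm)) dedup_tol_mm <- min(grid$voxel_size) / 2
  fc_dir <- fc_threshold_direction(grid_spec)

  trees <- list()
  cand_rows <- list()
  for (d in grid_spec$depth_percents) {
    near_roi <- percentile_threshold(depth, roi, d, direction = "lowest")
    nodes <- list()
    prev_ids <- integer(0)
    ## lenient levels are supersets of stringent ones: iterate stringent first
    for (p in grid_spec$fc_percents) {
      m <- percentile_threshold(fc, near_roi, p, direction = fc_dir)
      labs <- connected_components(m, connectivity = connectivity)
      k <- max(labs$label)
      level_ids <- integer(k)
      for (lab in seq_len(k)) {
        vox <- component_voxels(labs, lab)
        ctr <- component_centroid(labs, lab)
        id <- length(nodes) + 1L
        nodes[[id]] <- new_node(id, p, d, vox, ctr$world_mm)
        level_ids[lab] <- id
      }
      ## nested masks: each previous node lies in exactly one current
      ## component, identified by any one of its voxels
      for (pid in prev_ids) {
        rep_vox <- nodes[[pid]]$voxels[1]
        parent <- level_ids[labs$label[rep_vox]]
        nodes[[pid]]$parent <- parent
        nodes[[parent]]$children <- c(nodes[[parent]]$children, pid)
      }
      prev_ids <- level_ids
    }
    trees[[as.character(d)]] <- nodes
    for (nd in nodes) {
      n_child <- length(nd$children)
      if (n_child == 0L || n_child >= 2L) {
        cand_rows[[length(cand_rows) + 1L]] <- data.frame(
          depth_percent = nd$depth_percent, fc_percent = nd$fc_percent,
          node_id = nd$id, n_children = n_child, n_voxels = length(nd$voxels),
          x_mm = nd$centroid[1], y_mm = nd$centroid[2], z_mm = nd$centroid[3])
      }
    }
  }
  if (!length(cand_rows)) stop("all threshold masks empty; no candidates")
  info <- do.call(rbind, cand_rows)
  ## deterministic order before dedup: depth, fc level, node id
  info <- info[order(info$depth_percent, info$fc_percent, info$node_id), ,
               drop = FALSE]
  keep <- dedup_points(as.matrix(info[, c("x_mm", "y_mm", "z_mm")]),
                       dedup_tol_mm)
  info <- info[keep, , drop = FALSE]
  rownames(info) <- NULL
  candidates <- lapply(seq_len(nrow(info)), function(i) {
    target_point(grid, c(info$x_mm[i], info$y_mm[i], info$z_mm[i]),
                 meta = list(algorithm = "tree",
                             depth_percent = info$depth_percent[i],
                             fc_percent = info$fc_percent[i],
                             n_children = info$n_children[i]))
  })
  structure(list(trees = trees, candidates = candidates,
                 candidate_info = info, grid = grid,
                 settings = list(grid_spec = grid_spec,
                                 connectivity = connectivity,
                                 dedup_tol_mm = dedup_tol_mm)),
            class = "candidate_forest")
}

#' @export
print.candidate_forest <- function(x, ...) {
  cat("candidate_forest:", length(x$trees), "depth thresholds,",
      length(x$candidates), "candidate targets\n")
  invisible(x)
}

## greedy first-seen dedup at tolerance tol (mm); returns logical keep vector
dedup_points <- function(xyz, tol) {
  n <- nrow(xyz)
  keep <- logical(n)
  kept <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    if (!nrow(kept) ||
        min(colSums((t(kept) - xyz[i, ])^2)) > tol^2) {
      keep[i] <- TRUE
      kept <- rbind(kept, xyz[i, ])
    }
  }
  keep
}

#' Consensus target among candidates
#'
#' Phase 3: returns the candidate minimizing the mean Euclidean distance to
#' all other candidates. A single candidate is returned as-is. Ties on mean
#' distance (within 1e-9 mm) are broken by the more favorable FC value at the
#' candidate's nearest voxel when an FC map and direction are supplied, then
#' by lexicographic voxel index — the better-connected site wins,
#' deterministically.
#'
#' @param candidates non-empty list of [target_point()]s.
#' @param fc optional [scalar_map()] used for tie-breaking.
#' @param fc_direction `"negative"` or `"positive"`; which FC extreme is
#'   favorable.
#' @return The winning [target_point()], with `meta$mean_distance_mm` and
#'   `meta$n_candidates` recorded.
#' @export
consensus_target <- function(candidates, fc = NULL,
                             fc_direction = c("negative", "positive")) {
  fc_direction <- match.arg(fc_direction)
  if (!length(candidates)) stop("empty candidate list")
  n <- length(candidates)
  xyz <- t(vapply(candidates, function(t) t$world_mm, numeric(3)))
  if (n == 1L) {
    md <- 0
    best <- 1L
  } else {
    dm <- as.matrix(stats::dist(xyz))
    mean_d <- rowSums(dm) / (n - 1)
    best_d <- min(mean_d)
    tied <- which(mean_d <= best_d + 1e-9)
    if (length(tied) > 1L) {
      ## favorable FC first (lower for negative direction), then voxel index
      fc_val <- rep(0, length(tied))
      if (!is.null(fc)) {
        fc_val <- vapply(tied, function(i) {
          v <- fc$value[matrix(candidates[[i]]$voxel_index, nrow = 1)]
          if (is.na(v)) Inf else if (fc_direction == "negative") v else -v
        }, numeric(1))
      }
      vox <- t(vapply(tied, function(i) candidates[[i]]$voxel_index,
                      integer(3)))
      ord <- order(fc_val, vox[, 1], vox[, 2], vox[, 3])
      best <- tied[ord[1]]
    } else {
      best <- tied
    }
    md <- mean_d[best]
  }
  out <- candidates[[best]]
  out$meta$mean_distance_mm <- unname(md)
  out$meta$n_candidates <- n
  out
}

#' Tree-based consensus target localization
#'
#' The full three-phase pipeline: (1) the personalized network ROI within the
#' anatomical mask, (2) candidate trees over the sulcal-depth x FC threshold
#' sweep, (3) the consensus candidate closest on average to all others.
#'
#' @inheritParams personalized_roi
#' @inheritParams build_forest
#' @param fc individual seed-FC [scalar_map()].
#' @param depth sulcal-depth or distance-to-scalp [scalar_map()].
#' @return List with `target` (a [target_point()], `meta$algorithm = "tree"`)
#'   and `forest` (the full [build_forest()] output, for audit).
#' @export
tree_based_target <- function(parcellation, fc, depth, anatomical_mask,
                              target_networks, grid_spec = threshold_grid(),
                              connectivity = 26L, dedup_tol_mm = NULL) {
  roi <- personalized_roi(parcellation, target_networks, anatomical_mask)
  forest <- build_forest(fc, depth, roi, grid_spec = grid_spec,
                         connectivity = connectivity,
                         dedup_tol_mm = dedup_tol_mm)
  target <- consensus_target(forest$candidates, fc = fc,
                             fc_direction = grid_spec$fc_direction)
  target$meta$algorithm <- "tree"
  list(target = target, forest = forest)
}
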