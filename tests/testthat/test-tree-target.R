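test_that("threshold_grid validates its sweeps", {
  tg <- threshold_grid()
  expect_equal(tg$depth_percents, 5:10)
  expect_equal(tg$fc_percents, seq(5, 100, 5))
  expect_equal(tg$fc_direction, "negative")
  expect_error(threshold_grid(depth_percents = c(10, 5)), "increasing")
  expect_error(threshold_grid(fc_percents = c(0, 50)), "increasing")
})

test_that("personalized_roi filters parcellation labels inside the anatomical mask", {
  g <- grid_iso(4)
  parc_all <- label_map(g, array(2L, rep(4, 3)))
  anat <- mask_from_indices(g, 1:20)
  roi <- personalized_roi(parc_all, c(1L, 2L), anat)
  expect_identical(roi$member, anat$member)

  expect_error(personalized_roi(parc_all, 5L, anat), "no target-network")
  expect_error(personalized_roi(parc_all, integer(0), anat), "non-empty")

  ## checkerboard of labels {1,2,3}, targets {1,3}, half-grid mask
  labs <- array((seq_len(64) %% 3) + 1L, rep(4, 3))
  parc <- label_map(g, labs)
  half <- mask_from_indices(g, 1:32)
  roi2 <- personalized_roi(parc, c(1L, 3L), half)
  want <- (labs %in% c(1L, 3L)) & half$member
  expect_identical(as.vector(roi2$member), as.vector(want))
})

## a 1D double-well FC profile embedded in a 9x3x3 grid: two separated
## minima that merge only at the most lenient level
double_well <- function() {
  g <- volume_grid(c(9, 3, 3), diag(4))
  roi_sub <- cbind(1:9, 1, 1)
  roi <- mask_from_indices(g, treetarget:::sub_to_lin(g, roi_sub))
  fcv <- rep(NA_real_, prod(g$shape))
  fcv[mask_indices(roi)] <- c(-1, -0.9, -0.2, 0, 0.1, 0, -0.25, -0.95, -0.85)
  depthv <- rep(NA_real_, prod(g$shape))
  depthv[mask_indices(roi)] <- 1
  list(g = g, roi = roi, fc = scalar_map(g, fcv), depth = scalar_map(g, depthv))
}

test_that("build_forest traces component evolution: two wells give two leaves and a merge parent", {
  dw <- double_well()
  spec <- threshold_grid(depth_percents = 100, fc_percents = c(25, 50, 100))
  forest <- build_forest(dw$fc, dw$depth, dw$roi, spec)
  nodes <- forest$trees[["100"]]

  ## level 25%: 3 voxels {1,2} and {8} -> two leaves
  ## level 50%: 5 voxels {1,2} and {7,8,9} -> single-child chain parents
  ## level 100%: all 9 -> one root with two children (merge)
  info <- forest$candidate_info
  expect_equal(nrow(info), 3L)
  expect_setequal(info$fc_percent, c(25, 25, 100))
  leaf_x <- sort(info$x_mm[info$fc_percent == 25])
  expect_equal(leaf_x, c(mean(c(0, 1)), 7))   # centroids of {1,2} and {8}
  expect_equal(info$x_mm[info$fc_percent == 100], 4)  # centroid of 1..9
  expect_equal(info$n_children[info$fc_percent == 100], 2L)

  ## chain nodes at 50% exist in the tree but are not candidates
  chain <- Filter(function(n) n$fc_percent == 50, nodes)
  expect_length(chain, 2L)
  expect_true(all(vapply(chain, function(n) length(n$children), 1L) == 1L))

  ## voxelwise parent containment
  for (nd in nodes) {
    for (ch in nd$children) {
      expect_true(all(nodes[[ch]]$voxels %in% nd$voxels))
    }
  }
})

test_that("a single isolated ROI voxel yields one linear chain and one candidate", {
  g <- grid_iso(4)
  roi <- mask_from_indices(g, 7)
  v <- rep(NA_real_, 64); v[7] <- -0.5
  d <- rep(NA_real_, 64); d[7] <- 2
  forest <- build_forest(scalar_map(g, v), scalar_map(g, d), roi,
                         threshold_grid(depth_percents = c(50, 100)))
  expect_length(forest$candidates, 1L)
  expect_equal(forest$candidates[[1]]$world_mm, voxel_to_world(g, c(3, 2, 1))[1, ])
})

test_that("surviving voxel sets are nested across the FC sweep", {
  subj <- small_subject()
  fc <- fc_map(subj$sessions[[1]], subj$seed_timecourses[[1]], subj$gray)
  roi <- personalized_roi(subj$parcellation, subj$target_networks,
                          subj$anatomical_mask)
  near <- percentile_threshold(subj$depth, roi, 8, "lowest")
  prev <- NULL
  for (p in seq(5, 100, 5)) {
    cur <- percentile_threshold(fc, near, p, "lowest")
    if (!is.null(prev)) expect_true(all(cur$member[prev$member]))
    prev <- cur
  }
})

test_that("consensus_target minimizes mean distance with deterministic ties", {
  g <- grid_iso(20)
  mk <- function(x) target_point(g, c(x, 0, 0))
  one <- consensus_target(list(mk(4)))
  expect_equal(one$world_mm, c(4, 0, 0))

  cands <- lapply(c(0, 1, 10), mk)
  best <- consensus_target(cands)
  expect_equal(best$world_mm, c(1, 0, 0))
  expect_equal(best$meta$mean_distance_mm, 5)

  ## two candidates: symmetric tie, resolved deterministically and stably
  pair <- lapply(c(2, 6), mk)
  t1 <- consensus_target(pair)
  t2 <- consensus_target(pair)
  expect_identical(t1$world_mm, t2$world_mm)
  expect_equal(t1$world_mm, c(2, 0, 0))     # lexicographic voxel-index tie-break

  ## FC tie-break prefers the better-connected site
  fcv <- rep(0, 8000)
  fcv[treetarget:::sub_to_lin(g, c(7, 1, 1))] <- -0.9
  tie_fc <- consensus_target(pair, fc = scalar_map(grid_iso(20), fcv),
                             fc_direction = "negative")
  expect_equal(tie_fc$world_mm, c(6, 0, 0))

  expect_error(consensus_target(list()), "empty")
})

test_that("tree_based_target recovers a planted near-scalp blob and is deterministic", {
  subj <- small_subject()
  fc <- fc_map(subj$sessions[[1]], subj$seed_timecourses[[1]], subj$gray)
  res <- tree_based_target(subj$parcellation, fc, subj$depth,
                           subj$anatomical_mask, subj$target_networks)
  err <- sqrt(sum((res$target$world_mm - subj$truth[1, ])^2))
  expect_lt(err, 2 * max(subj$grid$voxel_size))

  ## consensus is a member of the candidate set
  xyz <- t(vapply(res$forest$candidates, function(t) t$world_mm, numeric(3)))
  expect_true(any(colSums(abs(t(xyz) - res$target$world_mm)) < 1e-12))

  ## bit-identical rerun
  res2 <- tree_based_target(subj$parcellation, fc, subj$depth,
                            subj$anatomical_mask, subj$target_networks)
  expect_identical(res$target$world_mm, res2$target$world_mm)
  expect_identical(res$forest$candidate_info, res2$forest$candidate_info)
})

test_that("negating FC and flipping the direction leaves the target unchanged", {
  subj <- small_subject()
  fc <- fc_map(subj$sessions[[1]], subj$seed_timecourses[[1]], subj$gray)
  res_neg <- tree_based_target(subj$parcellation, fc, subj$depth,
                               subj$anatomical_mask, subj$target_networks,
                               grid_spec = threshold_grid(fc_direction = "negative"))
  fc_flip <- scalar_map(fc$grid, -fc$value, valid = fc$valid)
  res_pos <- tree_based_target(subj$parcellation, fc_flip, subj$depth,
                               subj$anatomical_mask, subj$target_networks,
                               grid_spec = threshold_grid(fc_direction = "positive"))
  expect_identical(res_neg$target$world_mm, res_pos$target$world_mm)
})

test_that("all candidate components lie within the personalized ROI and their depth mask", {
  subj <- small_subject()
  fc <- fc_map(subj$sessions[[1]], subj$seed_timecourses[[1]], subj$gray)
  roi <- personalized_roi(subj$parcellation, subj$target_networks,
                          subj$anatomical_mask)
  forest <- build_forest(fc, subj$depth, roi)
  for (d in names(forest$trees)) {
    near <- percentile_threshold(subj$depth, roi, as.numeric(d), "lowest")
    for (nd in forest$trees[[d]]) {
      expect_true(all(near$member[nd$voxels]))
      expect_true(all(roi$member[nd$voxels]))
    }
  }
})
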