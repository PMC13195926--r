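test_that("cluster_target picks the centroid of the largest surviving component", {
  g <- grid_iso(10)
  ## FC: a 10-voxel negative bar and a 3-voxel more-negative clump,
  ## everything else mildly positive
  fcv <- rep(0.5, 1000)
  bar <- treetarget:::sub_to_lin(g, cbind(1:10, 2, 2))
  clump <- treetarget:::sub_to_lin(g, cbind(1:3, 8, 8))
  fcv[bar] <- -0.5
  fcv[clump] <- -0.9
  fc <- scalar_map(g, fcv)
  mask <- brain_mask(g, array(TRUE, rep(10, 3)))

  ## 13/1000 voxels -> 1.3% retains exactly bar+clump; bar is the larger component
  t13 <- cluster_target(fc, mask, 1.3)
  expect_equal(t13$world_mm, colMeans(voxel_to_world(g, cbind(1:10, 2, 2))))
  expect_equal(t13$meta$algorithm, "cluster")

  ## single blob: its centroid regardless of anything else
  t3 <- cluster_target(fc, mask, 0.3)
  expect_equal(t3$world_mm, colMeans(voxel_to_world(g, cbind(1:3, 8, 8))))

  ## absolute cutoff dialect
  tabs <- cluster_target(fc, mask, absolute_r = -0.8)
  expect_equal(tabs$world_mm, t3$world_mm)

  ## equal-size components: deterministic, stable tie-break
  fcv2 <- rep(0.5, 1000)
  a <- treetarget:::sub_to_lin(g, cbind(1:3, 1, 1))
  b <- treetarget:::sub_to_lin(g, cbind(1:3, 5, 5))
  fcv2[c(a, b)] <- -0.7
  fc2 <- scalar_map(g, fcv2)
  r1 <- cluster_target(fc2, mask, 0.6)
  r2 <- cluster_target(fc2, mask, 0.6)
  expect_identical(r1$world_mm, r2$world_mm)
  expect_equal(r1$world_mm, colMeans(voxel_to_world(g, cbind(1:3, 1, 1))))
})

test_that("cluster_target equals tree_based_target when depth is uniform and one component survives everywhere", {
  g <- grid_iso(7)
  roi_idx <- treetarget:::sub_to_lin(g, as.matrix(expand.grid(2:6, 2:6, 2)))
  roi <- mask_from_indices(g, roi_idx)
  set.seed(13)
  fcv <- rep(NA_real_, 343)
  ## strictly decreasing toward the center voxel so every threshold keeps a
  ## single connected blob around it
  sub <- treetarget:::lin_to_sub(g, roi_idx)
  d2 <- (sub[, 1] - 4)^2 + (sub[, 2] - 4)^2
  fcv[roi_idx] <- -1 + d2 * 0.04 + seq_along(roi_idx) * 1e-5
  fc <- scalar_map(g, fcv)
  dep <- rep(NA_real_, 343); dep[roi_idx] <- 1
  depth <- scalar_map(g, dep)
  parc <- label_map(g, array(1L, rep(7, 3)))

  res <- tree_based_target(parc, fc, depth, roi, 1L,
                           grid_spec = threshold_grid(depth_percents = 100))
  ## all candidates are centroids of nested single components; the cluster
  ## target at the same most-stringent retention is one of them
  clus <- cluster_target(fc, roi, 5)
  xyz <- t(vapply(res$forest$candidates, function(t) t$world_mm, numeric(3)))
  expect_true(any(sqrt(colSums((t(xyz) - clus$world_mm)^2)) < 1e-9))
})

test_that("loocv_cluster_threshold picks the best training-mean threshold per held-out subject", {
  ## identical subjects -> every fold returns the same threshold
  g <- grid_iso(8, mm = 2)
  set.seed(21)
  mask <- mask_from_indices(g, treetarget:::sub_to_lin(
    g, as.matrix(expand.grid(2:7, 2:7, 2:7))))
  mk_subject <- function(blob_center_sub, seed) {
    set.seed(seed)
    sig <- rnorm(40)
    fcv <- rep(NA_real_, 512)
    sub <- treetarget:::lin_to_sub(g, mask_indices(mask))
    d2 <- rowSums((sub - matrix(blob_center_sub, nrow(sub), 3, byrow = TRUE))^2)
    coup <- -0.9 * exp(-d2 / 6)
    fcv[mask_indices(mask)] <- coup
    mat <- matrix(0, 40, 512)
    mat[, mask_indices(mask)] <- outer(sig, coup) +
      matrix(rnorm(40 * nrow(sub), 0, 0.4), 40)
    list(fc_train = scalar_map(g, fcv),
         ts_eval = timeseries_volume(g, mat, valid = mask),
         seed_eval = seed_timecourse(sig), mask = mask)
  }
  subs <- lapply(1:3, function(i) mk_subject(c(4, 4, 4), seed = 100))
  got <- loocv_cluster_threshold(subs, candidate_percents = c(10, 50, 100))
  expect_length(got, 3L)
  expect_true(all(got == got[1]))
  expect_true(all(got %in% c(10, 50, 100)))

  ## the held-out subject's own data must not influence its threshold:
  ## replacing subject 1's data leaves fold-1's choice unchanged
  subs2 <- subs
  subs2[[1]] <- mk_subject(c(6, 6, 6), seed = 200)
  got2 <- loocv_cluster_threshold(subs2, candidate_percents = c(10, 50, 100))
  expect_identical(got2[1], got[1])
})

test_that("surface_seeds extracts boundary voxels thinned to the requested spacing", {
  g <- grid_iso(12)
  ## 1-voxel-thick slab: every voxel is on the brain boundary
  slab_idx <- treetarget:::sub_to_lin(g, as.matrix(expand.grid(1:12, 1:12, 5)))
  brain <- mask_from_indices(g, slab_idx)
  seeds <- surface_seeds(brain, brain, spacing_mm = 4)
  expect_gt(length(seeds), 3L)
  xyz <- t(vapply(seeds, function(t) t$world_mm, numeric(3)))
  dmat <- as.matrix(dist(xyz))
  expect_true(all(dmat[upper.tri(dmat)] >= 4))

  ## spacing 0 retains every surface voxel
  all_seeds <- surface_seeds(brain, brain, spacing_mm = 0)
  expect_length(all_seeds, length(slab_idx))

  ## a fully interior mask has no surface voxels
  cube <- mask_from_indices(g, treetarget:::sub_to_lin(
    g, as.matrix(expand.grid(4:8, 4:8, 4:8))))
  inner <- mask_from_indices(g, treetarget:::sub_to_lin(g, c(6, 6, 6)))
  expect_warning(empty <- surface_seeds(inner, cube), "no brain-surface")
  expect_length(empty, 0L)
})

test_that("cone kernel weights are non-increasing and normalize to mean one", {
  k <- cone_kernel()
  expect_equal(k$radii_mm, c(2, 4, 7, 9, 12))
  d <- seq(0, 14, by = 0.5)
  w <- k$weight_at(d)
  expect_true(all(w >= 0))
  expect_true(all(diff(w) <= 1e-12))
  expect_equal(w[d > 12], rep(0, sum(d > 12)))

  for (mm in c(1, 2, 3.3)) {
    g <- grid_iso(31, mm = mm)
    rw <- realize_cone_weights(k, g, voxel_to_world(g, rep(16, 3))[1, ])
    expect_equal(mean(rw$w), 1, tolerance = 1e-9)
  }

  ks <- cone_kernel(profile = "shells")
  ws <- ks$weight_at(c(0, 3, 5, 8, 10, 13))
  expect_true(all(diff(ws) <= 1e-12))
  expect_equal(ws[6], 0)
})

test_that("cone_target scores seeds by the hand-computed weighted FC mean", {
  g <- grid_iso(15, mm = 2)
  fcv <- rep(0, 15^3)
  fc_const <- scalar_map(g, fcv)
  seeds <- lapply(list(c(3, 3, 3), c(8, 8, 8), c(12, 12, 12)), function(s)
    target_point(g, voxel_to_world(g, s)[1, ]))

  ## constant field: every seed ties; first in order wins
  t_const <- cone_target(fc_const, seeds)
  expect_equal(t_const$world_mm, seeds[[1]]$world_mm)
  expect_equal(t_const$meta$score, 0)

  ## dominant wide minimum under seed 2
  fcv2 <- rep(0, 15^3)
  blob <- sphere_mask(g, voxel_to_world(g, c(8, 8, 8))[1, ], 13)
  fcv2[mask_indices(blob)] <- -1
  t_blob <- cone_target(scalar_map(g, fcv2), seeds)
  expect_equal(t_blob$world_mm, seeds[[2]]$world_mm)

  ## hand-computed weighted mean on a sparse-valid map
  k <- cone_kernel()
  fcv3 <- rep(NA_real_, 15^3)
  vox <- rbind(c(8, 8, 8), c(9, 8, 8), c(8, 10, 8), c(8, 8, 11), c(10, 10, 8))
  vals <- c(-0.8, -0.4, 0.2, -0.1, 0.5)
  fcv3[treetarget:::sub_to_lin(g, vox)] <- vals
  fc3 <- scalar_map(g, fcv3)
  ctr <- voxel_to_world(g, c(8, 8, 8))[1, ]
  dmm <- sqrt(colSums((t(voxel_to_world(g, vox)) - ctr)^2))
  wts <- k$weight_at(dmm)
  hand <- sum(wts * vals) / sum(wts)
  one_seed <- list(target_point(g, ctr))
  got <- cone_target(fc3, one_seed, k)
  expect_equal(got$meta$score, hand, tolerance = 1e-12)

  ## seeds with no valid FC voxels nearby are skipped; all skipped -> error
  far_seed <- list(target_point(g, voxel_to_world(g, c(1, 1, 1))[1, ]))
  expect_error(suppressMessages(cone_target(fc3, far_seed)), "skipped")
})

test_that("shifting FC by a constant shifts cone scores but preserves the argmin", {
  g <- grid_iso(13, mm = 2)
  set.seed(31)
  fcv <- rnorm(13^3, 0, 0.3)
  fc <- scalar_map(g, fcv)
  seeds <- lapply(list(c(3, 3, 3), c(7, 7, 7), c(10, 4, 6)), function(s)
    target_point(g, voxel_to_world(g, s)[1, ]))
  t0 <- cone_target(fc, seeds)
  t_shift <- cone_target(scalar_map(g, fcv + 5), seeds)
  expect_equal(t_shift$world_mm, t0$world_mm)
  expect_equal(t_shift$meta$score, t0$meta$score + 5, tolerance = 1e-9)
})
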