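test_that("sphere_mask matches brute-force enumeration and handles degenerate radii", {
  g <- grid_iso(25)
  ctr <- voxel_to_world(g, c(13, 13, 13))[1, ]

  m0 <- sphere_mask(g, ctr, 0)
  expect_equal(mask_indices(m0), treetarget:::sub_to_lin(g, c(13, 13, 13)))

  m10 <- sphere_mask(g, ctr, 10)
  w <- voxel_to_world(g, arrayInd(seq_len(25^3), rep(25, 3)))
  inside <- sqrt(colSums((t(w) - ctr)^2)) <= 10
  expect_identical(sort(mask_indices(m10)), which(inside))

  expect_warning(sphere_mask(g, c(500, 500, 500), 0), "outside|empty")
})

test_that("a union-of-spheres mask equals the voxelwise OR of the individual spheres", {
  ## the four canonical 20-mm DLPFC sphere centers (MNI mm)
  centers <- rbind(c(-36, 39, 43), c(-44, 40, 29), c(-41, 16, 54),
                   c(-37, 26, 49))
  aff <- diag(c(2, 2, 2, 1)); aff[1:3, 4] <- c(-70, -10, 10)
  g <- volume_grid(c(40, 40, 40), aff)
  parts <- lapply(seq_len(4), function(i) sphere_mask(g, centers[i, ], 20))
  dlpfc <- Reduce(mask_union, parts)
  manual <- Reduce(`|`, lapply(parts, function(m) m$member))
  expect_identical(dlpfc$member, manual)
  expect_gt(mask_size(dlpfc), mask_size(parts[[1]]))
})

test_that("percentile_threshold implements nearest-rank retention with nesting", {
  g <- grid_iso(5)
  set.seed(3)
  vals <- array(rnorm(125), rep(5, 3))
  map <- scalar_map(g, vals)
  roi <- mask_from_indices(g, sample(125, 20))

  expect_identical(percentile_threshold(map, roi, 100, "lowest")$member,
                   roi$member)

  m5 <- percentile_threshold(map, roi, 5, "lowest")
  expect_equal(mask_indices(m5),
               mask_indices(roi)[which.min(map$value[mask_indices(roi)])])

  prev <- NULL
  for (p in c(5, 20, 35, 50, 80, 100)) {
    cur <- percentile_threshold(map, roi, p, "lowest")
    expect_equal(mask_size(cur), ceiling(p / 100 * 20))
    if (!is.null(prev)) expect_true(all(cur$member[prev$member]))
    prev <- cur
  }

  for (p in c(10, 37, 62)) {
    for (dir in c("lowest", "highest")) {
      expect_identical(sort(mask_indices(percentile_threshold(map, roi, p, dir))),
                       sort_and_count_threshold(map$value, mask_indices(roi), p, dir))
    }
  }

  empty <- brain_mask(g, logical(125))
  expect_error(percentile_threshold(map, empty, 10), "empty ROI")
})

test_that("percentile_threshold breaks ties at the cutoff deterministically", {
  g <- grid_iso(3)
  map <- scalar_map(g, array(1, rep(3, 3)))   # all values tied
  roi <- brain_mask(g, array(TRUE, rep(3, 3)))
  m <- percentile_threshold(map, roi, 25, "lowest")
  expect_equal(mask_indices(m), 1:7)          # lowest linear indices win
  expect_identical(m$member,
                   percentile_threshold(map, roi, 25, "lowest")$member)
})

test_that("connectivity semantics: corner-sharing voxels split under 6 but join under 26", {
  g <- grid_iso(3)
  m <- mask_from_indices(g, treetarget:::sub_to_lin(g, rbind(c(1, 1, 1), c(2, 2, 2))))
  expect_equal(max(connected_components(m, 6)$label), 2L)
  expect_equal(max(connected_components(m, 18)$label), 2L)
  expect_equal(max(connected_components(m, 26)$label), 1L)
  empty <- brain_mask(g, logical(27))
  expect_equal(max(connected_components(empty)$label), 0L)
})

test_that("connected_components agrees with a BFS flood-fill oracle on random masks", {
  set.seed(11)
  for (rep in 1:12) {
    n <- sample(4:8, 1)
    conn <- sample(c(6L, 18L, 26L), 1)
    m <- random_mask(grid_iso(n), p = runif(1, 0.1, 0.5))
    got <- connected_components(m, conn)$label
    want <- bfs_components(m$member, conn)
    expect_identical(got, array(as.integer(want), dim(want)))
  }
})

test_that("component labels are ordered by decreasing size then lowest voxel index", {
  g <- grid_iso(10)
  big <- treetarget:::sub_to_lin(g, cbind(5:9, 5, 5))     # 5 voxels
  small <- treetarget:::sub_to_lin(g, cbind(1:2, 1, 1))   # 2 voxels
  labs <- connected_components(mask_from_indices(g, c(big, small)), 26)
  expect_true(all(labs$label[big] == 1L))
  expect_true(all(labs$label[small] == 2L))
})

test_that("component_centroid is the coordinate mean, optionally snapped", {
  g <- grid_iso(10, mm = 2)
  one <- mask_from_indices(g, treetarget:::sub_to_lin(g, c(4, 5, 6)))
  labs <- connected_components(one)
  expect_equal(component_centroid(labs, 1)$world_mm,
               voxel_to_world(g, c(4, 5, 6))[1, ])

  two <- mask_from_indices(g, treetarget:::sub_to_lin(g, rbind(c(1, 1, 1), c(2, 1, 1))))
  ctr <- component_centroid(connected_components(two), 1)$world_mm
  expect_equal(ctr, c(1, 0, 0))              # midpoint of (0,0,0) and (2,0,0)

  ## C-shape: centroid of the listed coordinates lies outside the component
  csub <- rbind(c(1, 1, 1), c(1, 2, 1), c(1, 3, 1),
                c(3, 1, 1), c(3, 2, 1), c(3, 3, 1), c(2, 3, 1))
  cmask <- mask_from_indices(g, treetarget:::sub_to_lin(g, csub))
  clabs <- connected_components(cmask)
  cc <- component_centroid(clabs, 1)
  expect_equal(cc$world_mm, colMeans(voxel_to_world(g, csub)))
  expect_false(cmask$member[matrix(round(world_to_voxel(g, cc$world_mm)), nrow = 1)])
  snapped <- component_centroid(clabs, 1, snap_to_component = TRUE)
  expect_true(cmask$member[matrix(snapped$voxel_index, nrow = 1)])

  expect_error(component_centroid(clabs, 99), "not present")
})

test_that("distance_to_scalp matches analytic sphere geometry", {
  n <- 25
  g <- grid_iso(n, mm = 2)
  w <- voxel_to_world(g, arrayInd(seq_len(n^3), rep(n, 3)))
  ctr <- voxel_to_world(g, rep((n + 1) / 2, 3))[1, ]
  r <- sqrt(colSums((t(w) - ctr)^2))
  R <- 20
  head <- brain_mask(g, r <= R)
  gray <- brain_mask(g, r <= R - 4 & r >= R - 12)
  d <- distance_to_scalp(gray, head)
  idx <- mask_indices(gray)
  expect_true(all(d$value[idx] >= 0))
  expect_lt(max(abs(d$value[idx] - (R - r[idx]))), max(g$voxel_size))
  expect_true(all(is.na(d$value[!gray$member])))
})

test_that("distance_to_scalp boundary handling", {
  g <- grid_iso(6)
  full <- brain_mask(g, array(TRUE, rep(6, 3)))
  expect_error(distance_to_scalp(full, full), "boundary")

  head <- mask_from_indices(g, which(array(TRUE, rep(6, 3)))[1:100])
  ## gray voxel on the head boundary is within one voxel diagonal of the surface
  surf <- mask_boundary(head)
  gray1 <- mask_from_indices(g, mask_indices(surf)[1])
  d <- distance_to_scalp(gray1, head)
  expect_lte(d$value[mask_indices(gray1)], sqrt(3) * max(g$voxel_size))

  outside <- mask_from_indices(g, setdiff(seq_len(216), mask_indices(head))[1])
  expect_warning(distance_to_scalp(outside, head), "outside")
})
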