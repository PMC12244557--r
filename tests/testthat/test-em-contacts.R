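# Distance transform, contact detection, patch assignment and rollups.

test_that("distance map reproduces hand-computed distances", {
  seeds <- array(0L, c(5, 5, 5)); seeds[3, 3, 3] <- 1L
  dmap <- distance_map(label_volume(seeds, c(10, 10, 10)))
  expect_equal(dmap$distances[3, 3, 3], 0)
  expect_equal(dmap$distances[1, 1, 1], sqrt(3 * 20^2), tolerance = 1e-12)
  # anisotropic z: neighbour along z is one z-spacing away
  seeds2 <- array(0L, c(3, 3, 3)); seeds2[2, 2, 2] <- 1L
  dmap2 <- distance_map(label_volume(seeds2, c(10, 10, 50)))
  expect_equal(dmap2$distances[2, 2, 3], 50)
  expect_equal(dmap2$distances[2, 3, 2], 10)
  expect_error(distance_map(label_volume(array(0L, c(3, 3, 3)), c(10, 10, 10))),
               "empty")
})

test_that("distance map equals the brute-force oracle on random volumes", {
  set.seed(19)
  for (trial in 1:10) {
    dm <- sample(4:16, 3, replace = TRUE)
    sp <- sample(c(5, 10, 50), 3, replace = TRUE)
    seeds <- array(0L, dm)
    seeds[sample(prod(dm), max(1, round(prod(dm) * 0.04)))] <- 1L
    got <- distance_map(label_volume(seeds, sp))$distances
    expect_equal(got, brute_force_edt(seeds, sp), tolerance = 1e-9)
  }
})

test_that("contact masks nest with distance and respect the gap", {
  cfg <- scene_config(seed = 2, spacing = c(10, 10, 10), shape = c(60, 60, 80))
  scn <- gen_em_scene(cfg, mito_spec = list(list(center = NULL, radius = 200)),
                      er_spec = list(list(gap = 20, thickness = 60)))
  mlab <- segment_labels_3d(scn$mito$labels > 0, scn$mito$spacing)
  dmap <- distance_map(mlab)
  masks <- lapply(c(10, 20, 30, 40, 50), function(d)
    detect_contacts(scn$er, dmap, d))
  for (m in 1:4) expect_true(all(masks[[m]] <= masks[[m + 1]])) # nesting
  # gap 60: empty at every sweep distance
  scn2 <- gen_em_scene(cfg, mito_spec = list(list(center = NULL, radius = 200)),
                       er_spec = list(list(gap = 60, thickness = 60)))
  dmap2 <- distance_map(segment_labels_3d(scn2$mito$labels > 0, scn2$mito$spacing))
  expect_false(any(detect_contacts(scn2$er, dmap2, 50)))
  # masked voxels lie within the analytic disc radius (+- 1 voxel)
  mask30 <- masks[[3]]
  idx <- which(mask30)
  ijk <- arrayInd(idx, dim(mask30))
  ax_x <- ((ijk[, 2] - 0.5) * 10)
  ax_y <- ((ijk[, 1] - 0.5) * 10)
  c_xy <- c(mean(range(ax_x)), mean(range(ax_y)))
  rad <- sqrt((ax_x - c_xy[1])^2 + (ax_y - c_xy[2])^2)
  expect_lte(max(rad), sqrt(4500) + 10)
})

test_that("patches are assigned to their mitochondrion, ties to smaller id", {
  # two mitochondria, one contact blob near each
  vol <- array(0L, c(30, 30, 10))
  vol[5:8, 5:8, 4:6] <- 1L
  vol[20:23, 20:23, 4:6] <- 1L
  mito <- segment_labels_3d(vol > 0, c(10, 10, 10))
  expect_equal(max(mito$labels), 2L)
  mask <- array(FALSE, dim(vol))
  mask[6:7, 10:11, 5] <- TRUE  # near mito 1
  mask[21:22, 17:18, 5] <- TRUE # near mito 2
  pt <- label_and_assign(mask, mito, search_distance = 30)
  expect_equal(nrow(pt), 2)
  expect_equal(sort(pt$assigned_mito), c(1L, 2L))
  # empty mask: empty list
  expect_equal(nrow(label_and_assign(array(FALSE, dim(vol)), mito)), 0)
  # exactly equidistant blob goes to label 1
  vol2 <- array(0L, c(21, 9, 9))
  vol2[3, 5, 5] <- 1L; vol2[19, 5, 5] <- 1L
  mito2 <- segment_labels_3d(vol2 > 0, c(10, 10, 10))
  mask2 <- array(FALSE, dim(vol2)); mask2[11, 5, 5] <- TRUE
  pt2 <- label_and_assign(mask2, mito2)
  expect_equal(pt2$assigned_mito, 1L)
})

test_that("3D labelling distinguishes separated and diagonal-touching parts", {
  v <- array(FALSE, c(8, 8, 4))
  v[2, 2, 2] <- TRUE; v[3, 3, 3] <- TRUE # diagonal in 3D: one 26-component
  v[7, 7, 2] <- TRUE
  lab <- segment_labels_3d(v, c(10, 10, 10))
  expect_equal(max(lab$labels), 2L)
  expect_equal(lab$labels[2, 2, 2], lab$labels[3, 3, 3])
  expect_equal(max(segment_labels_3d(array(FALSE, c(4, 4, 4)), c(10, 10, 10))$labels), 0L)
})

test_that("patch areas follow the half-mesh rule and scale with spacing", {
  # single voxel: voxel-face fallback, 6 * 100 / 2 = 300 nm^2 at 10 nm
  dm <- c(7L, 7L, 7L)
  v1 <- array(FALSE, dm); v1[4, 4, 4] <- TRUE
  expect_equal(patch_area(which(v1), dm, c(10, 10, 10)), 300)
  # doubling all spacings quadruples the area
  v <- array(FALSE, c(12, 12, 6)); v[3:9, 3:9, 3] <- TRUE
  ii <- which(v)
  a1 <- patch_area(ii, dim(v), c(10, 10, 10))
  a2 <- patch_area(ii, dim(v), c(20, 20, 20))
  expect_equal(a2 / a1, 4, tolerance = 1e-12)
})

test_that("contact tables conserve area and include contact-free mitochondria", {
  cfg <- scene_config(seed = 6, spacing = c(10, 10, 10), shape = c(60, 80, 80))
  scn <- gen_em_scene(cfg,
                      mito_spec = list(list(center = c(300, 250, 300), radius = 150),
                                       list(center = c(650, 250, 250), radius = 100)),
                      er_spec = list(list(gap = 20, thickness = 60, ref_mito = 1)))
  mlab <- segment_labels_3d(scn$mito$labels > 0, scn$mito$spacing)
  ct <- build_contact_table(scn$er, mlab, cell_id = "c1")
  # conservation: per-mito totals match the patch sums at every distance
  for (d in ct$distances) {
    pm <- ct$per_mito[ct$per_mito$search_distance == d, ]
    pp <- ct$patches[ct$patches$search_distance == d, ]
    expect_equal(sum(pm$total_contact_area), sum(pp$area), tolerance = 1e-9)
  }
  # both mitochondria reported at every distance, even with zero contact
  expect_equal(nrow(ct$per_mito), 2 * length(ct$distances))
  expect_true(all(ct$per_mito$mito_surface_area > 0))
  # per-cell mean equals the mean of the per-mito totals
  d50 <- ct$per_mito[ct$per_mito$search_distance == 50, ]
  expect_equal(ct$per_cell$mean_contact_area[ct$per_cell$search_distance == 50],
               mean(d50$total_contact_area))
  # per-mito totals are non-decreasing in d
  for (m in unique(ct$per_mito$mito_id)) {
    tot <- ct$per_mito$total_contact_area[ct$per_mito$mito_id == m]
    expect_true(all(diff(tot[order(ct$per_mito$search_distance[ct$per_mito$mito_id == m])]) >= -1e-9))
  }
})
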