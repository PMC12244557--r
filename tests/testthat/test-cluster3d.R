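# Segmentation, surface/contact areas, per-cell statistics, alpha-shape
# surface and density.

test_that("disjoint bright spheres are segmented as separate clusters", {
  sp <- c(0.1, 0.1, 0.1)
  vol <- array(0, dim = c(60, 60, 20))
  ax <- function(n, s) (seq_len(n) - 0.5) * s
  ctrs <- cbind(x = c(1, 3, 5, 1, 3), y = c(1, 1, 1, 4, 4), z = rep(1, 5))
  for (m in 1:5) {
    dd <- sqrt(outer(outer((ax(60, 0.1) - ctrs[m, "y"])^2,
                           (ax(60, 0.1) - ctrs[m, "x"])^2, "+"),
                     (ax(20, 0.1) - ctrs[m, "z"])^2, "+"))
    vol[dd <= 0.25] <- 100
  }
  seg <- segment_clusters(intensity_stack(vol, sp), threshold = 50, min_size = 1)
  expect_equal(nrow(seg$clusters$clusters), 5)
  # centroids recover the placed centres
  got <- seg$clusters$clusters[, c("x", "y", "z")]
  ord <- order(got$x + 100 * got$y)
  want <- ctrs[order(ctrs[, "x"] + 100 * ctrs[, "y"]), ]
  expect_equal(as.numeric(got$x[ord]), as.numeric(want[, "x"]), tolerance = 0.05)
  expect_equal(as.numeric(got$y[ord]), as.numeric(want[, "y"]), tolerance = 0.05)
})

test_that("background-only stacks give an empty cluster set, not an error", {
  stk <- intensity_stack(array(0, dim = c(10, 10, 5)), c(0.1, 0.1, 0.2))
  seg <- segment_clusters(stk, threshold = 0.5)
  expect_equal(nrow(seg$clusters$clusters), 0)
  st <- per_cell_stats(seg$clusters)
  expect_equal(st$n_clusters, 0)
  expect_true(is.na(st$median_contact_area))
  # non-finite input is an error
  bad <- array(0, dim = c(5, 5, 5)); bad[2, 2, 2] <- NaN
  expect_error(segment_clusters(intensity_stack(array(1, c(5, 5, 5)) * NA_real_,
                                                c(0.1, 0.1, 0.1))),
               "finite")
  expect_error(intensity_stack(bad, c(0.1, 0.1, 0.1)), "finite")
})

test_that("voxel-face areas follow the exposed-face count", {
  sp <- c(0.1, 0.1, 0.1)
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_equal(surface_area(label_volume(one, sp), 1, method = "voxel_faces"),
               6 * 0.01)
  cube <- array(0L, c(4, 4, 4)); cube[2:3, 2:3, 2:3] <- 1L
  expect_equal(surface_area(label_volume(cube, sp), 1, method = "voxel_faces"),
               24 * 0.01)
  expect_error(surface_area(label_volume(cube, sp), 7), "absent")
})

test_that("mesh area of digitized spheres converges (<= 5% at r >= 10 voxels)", {
  errs <- vapply(c(5, 10, 15), function(rv) {
    lv <- digitized_ball(rv * 0.1, c(0.1, 0.1, 0.1))
    abs(surface_area(lv, 1, method = "mesh") / (4 * pi * (rv * 0.1)^2) - 1)
  }, numeric(1))
  expect_lt(errs[2], 0.05)
  expect_lt(errs[3], 0.05)
  expect_lt(errs[3], errs[1] + 1e-12) # error shrinks with radius
  # anisotropic spacing (half the z resolution): within 10%
  lv <- digitized_ball(1, c(0.1, 0.1, 0.2))
  expect_lt(abs(surface_area(lv, 1, method = "mesh") / (4 * pi) - 1), 0.10)
  # single-voxel component falls back with a warning
  one <- array(0L, c(3, 3, 3)); one[2, 2, 2] <- 1L
  expect_warning(a <- surface_area(label_volume(one, c(0.1, 0.1, 0.1)), 1,
                                   method = "mesh"),
                 "voxel_faces")
  expect_equal(a, 0.06)
})

test_that("contact area is exactly half the surface area", {
  cfg <- scene_config(seed = 31, noise_sd = 0.2, shape = c(120, 120, 80))
  sim <- gen_clusters_on_cell(cfg, 4, 40, cluster_radius = 0.3, psf_sigma = 0.05)
  seg <- segment_clusters(sim$stack, threshold = 0.5, min_size = 10)
  cl <- seg$clusters$clusters
  expect_gt(nrow(cl), 0)
  expect_equal(cl$contact_area, cl$surface_area / 2, tolerance = 1e-14)
})

test_that("per-cell statistics use the half-surface rule and the median", {
  cl <- data.frame(id = 1:3, x = 0, y = 0, z = 0, voxel_count = 10L,
                   surface_area = c(1, 2, 3),
                   contact_area = c(0.5, 1, 1.5), mean_intensity = 1)
  st <- per_cell_stats(cluster_set(cl))
  expect_equal(st$median_contact_area, 1)
  one <- cl[1, ]; one$surface_area <- 0.8; one$contact_area <- 0.4
  expect_equal(per_cell_stats(cluster_set(one))$median_contact_area, 0.4)
  # the container enforces the half-surface invariant
  badcl <- cl; badcl$contact_area <- badcl$surface_area
  expect_error(cluster_set(badcl), "half|surface_area / 2")
})

test_that("alpha shape reproduces analytic areas and the hull limit", {
  # regular tetrahedron, edge a: surface sqrt(3) a^2
  a <- 2
  pts <- rbind(c(0, 0, 0), c(a, 0, 0), c(a / 2, a * sqrt(3) / 2, 0),
               c(a / 2, a * sqrt(3) / 6, a * sqrt(2 / 3)))
  s <- alpha_shape_surface(pts, alpha = Inf)
  expect_equal(s$area, sqrt(3) * a^2, tolerance = 1e-6)
  # fewer than 4 or coplanar points: geometry errors
  expect_error(alpha_shape_surface(pts[1:3, ]), "geometry")
  flat <- cbind(runif(10), runif(10), 0)
  expect_error(alpha_shape_surface(flat), "geometry|coplanar")
  # alpha = Inf equals the convex hull (brute-force oracle)
  pts2 <- mcsquant:::with_seed_(13, matrix(rnorm(40 * 3), ncol = 3))
  s2 <- alpha_shape_surface(pts2, alpha = Inf)
  expect_equal(s2$area, brute_force_hull_area(pts2), tolerance = 1e-6)
  # 1000 uniform points on a 5 um sphere: within 5% of 4 pi 25
  sph <- mcsquant:::with_seed_(17, mcsquant:::sample_sphere_surface(1000, 5))
  s3 <- alpha_shape_surface(sph, alpha = Inf)
  expect_equal(s3$area, 4 * pi * 25, tolerance = 0.05)
  # a large finite alpha (>= sphere radius) retains the hull-like surface
  s4 <- alpha_shape_surface(sph, alpha = 20)
  expect_equal(s4$area, s3$area, tolerance = 0.02)
  # alpha far below the curvature radius leaves no tetrahedra
  expect_error(alpha_shape_surface(sph, alpha = 0.5), "alpha")
})

test_that("cluster density and coverage follow their definitions", {
  cl <- data.frame(id = 1:100, x = 0, y = 0, z = 0, voxel_count = 10L,
                   surface_area = 1, contact_area = 0.5, mean_intensity = 1)
  set <- cluster_set(cl)
  surf <- structure(list(vertices = NULL, triangles = NULL, area = 400,
                         alpha = Inf), class = "cell_surface")
  expect_equal(cluster_density(set, surf), 0.25)
  expect_equal(coverage_fraction(set, surf), 0.125)
  empty <- cluster_set(cl[0, ])
  expect_equal(cluster_density(empty, surf), 0)
  expect_equal(coverage_fraction(empty, surf), 0)
  surf0 <- structure(list(area = 0), class = "cell_surface")
  expect_error(cluster_density(set, surf0), "division")
  # coverage = density x mean contact area when clusters are equal-sized
  expect_equal(coverage_fraction(set, surf),
               cluster_density(set, surf) * mean(cl$contact_area))
})

test_that("full pipeline recovers cluster count and density", {
  # count: low-noise scene at a density where puncta stay optically
  # separable; detected count within 5%
  cfg <- scene_config(seed = 23, spacing = c(0.1, 0.1, 0.15), noise_sd = 0.1)
  simc <- gen_clusters_on_cell(cfg, cell_radius = 8, n_clusters = 100,
                               cluster_radius = 0.12, intensity = 1,
                               psf_sigma = 0.05)
  segc <- suppressWarnings(segment_clusters(simc$stack, threshold = 0.45,
                                            min_size = 2))
  expect_lt(abs(nrow(segc$clusters$clusters) / 100 - 1), 0.05)
  # density: the 5-um / 100-cluster scene, truth 100/(4 pi 25) = 0.318 um^-2.
  # At this density a few sub-resolution pairs merge, but the convex surface
  # built from fewer points is correspondingly smaller, so density stays
  # within 10%.
  sim <- gen_clusters_on_cell(cfg, cell_radius = 5, n_clusters = 100,
                              cluster_radius = 0.12, intensity = 1,
                              psf_sigma = 0.05)
  seg <- suppressWarnings(segment_clusters(sim$stack, threshold = 0.45,
                                           min_size = 2))
  surf <- alpha_shape_surface(as.matrix(seg$clusters$clusters[, c("x", "y", "z")]),
                              alpha = Inf)
  den <- cluster_density(seg$clusters, surf)
  expect_lt(abs(den / sim$truth$true_density - 1), 0.1)
})
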