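# The generators define the study conditions; their ground truth must be
# exact and their output reproducible bit for bit.

test_that("cluster scenes are deterministic and carry the analytic density", {
  cfg <- scene_config(seed = 42, spacing = c(0.1, 0.1, 0.15), noise_sd = 0.2)
  s1 <- gen_clusters_on_cell(cfg, cell_radius = 3, n_clusters = 20,
                             cluster_radius = 0.2)
  s2 <- gen_clusters_on_cell(cfg, cell_radius = 3, n_clusters = 20,
                             cluster_radius = 0.2)
  expect_identical(s1$stack$values, s2$stack$values)
  expect_identical(s1$truth$true_centers, s2$truth$true_centers)
  # analytic sphere-area density: 100 / (4 pi 25) for a 5 um cell
  s3 <- gen_clusters_on_cell(scene_config(seed = 1, shape = c(120, 120, 80)),
                             cell_radius = 5, n_clusters = 100,
                             cluster_radius = 0.12)
  expect_equal(s3$truth$true_density, 100 / (4 * pi * 25), tolerance = 1e-12)
  expect_equal(s3$truth$true_density, 0.318, tolerance = 0.002)
})

test_that("an empty scene is background plus noise with zero density", {
  cfg <- scene_config(seed = 5, noise_sd = 0, background = 7,
                      shape = c(40, 40, 30))
  s <- gen_clusters_on_cell(cfg, cell_radius = 1, n_clusters = 0)
  expect_true(all(s$stack$values == 7))
  expect_identical(s$truth$true_density, 0)
  cfgn <- scene_config(seed = 5, noise_sd = 0.3, background = 7,
                       shape = c(40, 40, 30))
  sn <- gen_clusters_on_cell(cfgn, cell_radius = 1, n_clusters = 0)
  expect_equal(mean(sn$stack$values), 7, tolerance = 0.01)
  expect_equal(sd(as.numeric(sn$stack$values)), 0.3, tolerance = 0.02)
})

test_that("cluster generation flags misfit geometry and crowded puncta", {
  cfg <- scene_config(seed = 1, shape = c(30, 30, 20))
  expect_error(gen_clusters_on_cell(cfg, cell_radius = 10, n_clusters = 5),
               "geometry")
  cfg2 <- scene_config(seed = 1, shape = c(120, 120, 80))
  expect_warning(gen_clusters_on_cell(cfg2, cell_radius = 2, n_clusters = 400,
                                      cluster_radius = 0.3),
                 "overlap")
})

test_that("sphere-surface sampling is isotropic (small mean resultant)", {
  res <- mcsquant:::with_seed_(77, {
    p <- mcsquant:::sample_sphere_surface(2000, 1)
    sqrt(sum(colMeans(p)^2))
  })
  expect_lt(res, 0.1)
})

test_that("ball-blur rendering profile matches the noncentral-chi-square oracle", {
  # (ball * gaussian)(p) = P(||p + sigma N|| <= R) with N standard trivariate
  # normal, i.e. a noncentral chi-square tail: an exact independent oracle
  R <- 0.25; sig <- 0.06
  dd <- c(1e-6, 0.05, 0.15, 0.25, 0.32, 0.5)
  ana <- mcsquant:::ball_blur_profile(dd, R, sig)
  orc <- pchisq((R / sig)^2, df = 3, ncp = (dd / sig)^2)
  expect_equal(ana, orc, tolerance = 1e-7)
})

test_that("two-channel truth fractions follow the shared/only counts", {
  cfg <- scene_config(seed = 9, shape = c(100, 100, 70))
  tc <- gen_two_channel_clusters(cfg, n_shared = 10, n_only_a = 0, n_only_b = 0,
                                 cell_radius = 3)
  expect_equal(tc$truth$true_fraction_a, 1)
  expect_equal(tc$truth$true_fraction_b, 1)
  tc2 <- gen_two_channel_clusters(cfg, n_shared = 5, n_only_a = 5, n_only_b = 0,
                                  cell_radius = 3)
  expect_equal(tc2$truth$true_fraction_a, 0.5)
  expect_equal(tc2$truth$true_fraction_b, 1)
  tc3 <- gen_two_channel_clusters(cfg, n_shared = 0, n_only_a = 4, n_only_b = 4,
                                  cell_radius = 3)
  expect_equal(tc3$truth$true_fraction_a, 0)
  expect_equal(tc3$truth$true_fraction_b, 0)
})

test_that("EM scene truth implements the sphere-plane oracle", {
  cfg <- scene_config(seed = 2, spacing = c(10, 10, 10), shape = c(60, 60, 80))
  scn <- gen_em_scene(cfg, mito_spec = list(list(center = NULL, radius = 200)),
                      er_spec = list(list(gap = 20, thickness = 60)))
  tr <- scn$truth$true_contact_area_by_distance
  expect_equal(tr[["30"]], pi * (230^2 - 220^2)) # pi * 4500
  expect_equal(tr[["30"]], 14137, tolerance = 1e-4)
  expect_equal(tr[["10"]], 0)
  expect_equal(tr[["20"]], 0) # d = g boundary: zero true area
  expect_true(all(diff(tr[order(as.numeric(names(tr)))]) >= 0))
  # gap beyond the sweep: all-zero truth
  scn2 <- gen_em_scene(cfg, mito_spec = list(list(center = NULL, radius = 200)),
                       er_spec = list(list(gap = 60, thickness = 60)))
  expect_true(all(scn2$truth$true_contact_area_by_distance == 0))
  # overlapping labels rejected
  expect_error(gen_em_scene(cfg,
                            mito_spec = list(list(center = NULL, radius = 200)),
                            er_spec = list(list(gap = -30, thickness = 60))),
               "overlap|geometry")
})

test_that("profile generator realizes the rounded fraction exactly", {
  p <- gen_profile(100, 0.25, noise_sd = 0, seed = 3)
  expect_equal(p$truth$true_fraction_above, 0.25)
  p2 <- gen_profile(64, 1.0, noise_sd = 0, seed = 3)
  expect_equal(p2$truth$true_fraction_above, 1.0)
  # round-half-even contract: 0.5 * 101 = 50.5 -> 50
  p3 <- gen_profile(101, 0.5, noise_sd = 0, seed = 3)
  expect_equal(p3$truth$n_above, 50L)
  expect_equal(p3$truth$true_fraction_above, 50 / 101)
})

test_that("track generator moves spots at the configured speed", {
  g <- gen_tracks(5, 10, frame_interval = 5, speed = 0.02, seed = 8)
  d <- g$spots
  one <- d[d$spot_id == 3, ]
  steps <- sqrt(diff(one$x_um)^2 + diff(one$y_um)^2)
  expect_equal(steps, rep(0.1, 9), tolerance = 1e-10)
  g0 <- gen_tracks(4, 6, speed = 0, seed = 8)
  expect_equal(sd(g0$spots$x_um[g0$spots$spot_id == 1]), 0)
  g2 <- gen_tracks(5, 10, frame_interval = 5, speed = 0.02, seed = 8)
  expect_identical(g$spots, g2$spots)
})
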