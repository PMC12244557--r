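# Cross-channel cluster matching and the paired/group statistics.

seg_from_labels <- function(lab, sp = c(0.1, 0.1, 0.1)) {
  lv <- label_volume(lab, sp, unit = "um")
  ids <- sort(setdiff(unique(as.integer(lab)), 0L))
  cl <- do.call(rbind, lapply(ids, function(id) {
    ijk <- arrayInd(which(lab == id), dim(lab))
    data.frame(id = id, x = mean((ijk[, 2] - 0.5) * sp[2]),
               y = mean((ijk[, 1] - 0.5) * sp[1]),
               z = mean((ijk[, 3] - 0.5) * sp[3]),
               voxel_count = nrow(ijk), surface_area = 1,
               contact_area = 0.5, mean_intensity = 1)
  }))
  if (is.null(cl)) cl <- data.frame(id = integer(0), x = numeric(0),
                                    y = numeric(0), z = numeric(0),
                                    voxel_count = integer(0),
                                    surface_area = numeric(0),
                                    contact_area = numeric(0),
                                    mean_intensity = numeric(0))
  list(labels = lv, clusters = cluster_set(cl))
}

test_that("identical channels match fully, disjoint ones not at all", {
  lab <- array(0L, c(10, 10, 4))
  lab[2:3, 2:3, 2] <- 1L; lab[7:8, 7:8, 3] <- 2L
  a <- seg_from_labels(lab)
  m <- match_clusters(a, a)
  expect_equal(m$fraction_a, 1); expect_equal(m$fraction_b, 1)
  lab2 <- array(0L, c(10, 10, 4)); lab2[5:6, 2:3, 4] <- 1L
  m2 <- match_clusters(a, seg_from_labels(lab2))
  expect_equal(m2$fraction_a, 0); expect_equal(m2$fraction_b, 0)
  m3 <- match_clusters(a, seg_from_labels(lab2), criterion = "centroid",
                       tolerance = 0.05)
  expect_equal(m3$fraction_a, 0)
  # grids must agree
  lab3 <- array(0L, c(9, 10, 4)); lab3[1, 1, 1] <- 1L
  expect_error(match_clusters(a, seg_from_labels(lab3)), "input error")
})

test_that("synthetic two-channel scenes recover the colocalized fractions", {
  cfg <- scene_config(seed = 41, spacing = c(0.1, 0.1, 0.15), noise_sd = 0.15)
  tc <- gen_two_channel_clusters(cfg, n_shared = 5, n_only_a = 5, n_only_b = 0,
                                 cell_radius = 5, cluster_radius = 0.25,
                                 psf_sigma = 0.05)
  sa <- segment_clusters(tc$stack_a, threshold = 0.5, min_size = 5)
  sb <- segment_clusters(tc$stack_b, threshold = 0.5, min_size = 5)
  m <- match_clusters(sa, sb)
  # within one cluster of the construction truth
  expect_lte(abs(m$n_a_matched - 5), 1)
  expect_equal(m$n_b, 5)
  expect_lte(abs(m$n_b_matched - 5), 1)
  expect_equal(m$n_a, 10)
  # centroid criterion agrees for co-centred puncta
  mc <- match_clusters(sa, sb, criterion = "centroid", tolerance = 0.25)
  expect_lte(abs(mc$n_a_matched - 5), 1)
})

test_that("Holm adjustment follows the step-down rule and dominates raw p", {
  out <- paired_prepost_test(list(
    a = list(pre = c(10, 12, 11, 13), post = c(12, 14, 12, 16)),
    b = list(pre = c(5, 6, 7, 8), post = c(5, 7, 7, 9)),
    c = list(pre = c(1, 2, 3, 4), post = c(2, 4, 3, 6))))
  # direct check on the published-rule example
  expect_equal(p.adjust(c(0.01, 0.04, 0.03), "holm"), c(0.03, 0.06, 0.06))
  # Holm dominates Bonferroni and never drops below raw
  expect_true(all(out$p_adj >= out$p_raw))
  expect_true(all(out$p_adj <= pmin(1, length(out$p_raw) * out$p_raw) + 1e-15))
  # family of one: adjusted equals raw
  one <- paired_prepost_test(list(list(pre = c(1, 2, 3), post = c(2, 2, 4))))
  expect_equal(one$p_adj, one$p_raw)
})

test_that("paired t matches the closed-form computation on the toy vectors", {
  pre <- c(1, 2, 3, 4); post <- c(2, 4, 3, 6)
  out <- paired_prepost_test(list(list(pre = pre, post = post)))
  orc <- paired_t_closed_form(pre, post)
  expect_equal(out$t, orc$t, tolerance = 1e-12)
  expect_equal(out$df, orc$df)
  expect_equal(out$p_raw, orc$p, tolerance = 1e-12)
  # degenerate inputs error
  expect_error(paired_prepost_test(list(list(pre = c(1, 2, 3), post = c(1, 2, 3)))),
               "degenerate")
  expect_error(paired_prepost_test(list(list(pre = c(1, 2), post = c(1, 2, 3)))),
               "mismatch")
})

test_that("ANOVA/Tukey handles the degenerate, two-group and separated cases", {
  # three identical groups: F ~ 0, all pairwise p = 1
  g <- group_comparison(rep(c(1, 2, 3), 3), rep(c("a", "b", "c"), each = 3))
  expect_lt(abs(g$anova$F), 1e-10)
  expect_equal(g$tukey$p_adj, rep(1, 3), tolerance = 1e-10)
  # two groups: Tukey p equals the equal-variance t test p
  x <- c(1.1, 2.3, 3.1, 2.2); y <- c(4.3, 5.1, 4.4, 6.0)
  g2 <- group_comparison(c(x, y), rep(c("a", "b"), each = 4))
  tt <- t.test(x, y, var.equal = TRUE)
  expect_equal(g2$tukey$p_adj, tt$p.value, tolerance = 1e-4) # ptukey quadrature

  # strong separation
  g3 <- group_comparison(c(0, 0.1, -0.1, 10, 10.1, 9.9),
                         rep(c("a", "b"), each = 3))
  expect_lt(g3$tukey$p_adj, 0.001)
  expect_error(group_comparison(c(1, 2, 3), c("a", "a", "b")), "input error")
})

test_that("Welch/Student t matches the closed form and is antisymmetric", {
  x <- c(1, 2, 3, 4); y <- c(2, 3, 4, 5)
  w <- welch_or_student_t(x, y, welch = TRUE)
  orc <- welch_t_closed_form(x, y)
  expect_equal(w$t, orc$t, tolerance = 1e-12)
  expect_equal(w$df, orc$df, tolerance = 1e-12)
  expect_equal(w$p, orc$p, tolerance = 1e-12)
  # x = y: t = 0, p = 1
  e <- welch_or_student_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(e$t, 0); expect_equal(e$p, 1)
  # swapping negates t, p unchanged
  w2 <- welch_or_student_t(y, x)
  expect_equal(w2$t, -w$t); expect_equal(w2$p, w$p)
  expect_error(welch_or_student_t(c(1, 1, 1), y), "degenerate")
})
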