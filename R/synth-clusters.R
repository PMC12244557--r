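# Synthetic light-microscopy scenes: diffraction-limited puncta on a cell
# surface, rendered as hard spheres convolved with an isotropic Gaussian
# (closed-form profile; no full PSF model), over a constant background with
# additive Gaussian noise.

#' Scene configuration for the synthetic generators
#'
#' @param seed integer RNG seed; identical seed + parameters give
#'   bit-identical scenes.
#' @param spacing physical voxel spacing `c(y=, x=, z=)`; um for
#'   light-microscopy scenes, nm for EM scenes.
#' @param shape grid dimensions `c(ny, nx, nz)`, or `NULL` to let each
#'   generator fit the grid to its geometry.
#' @param noise_sd additive Gaussian noise sd, intensity units.
#' @param background baseline intensity.
#' @return a `scene_config` list.
#' @export
scene_config <- function(seed = 1L, spacing = c(y = 0.1, x = 0.1, z = 0.15),
                         shape = NULL, noise_sd = 0, background = 0) {
  spacing <- check_spacing(spacing)
  if (!is.null(shape)) {
    if (length(shape) != 3L || any(shape < 1)) stop("'shape' must be 3 dims >= 1")
    shape <- as.integer(shape)
  }
  if (noise_sd < 0) stop("'noise_sd' must be >= 0")
  structure(list(seed = as.integer(seed), spacing = spacing, shape = shape,
                 noise_sd = noise_sd, background = background),
            class = "scene_config")
}

# uniform points on a sphere surface via normalised 3D Gaussian draws
sample_sphere_surface <- function(n, radius) {
  g <- matrix(rnorm(3 * n), ncol = 3)
  g / sqrt(rowSums(g^2)) * radius
}

# add blurred-ball intensity footprints into vol (modified in place semantics
# via return); centers are physical (x, y, z)
render_puncta <- function(vol, spacing, centers, radius, intensity, psf_sigma) {
  d <- dim(vol)
  reach <- radius + 4 * psf_sigma
  ax_y <- axis_coords(d[1], spacing["y"])
  ax_x <- axis_coords(d[2], spacing["x"])
  ax_z <- axis_coords(d[3], spacing["z"])
  for (m in seq_len(nrow(centers))) {
    cx <- centers[m, 1]; cy <- centers[m, 2]; cz <- centers[m, 3]
    iy <- which(abs(ax_y - cy) <= reach)
    ix <- which(abs(ax_x - cx) <= reach)
    iz <- which(abs(ax_z - cz) <= reach)
    if (!length(iy) || !length(ix) || !length(iz)) next
    dy2 <- (ax_y[iy] - cy)^2
    dx2 <- (ax_x[ix] - cx)^2
    dz2 <- (ax_z[iz] - cz)^2
    dd <- sqrt(outer(outer(dy2, dx2, "+"), dz2, "+"))
    vol[iy, ix, iz] <- vol[iy, ix, iz] +
      intensity * ball_blur_profile(dd, radius, psf_sigma)
  }
  vol
}

#' Generate a synthetic cell with surface clusters
#'
#' Places `n_clusters` spherical puncta uniformly on the surface of a sphere
#' of radius `cell_radius` (the idealized cell), renders them as blurred
#' intensity blobs over background, and adds Gaussian noise. The ground truth
#' records the centres and the true surface density
#' `n_clusters / (4 * pi * cell_radius^2)`.
#'
#' @param config a [scene_config()]; spacing in um.
#' @param cell_radius cell radius, um.
#' @param n_clusters number of puncta (>= 0).
#' @param cluster_radius punctum radius, um.
#' @param intensity peak (unblurred) punctum intensity above background.
#' @param psf_sigma isotropic Gaussian blur sd, um; default one in-plane
#'   voxel.
#' @return list with `stack` ([intensity_stack]) and `truth` (ground-truth
#'   record: `true_centers` (x,y,z), `true_density` (um^-2),
#'   `true_surface_area` of the cell, `cluster_radius`,
#'   `true_cluster_surface_area`, `true_median_contact_area`).
#' @export
gen_clusters_on_cell <- function(config, cell_radius, n_clusters,
                                 cluster_radius = 0.3, intensity = 1,
                                 psf_sigma = NULL) {
  stopifnot(inherits(config, "scene_config"), n_clusters >= 0, cell_radius > 0)
  sp <- config$spacing
  psf_sigma <- psf_sigma %||% min(sp)
  margin <- cluster_radius + 4 * psf_sigma + 2 * max(sp)
  shape <- config$shape %||% as.integer(ceiling(2 * (cell_radius + margin) / sp))
  extent <- shape * sp
  if (any(extent < 2 * (cell_radius + cluster_radius))) {
    stop("geometry error: cell plus cluster radius does not fit in the grid")
  }
  if (n_clusters > 0) {
    exp_nn <- 0.5 * sqrt(4 * pi * cell_radius^2 / n_clusters)
    if (exp_nn < 2 * cluster_radius) {
      warning("expected nearest-neighbour spacing (", signif(exp_nn, 3),
              " um) < cluster diameter; puncta will overlap/merge")
    }
  }
  with_seed_(config$seed, {
    center0 <- extent[c("x", "y", "z")] / 2
    centers <- if (n_clusters > 0) {
      sweep(sample_sphere_surface(n_clusters, cell_radius), 2, center0, "+")
    } else matrix(numeric(0), ncol = 3)
    colnames(centers) <- c("x", "y", "z")
    vol <- array(0, dim = shape)
    if (n_clusters > 0) {
      vol <- render_puncta(vol, sp, centers, cluster_radius, intensity, psf_sigma)
    }
    vol <- vol + config$background
    if (config$noise_sd > 0) vol <- vol + rnorm(length(vol), sd = config$noise_sd)
    truth <- structure(list(
      true_centers = centers,
      cell_center = center0,
      cell_radius = cell_radius,
      true_density = n_clusters / (4 * pi * cell_radius^2),
      true_surface_area = 4 * pi * cell_radius^2,
      cluster_radius = cluster_radius,
      true_cluster_surface_area = 4 * pi * cluster_radius^2,
      true_median_contact_area = 2 * pi * cluster_radius^2,
      intensity = intensity, psf_sigma = psf_sigma
    ), class = "ground_truth")
    list(stack = intensity_stack(vol, sp, unit = "um", channel = "green"),
         truth = truth)
  })
}

#' Generate a two-channel scene with partially shared puncta
#'
#' Channel A holds `n_shared + n_only_a` puncta, channel B
#' `n_shared + n_only_b`; shared puncta are co-centred. Distinct centres are
#' placed by rejection sampling with a minimum pairwise separation so that
#' the expected colocalized fraction is exact by construction.
#'
#' @inheritParams gen_clusters_on_cell
#' @param n_shared,n_only_a,n_only_b punctum counts (>= 0).
#' @param min_separation minimum distance between distinct centres, um.
#' @return list with `stack_a`, `stack_b` and `truth` (includes
#'   `true_fraction_a = (n_shared)/(n_shared + n_only_a)` and the B
#'   analogue; `NA` when a channel is empty).
#' @export
gen_two_channel_clusters <- function(config, n_shared, n_only_a, n_only_b,
                                     cell_radius = 5, cluster_radius = 0.2,
                                     intensity = 1, psf_sigma = NULL,
                                     min_separation = NULL) {
  stopifnot(inherits(config, "scene_config"),
            n_shared >= 0, n_only_a >= 0, n_only_b >= 0)
  sp <- config$spacing
  psf_sigma <- psf_sigma %||% min(sp)
  min_separation <- min_separation %||% (2 * cluster_radius + 6 * psf_sigma)
  n_tot <- n_shared + n_only_a + n_only_b
  margin <- cluster_radius + 4 * psf_sigma + 2 * max(sp)
  shape <- config$shape %||% as.integer(ceiling(2 * (cell_radius + margin) / sp))
  extent <- shape * sp
  with_seed_(config$seed, {
    center0 <- extent[c("x", "y", "z")] / 2
    centers <- matrix(numeric(0), ncol = 3)
    tries <- 0L
    while (nrow(centers) < n_tot) {
      cand <- as.numeric(sample_sphere_surface(1, cell_radius)) +
        as.numeric(center0)
      ok <- !nrow(centers) ||
        min(sqrt(colSums((t(centers) - cand)^2))) >= min_separation
      if (ok) centers <- rbind(centers, cand)
      tries <- tries + 1L
      if (tries > 1000L * max(1L, n_tot)) {
        stop("geometry error: cannot place ", n_tot,
             " puncta with separation ", min_separation)
      }
    }
    colnames(centers) <- c("x", "y", "z")
    idx_shared <- seq_len(n_shared)
    idx_a <- c(idx_shared, n_shared + seq_len(n_only_a))
    idx_b <- c(idx_shared, n_shared + n_only_a + seq_len(n_only_b))
    mk <- function(idx, ch) {
      vol <- array(0, dim = shape)
      if (length(idx)) {
        vol <- render_puncta(vol, sp, centers[idx, , drop = FALSE],
                             cluster_radius, intensity, psf_sigma)
      }
      vol <- vol + config$background
      if (config$noise_sd > 0) vol <- vol + rnorm(length(vol), sd = config$noise_sd)
      intensity_stack(vol, sp, unit = "um", channel = ch)
    }
    stack_a <- mk(idx_a, "A")
    stack_b <- mk(idx_b, "B")
    truth <- structure(list(
      true_centers = centers,
      n_shared = n_shared, n_only_a = n_only_a, n_only_b = n_only_b,
      true_fraction_a = if (length(idx_a)) n_shared / length(idx_a) else NA_real_,
      true_fraction_b = if (length(idx_b)) n_shared / length(idx_b) else NA_real_,
      cluster_radius = cluster_radius
    ), class = "ground_truth")
    list(stack_a = stack_a, stack_b = stack_b, truth = truth)
  })
}
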