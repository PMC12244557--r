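# Synthetic EM label scenes: voxelized mitochondria (spheres) and ER (plane
# slabs) with controlled intermembrane gaps, plus the analytic sphere-plane
# contact-area oracle. For a sphere of radius R and a slab whose near face
# lies at gap g from the sphere surface, the true contact area at search
# distance d is pi * ((R + d)^2 - (R + g)^2) for d >= g, else 0.

#' Generate a synthetic EM scene (mitochondria spheres + ER slabs)
#'
#' @param config a [scene_config()]; spacing in nm (e.g. `c(10, 10, 10)`).
#' @param mito_spec list of spheres, each `list(center = c(x, y, z) nm,
#'   radius = nm)`. `center = NULL` centres the sphere in the grid.
#' @param er_spec list of slabs, each `list(gap = nm, thickness = nm,
#'   ref_mito = index)`: a slab normal to +z whose near face sits at
#'   `gap` nm above the surface of the referenced mitochondrion.
#' @param distances search distances for the ground-truth contact table, nm.
#' @return list with `mito` and `er` ([label_volume]s, nm) and `truth`
#'   carrying `true_contact_area_by_distance` (per mito x distance matrix,
#'   nm^2, non-decreasing in distance) and the totals per distance.
#' @export
gen_em_scene <- function(config, mito_spec, er_spec,
                         distances = c(10, 20, 30, 40, 50)) {
  stopifnot(inherits(config, "scene_config"))
  sp <- config$spacing
  shape <- config$shape %||% c(60L, 60L, 80L)
  extent <- shape * sp
  ax_y <- axis_coords(shape[1], sp["y"])
  ax_x <- axis_coords(shape[2], sp["x"])
  ax_z <- axis_coords(shape[3], sp["z"])

  # snap sphere centres to the voxel-centre lattice: distances in the EDT are
  # voxel-centre to voxel-centre, so an off-lattice sphere carries a
  # systematic half-voxel bias into every measured contact distance
  snap <- function(ctr) {
    s <- sp[c("x", "y", "z")]
    (round(ctr / s - 0.5) + 0.5) * s
  }
  mito <- array(0L, dim = shape)
  centers <- list()
  for (m in seq_along(mito_spec)) {
    spec <- mito_spec[[m]]
    ctr <- snap(spec$center %||% (extent[c("x", "y", "z")] / 2))
    R <- spec$radius
    if (any(ctr - R < 0) || any(ctr + R > extent[c("x", "y", "z")])) {
      stop("geometry error: mitochondrion ", m, " does not fit in the grid")
    }
    centers[[m]] <- ctr
    dy2 <- (ax_y - ctr[2])^2
    dx2 <- (ax_x - ctr[1])^2
    dz2 <- (ax_z - ctr[3])^2
    inside <- outer(outer(dy2, dx2, "+"), dz2, "+") <= R^2
    if (any(mito[inside] != 0L)) stop("geometry error: overlapping mitochondria")
    mito[inside] <- m
  }

  er <- array(0L, dim = shape)
  truth_rows <- list()
  for (s in seq_along(er_spec)) {
    spec <- er_spec[[s]]
    ref <- spec$ref_mito %||% 1L
    R <- mito_spec[[ref]]$radius
    ctr <- centers[[ref]]
    z0 <- ctr[3] + R + spec$gap
    z1 <- z0 + (spec$thickness %||% (extent["z"] - z0))
    if (z0 >= extent["z"]) stop("geometry error: ER slab outside the grid")
    inside <- ax_z >= z0 & ax_z <= z1
    er[, , inside] <- 1L
    area <- vapply(distances, function(d) {
      if (d < spec$gap) 0 else pi * ((R + d)^2 - (R + spec$gap)^2)
    }, numeric(1))
    truth_rows[[s]] <- data.frame(mito_id = ref, gap = spec$gap,
                                  distance = distances, true_area = area)
  }
  if (any(er > 0L & mito > 0L)) stop("geometry error: overlapping mito/ER labels")

  truth_df <- do.call(rbind, truth_rows)
  by_d <- vapply(distances, function(d) sum(truth_df$true_area[truth_df$distance == d]),
                 numeric(1))
  names(by_d) <- distances
  truth <- structure(list(
    per_contact = truth_df,
    true_contact_area_by_distance = by_d,
    distances = distances
  ), class = "ground_truth")
  list(mito = label_volume(mito, sp, unit = "nm"),
       er = label_volume(er, sp, unit = "nm"),
       truth = truth)
}
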