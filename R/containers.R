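# Core data containers. Image grids are stored as R arrays with dim
# (ny, nx, nz); physical coordinates are (x, y, z) with the centre of voxel
# [i, j, k] at ((j - 0.5) * sx, (i - 0.5) * sy, (k - 0.5) * sz). Spacing is a
# named vector c(y =, x =, z =) in the declared unit (um for light microscopy,
# nm for EM).

#' Intensity stack
#'
#' A scalar image grid (3D z-stack, a single 2D slice, or a 2D time-lapse
#' frame) with physical voxel spacing.
#'
#' @param values numeric array, dim `(ny, nx)` or `(ny, nx, nz)`; all finite.
#' @param spacing positive numeric vector of physical spacings, one per axis,
#'   named `c(y=, x=, z=)` (the z entry is dropped for 2D data).
#' @param unit length unit, `"um"` or `"nm"`.
#' @param channel optional channel name.
#' @return an object of class `intensity_stack`.
#' @export
intensity_stack <- function(values, spacing, unit = "um", channel = "") {
  if (is.matrix(values)) values <- array(values, dim = c(dim(values), 1L))
  if (length(dim(values)) != 3L) stop("'values' must be a 2D or 3D array")
  if (!all(is.finite(values))) stop("'values' contains non-finite entries")
  spacing <- check_spacing(spacing)
  structure(list(values = values, spacing = spacing, unit = unit,
                 channel = channel),
            class = "intensity_stack")
}

#' Label volume
#'
#' An integer-labelled 3D grid (0 = background) sharing the spacing model of
#' [intensity_stack()].
#'
#' @param labels integer array, dim `(ny, nx, nz)`; non-negative.
#' @param spacing positive numeric vector `c(y=, x=, z=)`.
#' @param unit length unit, `"nm"` for EM volumes, `"um"` for light microscopy.
#' @return an object of class `label_volume`.
#' @export
label_volume <- function(labels, spacing, unit = "nm") {
  if (is.matrix(labels)) labels <- array(labels, dim = c(dim(labels), 1L))
  if (length(dim(labels)) != 3L) stop("'labels' must be a 3D array")
  storage.mode(labels) <- "integer"
  if (anyNA(labels) || min(labels) < 0L) stop("labels must be non-negative integers")
  spacing <- check_spacing(spacing)
  structure(list(labels = labels, spacing = spacing, unit = unit),
            class = "label_volume")
}

check_spacing <- function(spacing) {
  spacing <- as.numeric(spacing)
  if (length(spacing) == 2L) spacing <- c(spacing, spacing[1])
  if (length(spacing) != 3L) stop("'spacing' must have 2 or 3 entries")
  if (!all(is.finite(spacing)) || any(spacing <= 0)) stop("spacings must be > 0")
  names(spacing) <- c("y", "x", "z")
  spacing
}

#' @export
print.intensity_stack <- function(x, ...) {
  d <- dim(x$values)
  cat(sprintf("<intensity_stack> %d x %d x %d voxels, spacing (%s) %s%s\n",
              d[1], d[2], d[3], paste(signif(x$spacing, 4), collapse = ", "),
              x$unit,
              if (nzchar(x$channel)) paste0(", channel '", x$channel, "'") else ""))
  invisible(x)
}

#' @export
print.label_volume <- function(x, ...) {
  d <- dim(x$labels)
  cat(sprintf("<label_volume> %d x %d x %d voxels, %d labels, spacing (%s) %s\n",
              d[1], d[2], d[3], max(x$labels),
              paste(signif(x$spacing, 4), collapse = ", "), x$unit))
  invisible(x)
}

#' Per-cell cluster set
#'
#' A collection of segmented clusters for one cell, with per-cluster surface
#' and contact areas. Contact area is defined as half the cluster surface
#' area (the cluster is a double-membrane apposition; one face touches the
#' partner organelle).
#'
#' @param clusters data.frame with columns `id`, `x`, `y`, `z` (physical
#'   centroid), `voxel_count`, `surface_area`, `contact_area`,
#'   `mean_intensity`.
#' @param cell_id cell identifier.
#' @param stage cell-cycle stage label (`"interphase"`, `"metaphase"`, ...).
#' @param unit length unit of the areas.
#' @return an object of class `cluster_set`.
#' @export
cluster_set <- function(clusters, cell_id = "cell", stage = "interphase",
                        unit = "um") {
  need <- c("id", "x", "y", "z", "voxel_count", "surface_area",
            "contact_area", "mean_intensity")
  if (!all(need %in% names(clusters))) {
    stop("missing cluster columns: ", paste(setdiff(need, names(clusters)), collapse = ", "))
  }
  if (anyDuplicated(clusters$id)) stop("cluster ids must be unique within a cell")
  if (nrow(clusters) &&
      max(abs(clusters$contact_area - clusters$surface_area / 2)) > 1e-12 * max(1, max(clusters$surface_area))) {
    stop("contact_area must equal surface_area / 2")
  }
  structure(list(clusters = clusters, cell_id = cell_id, stage = stage,
                 unit = unit),
            class = "cluster_set")
}

#' @export
print.cluster_set <- function(x, ...) {
  cat(sprintf("<cluster_set> cell '%s' (%s): %d clusters\n",
              x$cell_id, x$stage, nrow(x$clusters)))
  if (nrow(x$clusters)) {
    cat(sprintf("  median contact area %.4g %s^2, median size %d voxels\n",
                median(x$clusters$contact_area), x$unit,
                as.integer(median(x$clusters$voxel_count))))
  }
  invisible(x)
}

n_clusters <- function(set) nrow(set$clusters)
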