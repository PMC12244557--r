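# Alpha-shape approximation of the cell surface from cluster centroids.
# The 3D Delaunay tetrahedralization is computed in compiled code
# (incremental Bowyer-Watson); the alpha complex keeps tetrahedra with
# circumradius <= alpha, and the surface is the set of faces incident to
# exactly one retained tetrahedron. alpha = Inf gives the convex hull.
#
# Points sampled on (or detected near) a smooth closed surface are an
# almost-co-spherical configuration: every local tetrahedron has a
# circumradius close to the radius of curvature of the surface, not to the
# point spacing. The practical default is therefore alpha = Inf (convex
# hull), with finite alpha available for concave cells.

#' Alpha-shape cell surface from 3D points
#'
#' @param points numeric matrix (n x 3) of physical (x, y, z) coordinates;
#'   at least 4 non-coplanar points.
#' @param alpha circumradius cutoff in the same length unit as `points`;
#'   `Inf` (default) gives the convex hull.
#' @return an object of class `cell_surface`: `vertices` (the input points),
#'   `triangles` (m x 3 vertex indices), `area` (sum of triangle areas),
#'   `alpha`, `n_tetrahedra` retained.
#' @export
alpha_shape_surface <- function(points, alpha = Inf) {
  points <- as.matrix(points)
  if (ncol(points) != 3) stop("geometry error: 'points' must be n x 3")
  if (nrow(points) < 4) stop("geometry error: need at least 4 points")
  if (!all(is.finite(points))) stop("geometry error: non-finite coordinates")
  ctr <- colMeans(points)
  pc <- sweep(points, 2, ctr)
  scale <- max(abs(pc), 1e-12)
  ps <- pc / scale
  sv <- svd(ps, nu = 0, nv = 0)$d
  if (sv[3] < 1e-9 * sv[1]) {
    stop("geometry error: points are (near-)coplanar or collinear")
  }
  # symbolic perturbation: co-spherical inputs (the typical case here) make
  # the insphere predicate degenerate; a deterministic jitter far above
  # double rounding error but negligible geometrically resolves it. Escalate
  # and re-audit if the triangulation comes out non-watertight.
  for (jit in c(1e-9, 1e-7, 1e-5)) {
    pj <- ps + jit * vapply(1:3, function(j) hash_noise(seq_len(nrow(ps)), j),
                            numeric(nrow(ps)))
    dl <- tryCatch(cpp_delaunay3d(pj), error = function(e) NULL)
    if (is.null(dl) || nrow(dl$tets) == 0) next
    keep <- dl$circumradius * scale <= alpha
    if (!any(keep)) {
      stop("geometry error: no tetrahedron has circumradius <= alpha = ",
           alpha, " (alpha too small for this point cloud)")
    }
    tets <- dl$tets[keep, , drop = FALSE]
    tri <- boundary_faces(tets)
    if (!is.finite(alpha) && !is_watertight(tri)) next # retry larger jitter
    area <- sum(triangle_areas(points, tri))
    return(structure(list(vertices = points, triangles = tri, area = area,
                          alpha = alpha, n_tetrahedra = nrow(tets)),
                     class = "cell_surface"))
  }
  stop("geometry error: degenerate point configuration (collinear/coplanar?)")
}

# faces incident to exactly one tetrahedron
boundary_faces <- function(tets) {
  fidx <- rbind(c(1, 2, 3), c(1, 2, 4), c(1, 3, 4), c(2, 3, 4))
  faces <- do.call(rbind, lapply(1:4, function(m) tets[, fidx[m, ], drop = FALSE]))
  key <- apply(faces, 1, function(f) paste(sort(f), collapse = "-"))
  tab <- table(key)
  faces[key %in% names(tab)[tab == 1L], , drop = FALSE]
}

triangle_areas <- function(pts, tri) {
  if (!nrow(tri)) return(numeric(0))
  a <- pts[tri[, 1], , drop = FALSE]
  b <- pts[tri[, 2], , drop = FALSE]
  c_ <- pts[tri[, 3], , drop = FALSE]
  u <- b - a; v <- c_ - a
  cr <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
              u[, 3] * v[, 1] - u[, 1] * v[, 3],
              u[, 1] * v[, 2] - u[, 2] * v[, 1])
  0.5 * sqrt(rowSums(cr^2))
}

# every edge of a closed triangulated surface borders exactly two faces
is_watertight <- function(tri) {
  if (!nrow(tri)) return(FALSE)
  e <- rbind(tri[, c(1, 2)], tri[, c(2, 3)], tri[, c(1, 3)])
  e <- t(apply(e, 1, sort))
  key <- paste(e[, 1], e[, 2])
  all(table(key) == 2L)
}

#' @export
print.cell_surface <- function(x, ...) {
  cat(sprintf("<cell_surface> %d vertices, %d boundary triangles, area %.4g (alpha = %s)\n",
              nrow(x$vertices), nrow(x$triangles), x$area,
              if (is.finite(x$alpha)) signif(x$alpha, 4) else "Inf"))
  invisible(x)
}
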