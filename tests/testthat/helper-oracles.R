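# Independent oracles and small fixture builders used across the tests.

# digitized ball as a label_volume (label 1), voxel centres at (i-0.5)*sp
digitized_ball <- function(r, spacing, pad = 4L, unit = "um") {
  spacing <- mcsquant:::check_spacing(spacing)
  n <- as.integer(ceiling(2 * r / spacing)) + 2L * pad
  ctr <- n * spacing / 2
  ax <- function(k) (seq_len(n[k]) - 0.5) * spacing[k] - ctr[k]
  dd <- outer(outer(ax(1)^2, ax(2)^2, "+"), ax(3)^2, "+")
  label_volume(array(as.integer(dd <= r^2), dim = n), spacing, unit = unit)
}

# brute-force all-pairs minimum distance oracle for the EDT (chunked so
# volumes up to 32^3 stay fast)
brute_force_edt <- function(seeds, spacing) {
  dm <- dim(seeds)
  n <- prod(dm)
  pos <- t(t(arrayInd(seq_len(n), dm)) * as.numeric(spacing))
  spos <- pos[which(seeds > 0L), , drop = FALSE]
  s2 <- rowSums(spos^2)
  out <- numeric(n)
  chunk <- 4000L
  for (st in seq(1, n, by = chunk)) {
    en <- min(n, st + chunk - 1L)
    pc <- pos[st:en, , drop = FALSE]
    d2 <- outer(rowSums(pc^2), s2, "+") - 2 * pc %*% t(spos)
    out[st:en] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  array(out, dim = dm)
}

# brute-force convex hull area: keep every triangle with all points on one
# side of its plane (O(n^4); fine for small n)
brute_force_hull_area <- function(pts) {
  n <- nrow(pts)
  area <- 0
  for (i in 1:(n - 2)) for (j in (i + 1):(n - 1)) for (k in (j + 1):n) {
    a <- pts[i, ]; b <- pts[j, ]; c_ <- pts[k, ]
    nrm <- c((b - a)[2] * (c_ - a)[3] - (b - a)[3] * (c_ - a)[2],
             (b - a)[3] * (c_ - a)[1] - (b - a)[1] * (c_ - a)[3],
             (b - a)[1] * (c_ - a)[2] - (b - a)[2] * (c_ - a)[1])
    s <- (pts[-c(i, j, k), , drop = FALSE] %*% nrm) - sum(nrm * a)
    if (all(s <= 1e-9) || all(s >= -1e-9)) {
      area <- area + 0.5 * sqrt(sum(nrm^2))
    }
  }
  area
}

# bare normalized profile_record from a numeric vector
profile_from_values <- function(v) {
  structure(list(arc = seq_along(v) - 1, green = v, red = v,
                 background = c(green = 0, red = 0),
                 max_value = c(green = 1, red = 1),
                 step = 1, closed = TRUE, normalized = TRUE),
            class = "profile_record")
}

# render a spot table frame as an image (Gaussian spots), for detection tests
render_frame <- function(spots_frame, fov = c(20, 20), spacing = c(0.1, 0.1),
                         sigma = 0.15, intensity = 1) {
  ny <- round(fov[2] / spacing[1]); nx <- round(fov[1] / spacing[2])
  img <- matrix(0, ny, nx)
  ax_y <- (seq_len(ny) - 0.5) * spacing[1]
  ax_x <- (seq_len(nx) - 0.5) * spacing[2]
  for (m in seq_len(nrow(spots_frame))) {
    dy2 <- (ax_y - spots_frame$y_um[m])^2
    dx2 <- (ax_x - spots_frame$x_um[m])^2
    img <- img + intensity * exp(-outer(dy2, dx2, "+") / (2 * sigma^2))
  }
  img
}

# paired t statistic from the closed-form definition (independent of t.test)
paired_t_closed_form <- function(pre, post) {
  d <- post - pre
  n <- length(d)
  t <- mean(d) / (sd(d) / sqrt(n))
  list(t = t, df = n - 1, p = 2 * pt(-abs(t), n - 1))
}

# Welch t from the closed-form definition
welch_t_closed_form <- function(x, y) {
  vx <- var(x) / length(x); vy <- var(y) / length(y)
  t <- (mean(x) - mean(y)) / sqrt(vx + vy)
  df <- (vx + vy)^2 / (vx^2 / (length(x) - 1) + vy^2 / (length(y) - 1))
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}
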