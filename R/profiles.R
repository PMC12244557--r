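# Perimeter intensity profiles: sample two channels along a manually drawn
# closed organelle outline, normalize to the image background/maximum, and
# score the MCS fraction as the run-length-encoded fraction of samples above
# a threshold. "Above" is strict (>): ties at the threshold count as below.

#' Sample a two-channel intensity profile along a closed outline
#'
#' Both channels are bilinearly interpolated at equal arc-length steps
#' around the closed polygon (auto-closed when the first and last vertex
#' differ). Per-channel background and maximum are recorded from the images
#' for later normalization.
#'
#' @param green,red 2D numeric matrices (ny x nx), one per channel.
#' @param spacing pixel spacing `c(y=, x=)`, um.
#' @param outline polygon matrix (k x 2) of physical `(x, y)` coordinates,
#'   um; >= 3 vertices.
#' @param step arc-length sampling step, um.
#' @param background per-channel background `c(green=, red=)`; defaults to
#'   the per-image minimum.
#' @return a `profile_record`: `arc`, `green`, `red`, `background`,
#'   `max_value`, `step`.
#' @export
sample_profile <- function(green, red, spacing, outline, step = 0.05,
                           background = NULL) {
  stopifnot(is.matrix(green), is.matrix(red), step > 0)
  if (!identical(dim(green), dim(red))) stop("input error: channel shape mismatch")
  spacing <- check_spacing(spacing)[c("y", "x")]
  outline <- as.matrix(outline)
  if (nrow(outline) < 3) stop("geometry error: outline needs >= 3 vertices")
  if (any(outline[1, ] != outline[nrow(outline), ])) {
    outline <- rbind(outline, outline[1, ])
  }
  seg <- diff(outline)
  seglen <- sqrt(rowSums(seg^2))
  L <- sum(seglen)
  n <- max(1L, floor(L / step))
  s <- (seq_len(n) - 1) * step
  cum <- c(0, cumsum(seglen))
  seg_i <- findInterval(s, cum, rightmost.closed = TRUE)
  seg_i[seg_i > nrow(seg)] <- nrow(seg)
  tt <- (s - cum[seg_i]) / seglen[seg_i]
  pts <- outline[seg_i, , drop = FALSE] + seg[seg_i, , drop = FALSE] * tt
  gv <- bilinear_sample(green, spacing, pts)
  rv <- bilinear_sample(red, spacing, pts)
  bg <- background %||% c(green = min(green), red = min(red))
  mx <- c(green = max(green), red = max(red))
  structure(list(arc = s, green = gv, red = rv, background = bg,
                 max_value = mx, step = step, closed = TRUE,
                 normalized = FALSE),
            class = "profile_record")
}

# bilinear interpolation at physical (x, y); pixel centres at (j-0.5)*sx
bilinear_sample <- function(img, spacing, pts) {
  ny <- nrow(img); nx <- ncol(img)
  fx <- pts[, 1] / spacing["x"] + 0.5 # fractional column index
  fy <- pts[, 2] / spacing["y"] + 0.5
  if (any(fx < 1 | fx > nx | fy < 1 | fy > ny)) {
    stop("geometry error: outline sample outside the image")
  }
  j0 <- pmin(pmax(floor(fx), 1), nx - 1); i0 <- pmin(pmax(floor(fy), 1), ny - 1)
  wx <- fx - j0; wy <- fy - i0
  v00 <- img[cbind(i0, j0)]; v01 <- img[cbind(i0, j0 + 1)]
  v10 <- img[cbind(i0 + 1, j0)]; v11 <- img[cbind(i0 + 1, j0 + 1)]
  as.numeric((1 - wy) * ((1 - wx) * v00 + wx * v01) +
             wy * ((1 - wx) * v10 + wx * v11))
}

#' Normalize a profile to the image background and maximum
#'
#' Maps each channel to `(I - background) / (max - background)`.
#'
#' @param p a `profile_record`.
#' @param clip clip the normalized values to `[0, 1]`.
#' @return the normalized `profile_record`.
#' @export
normalize_profile <- function(p, clip = FALSE) {
  stopifnot(inherits(p, "profile_record"))
  for (ch in c("green", "red")) {
    b <- p$background[[ch]]; m <- p$max_value[[ch]]
    if (!(m > b)) stop("input error: max <= background for channel ", ch)
    v <- (p[[ch]] - b) / (m - b)
    if (clip) v <- pmin(pmax(v, 0), 1)
    p[[ch]] <- v
  }
  p$normalized <- TRUE
  p
}

#' MCS fraction of a perimeter profile
#'
#' Fraction of samples strictly above the threshold, with the above-threshold
#' stretches reported as runs. Because the outline is a closed perimeter,
#' runs touching the start and end of the sample vector are merged across
#' the seam.
#'
#' @param p a normalized `profile_record` (see [normalize_profile()]).
#' @param channel which channel to score.
#' @param threshold threshold on the normalized scale.
#' @return an `mcs_fraction_result`: `fraction`, `runs` (data.frame
#'   `start`, `length`), `threshold`, `n_samples`.
#' @export
mcs_fraction <- function(p, channel = "green", threshold = 0.5) {
  stopifnot(inherits(p, "profile_record"))
  if (!isTRUE(p$normalized)) {
    stop("input error: profile must be normalized first (see normalize_profile)")
  }
  v <- p[[channel]]
  n <- length(v)
  if (!n) stop("input error: empty profile")
  ab <- v > threshold
  r <- rle(ab)
  starts <- cumsum(c(1L, r$lengths))[seq_along(r$lengths)]
  runs <- data.frame(start = starts[r$values], length = r$lengths[r$values])
  # wrap-around: merge a trailing run into a leading run
  if (nrow(runs) >= 2 && ab[1] && ab[n]) {
    last <- nrow(runs)
    runs$start[1] <- runs$start[last]
    runs$length[1] <- runs$length[1] + runs$length[last]
    runs <- runs[-last, , drop = FALSE]
  }
  structure(list(fraction = sum(ab) / n, runs = runs,
                 threshold = threshold, n_samples = n,
                 channel = channel),
            class = "mcs_fraction_result")
}

#' @export
print.mcs_fraction_result <- function(x, ...) {
  cat(sprintf("<mcs_fraction> %.4f of %d samples above %.3g (%d runs)\n",
              x$fraction, x$n_samples, x$threshold, nrow(x$runs)))
  invisible(x)
}

#' Pixelwise Pearson colocalization of two channels
#'
#' @param a,b 2D numeric matrices of identical shape.
#' @param mask optional logical matrix restricting the correlation to a
#'   region (>= 2 pixels; both channels must vary within it).
#' @return Pearson correlation coefficient in `[-1, 1]`.
#' @export
pearson_coloc <- function(a, b, mask = NULL) {
  if (!identical(dim(a), dim(b))) stop("input error: shape mismatch")
  va <- as.numeric(a); vb <- as.numeric(b)
  if (!is.null(mask)) {
    mask <- as.logical(mask)
    va <- va[mask]; vb <- vb[mask]
  }
  if (length(va) < 2) stop("input error: need >= 2 pixels")
  if (sd(va) == 0 || sd(vb) == 0) {
    stop("undefined-correlation error: constant channel within mask")
  }
  cor(va, vb)
}
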