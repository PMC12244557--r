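# Spot detection in time-lapse frames, greedy nearest-neighbour linking,
# the track filters (minimum length and minimum end time, both inclusive),
# and per-frame / per-track mobility statistics.

#' Detect spots in a single 2D frame
#'
#' Connected components (8-connectivity) of the thresholded frame with at
#' least `min_area` physical area.
#'
#' @param frame 2D numeric matrix.
#' @param spacing pixel spacing `c(y=, x=)`, um.
#' @param threshold intensity threshold (strictly above = foreground).
#' @param min_area minimum spot area, um^2.
#' @return data.frame `spot_id`, `x_um`, `y_um`, `area_um2`,
#'   `mean_intensity`, `n_px`.
#' @export
detect_spots_2d <- function(frame, spacing, threshold, min_area = 0) {
  stopifnot(is.matrix(frame))
  spacing <- check_spacing(spacing)[c("y", "x")]
  px_area <- prod(spacing)
  dm <- c(dim(frame), 1L)
  lab <- cpp_label_components(as.logical(frame > threshold), dm, 26L)
  if (!any(lab > 0L)) {
    return(data.frame(spot_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0), n_px = integer(0)))
  }
  idx <- which(lab > 0L)
  g <- lab[idx]
  counts <- tabulate(g)
  keep <- which(counts * px_area >= min_area & counts > 0)
  if (!length(keep)) {
    return(data.frame(spot_id = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_um2 = numeric(0),
                      mean_intensity = numeric(0), n_px = integer(0)))
  }
  ij <- arrayInd(idx, dim(frame))
  v <- frame[idx]
  rows <- lapply(seq_along(keep), function(m) {
    id <- keep[m]
    sel <- g == id
    w <- v[sel]
    data.frame(spot_id = m,
               x_um = sum(w * (ij[sel, 2] - 0.5) * spacing["x"]) / sum(w),
               y_um = sum(w * (ij[sel, 1] - 0.5) * spacing["y"]) / sum(w),
               area_um2 = counts[id] * px_area,
               mean_intensity = mean(w), n_px = counts[id])
  })
  do.call(rbind, rows)
}

#' Link per-frame spots into tracks
#'
#' Greedy nearest-neighbour frame-to-frame linking: closest
#' (track, spot) pairs are linked first, links longer than `max_disp` are
#' refused, distance ties are broken toward the smaller spot id, and every
#' unlinked spot starts a new track. No gap closing, splitting or merging.
#'
#' @param spots data.frame with columns `frame`, `t_s`, `spot_id`, `x_um`,
#'   `y_um` and optionally `intensity` / `area_um2` (as from [gen_tracks()]
#'   or repeated [detect_spots_2d()] calls).
#' @param max_disp maximum frame-to-frame displacement, um.
#' @return a `tracks` data.frame (`track_id`, `frame`, `t_s`, `x_um`,
#'   `y_um`, plus carried columns).
#' @export
link_tracks <- function(spots, max_disp = 0.5) {
  stopifnot(all(c("frame", "t_s", "spot_id", "x_um", "y_um") %in% names(spots)))
  frames <- sort(unique(spots$frame))
  spots$track_id <- NA_integer_
  next_track <- 0L
  prev <- NULL # data.frame of last point per active track
  out <- list()
  for (f in frames) {
    cur <- spots[spots$frame == f, , drop = FALSE]
    cur <- cur[order(cur$spot_id), , drop = FALSE]
    if (!is.null(prev) && nrow(prev) && nrow(cur)) {
      dx <- outer(prev$x_um, cur$x_um, "-")
      dy <- outer(prev$y_um, cur$y_um, "-")
      dist <- sqrt(dx^2 + dy^2)
      dist[dist > max_disp] <- NA
      repeat {
        if (all(is.na(dist))) break
        m <- which(dist == min(dist, na.rm = TRUE), arr.ind = TRUE)
        # ties: smaller spot id (column), then smaller track row
        m <- m[order(m[, 2], m[, 1]), , drop = FALSE][1, , drop = FALSE]
        pi_ <- m[1, 1]; ci <- m[1, 2]
        cur$track_id[ci] <- prev$track_id[pi_]
        dist[pi_, ] <- NA
        dist[, ci] <- NA
      }
    }
    new <- is.na(cur$track_id)
    if (any(new)) {
      cur$track_id[new] <- next_track + seq_len(sum(new))
      next_track <- next_track + sum(new)
    }
    out[[length(out) + 1L]] <- cur
    prev <- cur
  }
  res <- do.call(rbind, out)
  res <- res[order(res$track_id, res$frame), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("tracks", "data.frame")
  res
}

#' Filter tracks by length and end time
#'
#' Retains tracks with at least `min_frames` points AND an end time of at
#' least `min_end_time` seconds (both inclusive).
#'
#' @param tracks a `tracks` data.frame from [link_tracks()].
#' @param min_frames minimum number of frames.
#' @param min_end_time minimum track end time, s.
#' @return the filtered `tracks` data.frame.
#' @export
filter_tracks <- function(tracks, min_frames = 4, min_end_time = 100) {
  if (!nrow(tracks)) return(tracks)
  n_by <- tapply(tracks$frame, tracks$track_id, length)
  end_by <- tapply(tracks$t_s, tracks$track_id, max)
  keep <- as.integer(names(n_by))[n_by >= min_frames & end_by >= min_end_time]
  out <- tracks[tracks$track_id %in% keep, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- class(tracks)
  out
}

#' Per-frame and per-track mobility statistics
#'
#' Speeds are per-step displacements divided by the time step; each track
#' is summarized by its median step speed and the cell-level mobility is
#' the median over tracks (single-point tracks carry no speed and are
#' excluded from the speed summary).
#'
#' @param tracks a `tracks` data.frame.
#' @return list with `per_frame` (data.frame `frame`, `n`, `mean_area`,
#'   `mean_intensity`), `per_track` (data.frame `track_id`, `n_frames`,
#'   `end_time`, `median_speed`), and `median_speed` (cell-level, um/s).
#' @export
track_stats <- function(tracks) {
  if (!nrow(tracks)) {
    return(list(per_frame = data.frame(frame = integer(0), n = integer(0),
                                       mean_area = numeric(0),
                                       mean_intensity = numeric(0)),
                per_track = data.frame(track_id = integer(0),
                                       n_frames = integer(0),
                                       end_time = numeric(0),
                                       median_speed = numeric(0)),
                median_speed = NA_real_))
  }
  per_frame <- do.call(rbind, lapply(split(tracks, tracks$frame), function(d) {
    data.frame(frame = d$frame[1], n = nrow(d),
               mean_area = if ("area_um2" %in% names(d)) mean(d$area_um2) else NA_real_,
               mean_intensity = if ("intensity" %in% names(d)) mean(d$intensity)
                                else if ("mean_intensity" %in% names(d)) mean(d$mean_intensity)
                                else NA_real_)
  }))
  rownames(per_frame) <- NULL
  per_track <- do.call(rbind, lapply(split(tracks, tracks$track_id), function(d) {
    d <- d[order(d$frame), , drop = FALSE]
    sp <- if (nrow(d) >= 2) {
      steps <- sqrt(diff(d$x_um)^2 + diff(d$y_um)^2) / diff(d$t_s)
      median(steps)
    } else NA_real_
    data.frame(track_id = d$track_id[1], n_frames = nrow(d),
               end_time = max(d$t_s), median_speed = sp)
  }))
  rownames(per_track) <- NULL
  list(per_frame = per_frame, per_track = per_track,
       median_speed = median(per_track$median_speed, na.rm = TRUE))
}
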