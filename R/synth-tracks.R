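# Synthetic time-lapse spot movement: each track takes a step of
# speed * frame_interval in a uniformly random direction every frame.

#' Generate synthetic moving spots
#'
#' @param n_tracks number of tracks.
#' @param n_frames frames per track (>= 1).
#' @param frame_interval seconds between frames (> 0).
#' @param speed true speed, um/s (per-frame displacement is
#'   `speed * frame_interval`).
#' @param seed RNG seed.
#' @param fov field of view `c(width, height)`, um; starting positions are
#'   uniform in the central half so tracks stay in view.
#' @return list with `spots` (data.frame `frame`, `t_s`, `spot_id`, `x_um`,
#'   `y_um`, `intensity`, `area_um2`) and `truth` (`true_speed`).
#' @export
gen_tracks <- function(n_tracks, n_frames, frame_interval = 5, speed = 0.02,
                       seed = 1L, fov = c(20, 20)) {
  stopifnot(n_frames >= 1, frame_interval > 0, speed >= 0, n_tracks >= 0)
  step <- speed * frame_interval
  with_seed_(seed, {
    x <- runif(n_tracks, fov[1] * 0.25, fov[1] * 0.75)
    y <- runif(n_tracks, fov[2] * 0.25, fov[2] * 0.75)
    rows <- vector("list", n_frames)
    for (f in seq_len(n_frames)) {
      if (f > 1 && n_tracks > 0) {
        ang <- runif(n_tracks, 0, 2 * pi)
        x <- pmin(pmax(x + step * cos(ang), 0), fov[1])
        y <- pmin(pmax(y + step * sin(ang), 0), fov[2])
      }
      rows[[f]] <- data.frame(frame = f, t_s = (f - 1) * frame_interval,
                              spot_id = seq_len(n_tracks),
                              x_um = x, y_um = y,
                              intensity = 1, area_um2 = 0.25)
    }
    list(spots = do.call(rbind, rows),
         truth = structure(list(true_speed = speed,
                                frame_interval = frame_interval),
                           class = "ground_truth"))
  })
}
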