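# Synthetic perimeter profiles: a closed two-channel intensity profile whose
# noiseless green channel exceeds the threshold on an exactly controlled
# number of samples (round-half-even), possibly split into several runs and
# wrapping across the seam.

#' Generate a synthetic closed perimeter profile
#'
#' The noiseless green values exceed `threshold` on exactly
#' `round(fraction_above * n_samples)` samples (banker's rounding), split
#' into `n_runs` contiguous stretches placed at a seeded random rotation
#' around the closed profile (so runs may wrap across the seam). The red
#' channel carries a constant organelle-marker level.
#'
#' @param n_samples number of samples along the closed profile (>= 1).
#' @param fraction_above target above-threshold fraction in `[0, 1]`.
#' @param threshold threshold on the normalized scale.
#' @param noise_sd additive Gaussian noise sd (normalized units).
#' @param seed RNG seed.
#' @param n_runs number of above-threshold stretches to split the target
#'   count into (capped by the count itself).
#' @param perimeter physical perimeter length, um.
#' @return list with `profile` (a `profile_record`) and `truth`
#'   (`true_fraction_above` = exact realized fraction of the noiseless
#'   profile).
#' @export
gen_profile <- function(n_samples, fraction_above, threshold = 0.5,
                        noise_sd = 0, seed = 1L, n_runs = 2L,
                        perimeter = 10) {
  stopifnot(n_samples >= 1, fraction_above >= 0, fraction_above <= 1)
  k <- round(fraction_above * n_samples) # round-half-even
  with_seed_(seed, {
    above <- rep(FALSE, n_samples)
    if (k > 0) {
      n_below <- n_samples - k
      nr <- max(1L, min(n_runs, k, n_below)) # each extra run needs a separator
      sizes <- diff(round(seq(0, k, length.out = nr + 1L)))
      sizes <- sizes[sizes > 0]
      gap <- if (length(sizes) > 1L) n_below %/% length(sizes) else 0L
      pos <- 1L
      for (sz in sizes) {
        above[pos - 1L + seq_len(sz)] <- TRUE
        pos <- pos + sz + max(1L, gap)
      }
      # random rotation so runs can wrap across the seam
      rot <- sample.int(n_samples, 1L) - 1L
      above <- above[((seq_len(n_samples) - 1L + rot) %% n_samples) + 1L]
    }
    lo <- threshold * 0.5
    hi <- threshold + (1 - threshold) * 0.6
    green_norm <- ifelse(above, hi, lo)
    if (noise_sd > 0) green_norm <- green_norm + rnorm(n_samples, sd = noise_sd)
    background <- c(green = 10, red = 12)
    maxv <- c(green = 210, red = 240)
    green <- background["green"] + green_norm * (maxv["green"] - background["green"])
    red <- background["red"] + (0.8 + if (noise_sd > 0) rnorm(n_samples, sd = noise_sd) else 0) *
      (maxv["red"] - background["red"])
    arc <- (seq_len(n_samples) - 1) / n_samples * perimeter
    prof <- structure(list(arc = arc, green = as.numeric(green),
                           red = as.numeric(red),
                           background = background, max_value = maxv,
                           step = perimeter / n_samples, closed = TRUE,
                           normalized = FALSE),
                      class = "profile_record")
    truth <- structure(list(true_fraction_above = k / n_samples,
                            n_above = k),
                       class = "ground_truth")
    list(profile = prof, truth = truth)
  })
}
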