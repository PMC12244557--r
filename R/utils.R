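# misc internal helpers

# run expr with a fixed RNG seed, restoring the caller's RNG state
with_seed_ <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# physical voxel-centre coordinates along each axis
axis_coords <- function(n, step) (seq_len(n) - 0.5) * step

# Otsu threshold from a 256-bin histogram (maximises between-class variance)
otsu_threshold <- function(values) {
  v <- as.numeric(values)
  rng <- range(v)
  if (diff(rng) == 0) stop("cannot threshold a constant image")
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((v - rng[1]) / diff(rng) * nb)), nbins = nb)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  w0 <- cumsum(p)
  mu <- cumsum(p * mids)
  mu_t <- mu[nb]
  between <- (mu_t * w0 - mu)^2 / (w0 * (1 - w0))
  between[!is.finite(between)] <- -Inf
  mids[which.max(between)]
}

# Intensity profile of a solid ball of radius R convolved with an isotropic
# Gaussian of sd sigma, evaluated at distance d from the centre (closed form).
ball_blur_profile <- function(d, R, sigma) {
  if (sigma <= 0) return(as.numeric(d <= R))
  d <- pmax(d, 1e-12)
  s2 <- sigma * sqrt(2)
  a <- 0.5 * (erf_((R - d) / s2) + erf_((R + d) / s2))
  b <- sigma / (d * sqrt(2 * pi)) *
    (exp(-(R - d)^2 / (2 * sigma^2)) - exp(-(R + d)^2 / (2 * sigma^2)))
  a - b
}

erf_ <- function(x) 2 * pnorm(x * sqrt(2)) - 1

# deterministic pseudo-noise in [-1, 1], a pure function of the inputs (used
# for symbolic perturbation where consuming RNG state would hurt
# reproducibility)
hash_noise <- function(i, j) {
  x <- sin(i * 12.9898 + j * 78.233) * 43758.5453
  2 * (x - floor(x)) - 1
}

`%||%` <- function(a, b) if (is.null(a)) b else a
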