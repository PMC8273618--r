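# Shared fixtures, generated in code at test time.

# small, fast 2D phantom spec used across tests
small_phantom_spec <- function(seed = 1, ...) {
  args <- list(shape = c(64, 96), base_thickness_px = 16, amplitude_px = 4,
               spatial_period_px = 48, interface_roughness_px = 0.5,
               cartilage_depth_px = 18, noise_sd = 0.03,
               void_density_per_1000px = 0.2, void_radius_px_range = c(1, 2),
               seed = seed)
  args[names(list(...))] <- list(...)
  do.call(phantom_spec, args)
}

# random blob-like binary matrix (smoothed noise, thresholded) with a density
# guard; degenerates to Bernoulli noise when smooth = 0
random_mask_2d <- function(h, w, p = 0.5, smooth = 0) {
  z <- matrix(stats::rnorm(h * w), h, w)
  if (smooth > 0) {
    k <- rep(1, 2 * smooth + 1) / (2 * smooth + 1)
    z <- apply(z, 2, function(col) stats::filter(col, k, circular = TRUE))
    z <- t(apply(z, 1, function(row) stats::filter(row, k, circular = TRUE)))
  }
  (z > stats::quantile(z, 1 - p)) * 1
}

random_mask_3d <- function(d, p = 0.3) {
  array(as.numeric(stats::runif(prod(d)) < p), dim = d)
}

# a deterministic fake model: probability = smoothed intensity band indicator
fake_band_model <- function(lo = 0.4, hi = 0.7) {
  function(tile) {
    p <- ifelse(tile >= lo & tile <= hi, 0.95, 0.05)
    matrix(p, nrow(tile), ncol(tile))
  }
}

constant_model <- function(c) function(tile) matrix(c, nrow(tile), ncol(tile))
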