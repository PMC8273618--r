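#' Specification of a synthetic osteochondral phantom
#'
#' The phantom emulates the three-phase appearance of an osteochondral image:
#' dark articular cartilage on top, an intermediate-intensity calcified
#' cartilage (CC) band of prescribed, laterally varying thickness, and bright
#' trabecular-like bone below. Small dark chondrocyte-like voids are placed
#' fully inside the CC band, and additive Gaussian noise is applied last.
#'
#' The local band thickness along the lateral position x (and y in 3D) is
#' `base + amplitude * sin(2*pi*x/period)` (times `sin(2*pi*y/period)` in 3D,
#' a separable sinusoid), plus smoothed zero-mean roughness noise.
#'
#' @param shape Grid dimensions: `c(rows, cols)` in 2D or
#'   `c(slices, rows, cols)` in 3D (axes slice, row, column).
#' @param base_thickness_px Mean CC band thickness in pixels.
#' @param amplitude_px Sinusoidal thickness modulation amplitude (pixels).
#' @param spatial_period_px Lateral period of the modulation (pixels).
#' @param interface_roughness_px SD of the smoothed roughness added to the
#'   thickness field (pixels).
#' @param intensity_means Means of the three phases,
#'   `c(cartilage, cc, bone)`, strictly increasing, in `[0, 1]`.
#' @param noise_sd SD of the additive Gaussian intensity noise.
#' @param void_density_per_1000px Expected chondrocyte-like voids per 1000
#'   pixels (2D) or voxels (3D) of CC band.
#' @param void_radius_px_range `c(min, max)` void radius in pixels.
#' @param cartilage_depth_px Rows of articular cartilage above the tidemark.
#' @param tidemark_amplitude_px Gentle undulation of the tidemark itself.
#' @param seed Integer seed; the sample is a deterministic function of
#'   (spec, seed).
#' @return An object of class `cc_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(128, 192),
                         base_thickness_px = 32,
                         amplitude_px = 8,
                         spatial_period_px = 128,
                         interface_roughness_px = 1,
                         intensity_means = c(0.25, 0.55, 0.85),
                         noise_sd = 0.04,
                         void_density_per_1000px = 0.15,
                         void_radius_px_range = c(2, 4),
                         cartilage_depth_px = 40,
                         tidemark_amplitude_px = 2,
                         seed = 1L) {
  if (!length(shape) %in% c(2L, 3L)) stop_ccm("shape must have 2 or 3 dims")
  if (base_thickness_px - amplitude_px < 2) {
    stop_ccm("base_thickness_px - amplitude_px must be >= 2 (band never vanishes)")
  }
  if (amplitude_px < 0 || interface_roughness_px < 0 || noise_sd < 0 ||
      void_density_per_1000px < 0 || spatial_period_px <= 0) {
    stop_ccm("negative rate/amplitude parameters are not allowed")
  }
  if (!(intensity_means[1] < intensity_means[2] &&
        intensity_means[2] < intensity_means[3])) {
    stop_ccm("intensity means must satisfy cartilage < cc < bone strictly")
  }
  if (any(intensity_means < 0) || any(intensity_means > 1)) {
    stop_ccm("intensity means must lie in [0, 1]")
  }
  if (diff(void_radius_px_range) < 0) stop_ccm("void radius range must be ordered")
  structure(as.list(environment()), class = "cc_phantom_spec")
}

# Smoothed zero-mean roughness field of a given SD (moving-average of white
# noise, rescaled). Returns zeros when sd == 0 without consuming RNG draws
# differently (draws happen regardless so geometry stays comparable).
roughness_field <- function(n, sd_px, window = 9L) {
  z <- stats::rnorm(n)
  if (sd_px == 0) return(rep(0, n))
  k <- rep(1 / window, window)
  zs <- stats::filter(c(rev(z[seq_len(window)]), z, rev(z[n + 1 - seq_len(window)])),
                      k, sides = 2)
  zs <- as.numeric(zs)[window + seq_len(n)]
  zs <- zs - mean(zs)
  s <- stats::sd(zs)
  if (s == 0) return(rep(0, n))
  zs / s * sd_px
}

# Bone speckle: multiplicative texture from smoothed binary noise, making the
# CC/bone boundary a gradient rather than a clean step.
bone_speckle <- function(d, strength = 0.25) {
  z <- array(stats::runif(prod(d)) > 0.5, dim = d) * 1
  k <- 2L
  zp <- pad_reflect(z, k)
  acc <- array(0, dim = dim(zp))
  cnt <- 0L
  offs <- expand.grid(lapply(seq_along(d), function(i) -k:k))
  for (i in seq_len(nrow(offs))) {
    o <- as.integer(offs[i, ])
    s <- zp
    for (ax in seq_along(d)) s <- shift_array(s, ax, o[ax], fill = 0.5)
    acc <- acc + s
    cnt <- cnt + 1L
  }
  sm <- crop_pad(acc / cnt, k, d)
  1 + strength * (sm - 0.5) * 2
}

#' Generate a 2D osteochondral phantom
#'
#' @param spec A [phantom_spec()] with a 2D `shape`.
#' @param meta [grid_metadata()] attached to the generated image and mask.
#' @return A list of class `cc_phantom` with fields `image` ([image2d()]),
#'   `truth_mask` ([binary_mask()]), `thickness_field_px` (per-column band
#'   thickness) and `spec`.
#' @export
#' @examples
#' ph <- generate_phantom_2d(phantom_spec(shape = c(64, 96), seed = 7))
#' range(colSums(ph$truth_mask$values))
generate_phantom_2d <- function(spec, meta = grid_metadata(modality = "histology")) {
  if (length(spec$shape) != 2) stop_ccm("generate_phantom_2d needs a 2D shape")
  set.seed(spec$seed)
  H <- spec$shape[1]; W <- spec$shape[2]
  x <- seq_len(W)
  thick <- spec$base_thickness_px +
    spec$amplitude_px * sin(2 * pi * x / spec$spatial_period_px) +
    roughness_field(W, spec$interface_roughness_px)
  tide <- spec$cartilage_depth_px +
    spec$tidemark_amplitude_px * sin(2 * pi * x / (2 * spec$spatial_period_px))
  if (any(tide + thick > H - 2)) {
    stop_ccm("band does not fit the image: increase rows or reduce thickness")
  }
  rows <- matrix(seq_len(H), H, W)
  tide_m <- matrix(tide, H, W, byrow = TRUE)
  thick_m <- matrix(thick, H, W, byrow = TRUE)
  in_band <- (rows >= tide_m) & (rows < tide_m + thick_m)
  below <- rows >= tide_m + thick_m

  img <- matrix(spec$intensity_means[1], H, W)
  img[in_band] <- spec$intensity_means[2]
  bone <- spec$intensity_means[3] * bone_speckle(c(H, W))
  img[below] <- bone[below]

  img <- add_voids_2d(img, in_band, spec)
  if (spec$noise_sd > 0) {
    img <- img + matrix(stats::rnorm(H * W, 0, spec$noise_sd), H, W)
  }
  img <- pmin(pmax(img, 0), 1)
  list2phantom(image2d(img, meta), binary_mask(in_band * 1, meta), thick, spec)
}

add_voids_2d <- function(img, in_band, spec) {
  H <- nrow(img); W <- ncol(img)
  area <- sum(in_band)
  n_void <- stats::rpois(1, spec$void_density_per_1000px * area / 1000)
  if (n_void == 0) return(img)
  # distance from band boundary: a void must fit fully inside the band
  d_in <- sqedt(in_band * 1)
  for (v in seq_len(n_void)) {
    r <- stats::runif(1, spec$void_radius_px_range[1], spec$void_radius_px_range[2])
    ok <- which(d_in > (r + 1)^2, arr.ind = TRUE)
    if (nrow(ok) == 0) next
    c0 <- ok[sample.int(nrow(ok), 1), ]
    rr <- ceiling(r)
    ri <- max(1, c0[1] - rr):min(H, c0[1] + rr)
    ci <- max(1, c0[2] - rr):min(W, c0[2] + rr)
    dd <- outer((ri - c0[1])^2, (ci - c0[2])^2, `+`)
    sel <- dd <= r^2
    sub <- img[ri, ci]
    sub[sel] <- spec$intensity_means[1] * 0.8
    img[ri, ci] <- sub
  }
  img
}

#' Generate a 3D osteochondral phantom
#'
#' As [generate_phantom_2d()] but the thickness field is a separable sinusoid
#' over the two lateral axes (row of slices x columns), voids are balls, and
#' the truth mask is a 3D band. Axes are (slice, row, column); the band runs
#' along the row axis (depth).
#'
#' @param spec A [phantom_spec()] with a 3D `shape` `c(slices, rows, cols)`.
#' @param meta [grid_metadata()] for the volume.
#' @return A `cc_phantom` with `image` ([image_volume()]), `truth_mask`
#'   (3D [binary_mask()]) and `thickness_field_px` (slices x cols matrix).
#' @export
generate_phantom_3d <- function(spec, meta = grid_metadata(modality = "microct")) {
  if (length(spec$shape) != 3) stop_ccm("generate_phantom_3d needs a 3D shape")
  set.seed(spec$seed)
  S <- spec$shape[1]; H <- spec$shape[2]; W <- spec$shape[3]
  xs <- seq_len(S); xw <- seq_len(W)
  thick <- spec$base_thickness_px +
    spec$amplitude_px * outer(sin(2 * pi * xs / spec$spatial_period_px),
                              sin(2 * pi * xw / spec$spatial_period_px)) +
    matrix(roughness_field(S * W, spec$interface_roughness_px), S, W)
  tide <- spec$cartilage_depth_px +
    spec$tidemark_amplitude_px *
      outer(sin(pi * xs / spec$spatial_period_px),
            sin(pi * xw / spec$spatial_period_px))
  if (any(tide + thick > H - 2)) {
    stop_ccm("band does not fit the volume: increase rows or reduce thickness")
  }
  vol <- array(spec$intensity_means[1], dim = c(S, H, W))
  in_band <- array(FALSE, dim = c(S, H, W))
  below <- array(FALSE, dim = c(S, H, W))
  rowsv <- array(rep(seq_len(H), each = S), dim = c(S, H, W))
  tide_v <- array(rep(tide, times = H), dim = c(S, W, H))
  tide_v <- aperm(tide_v, c(1, 3, 2))
  thick_v <- aperm(array(rep(thick, times = H), dim = c(S, W, H)), c(1, 3, 2))
  in_band <- (rowsv >= tide_v) & (rowsv < tide_v + thick_v)
  below <- rowsv >= tide_v + thick_v
  vol[in_band] <- spec$intensity_means[2]
  bone <- spec$intensity_means[3] * bone_speckle(c(S, H, W))
  vol[below] <- bone[below]
  vol <- add_voids_3d(vol, in_band, spec)
  if (spec$noise_sd > 0) {
    vol <- vol + array(stats::rnorm(S * H * W, 0, spec$noise_sd), dim = c(S, H, W))
  }
  vol <- pmin(pmax(vol, 0), 1)
  list2phantom(image_volume(vol, meta), binary_mask(in_band * 1, meta), thick, spec)
}

add_voids_3d <- function(vol, in_band, spec) {
  d <- dim(vol)
  n_void <- stats::rpois(1, spec$void_density_per_1000px * sum(in_band) / 1000)
  if (n_void == 0) return(vol)
  d_in <- sqedt(in_band * 1)
  for (v in seq_len(n_void)) {
    r <- stats::runif(1, spec$void_radius_px_range[1], spec$void_radius_px_range[2])
    ok <- which(d_in > (r + 1)^2, arr.ind = TRUE)
    if (nrow(ok) == 0) next
    c0 <- ok[sample.int(nrow(ok), 1), ]
    rr <- ceiling(r)
    ix <- lapply(1:3, function(a) max(1, c0[a] - rr):min(d[a], c0[a] + rr))
    dd <- outer(outer((ix[[1]] - c0[1])^2, (ix[[2]] - c0[2])^2, `+`),
                (ix[[3]] - c0[3])^2, `+`)
    sel <- dd <= r^2
    sub <- vol[ix[[1]], ix[[2]], ix[[3]], drop = FALSE]
    sub[sel] <- spec$intensity_means[1] * 0.8
    vol[ix[[1]], ix[[2]], ix[[3]]] <- sub
  }
  vol
}

list2phantom <- function(image, truth_mask, thickness_field_px, spec) {
  structure(list(image = image, truth_mask = truth_mask,
                 thickness_field_px = thickness_field_px, spec = spec),
            class = "cc_phantom")
}

#' Prescribed mean CC thickness of a phantom, in micrometres
#'
#' The analytic ground truth: the mean of the phantom's thickness field
#' multiplied by the physical pixel size.
#'
#' @param sample A `cc_phantom` from [generate_phantom_2d()] /
#'   [generate_phantom_3d()].
#' @param meta Optional [grid_metadata()]; defaults to the sample image's.
#' @return Mean prescribed thickness in um.
#' @export
prescribed_mean_thickness_um <- function(sample, meta = NULL) {
  tf <- sample$thickness_field_px
  if (is.null(tf) || length(tf) == 0) stop_ccm("phantom has no thickness field")
  meta <- meta %||% sample$image$meta
  mean(tf) * meta$pixel_size_um
}
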