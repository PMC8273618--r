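test_that("phantom spec validation rejects degenerate bands and bad phases", {
  expect_error(phantom_spec(base_thickness_px = 5, amplitude_px = 4), "never vanishes")
  expect_error(phantom_spec(intensity_means = c(0.5, 0.4, 0.9)), "strictly")
  expect_error(phantom_spec(noise_sd = -0.1), "negative")
})

test_that("a degenerate flat spec yields an exact horizontal slab", {
  sp <- phantom_spec(shape = c(64, 96), base_thickness_px = 20, amplitude_px = 0,
                     interface_roughness_px = 0, noise_sd = 0,
                     void_density_per_1000px = 0, tidemark_amplitude_px = 0,
                     cartilage_depth_px = 16)
  ph <- generate_phantom_2d(sp)
  expect_true(all(colSums(ph$truth_mask$values) == 20))
  # noise-free phases have disjoint intensity values outside the bone speckle
  in_band <- ph$truth_mask$values == 1
  expect_true(all(ph$image$intensities[in_band] == sp$intensity_means[2]))
})

test_that("truth mask vertical extent follows the prescribed sinusoid", {
  sp <- phantom_spec(shape = c(96, 256), base_thickness_px = 20, amplitude_px = 8,
                     spatial_period_px = 128, interface_roughness_px = 0,
                     cartilage_depth_px = 30, seed = 4)
  ph <- generate_phantom_2d(sp)
  x <- seq_len(256)
  expected <- 20 + 8 * sin(2 * pi * x / 128)
  expect_true(all(abs(colSums(ph$truth_mask$values) - round(expected)) <= 1))
})

test_that("phantoms are bit-identical under the same spec and seed", {
  a <- generate_phantom_2d(small_phantom_spec(seed = 7))
  b <- generate_phantom_2d(small_phantom_spec(seed = 7))
  expect_identical(a$image$intensities, b$image$intensities)
  expect_identical(a$truth_mask$values, b$truth_mask$values)
  s3 <- phantom_spec(shape = c(24, 48, 24), base_thickness_px = 12,
                     amplitude_px = 2, cartilage_depth_px = 10,
                     spatial_period_px = 24, seed = 5)
  expect_identical(generate_phantom_3d(s3)$image$intensities,
                   generate_phantom_3d(s3)$image$intensities)
})

test_that("seeds change the noise but not the deterministic geometry", {
  mk <- function(seed) generate_phantom_2d(
    small_phantom_spec(seed = seed, interface_roughness_px = 0,
                       void_density_per_1000px = 0))
  a <- mk(1); b <- mk(2)
  expect_identical(a$truth_mask$values, b$truth_mask$values)
  expect_identical(a$thickness_field_px, b$thickness_field_px)
  expect_false(identical(a$image$intensities, b$image$intensities))
})

test_that("3D thickness field mean equals the base over whole periods", {
  sp <- phantom_spec(shape = c(32, 64, 32), base_thickness_px = 16,
                     amplitude_px = 4, spatial_period_px = 32,
                     cartilage_depth_px = 12, seed = 2)
  ph <- generate_phantom_3d(sp)
  expect_lt(abs(mean(ph$thickness_field_px) - 16) / 16, 0.02)
  # ground-truth consistency: per-(slice, column) extent tracks the field
  extent <- apply(ph$truth_mask$values, c(1, 3), sum)
  expect_true(all(abs(extent - round(ph$thickness_field_px)) <= 1))
})

test_that("prescribed mean thickness converts pixels to micrometres", {
  flat <- generate_phantom_2d(phantom_spec(
    shape = c(40, 64), base_thickness_px = 10, amplitude_px = 0,
    interface_roughness_px = 0, tidemark_amplitude_px = 0,
    void_density_per_1000px = 0, cartilage_depth_px = 12))
  expect_equal(prescribed_mean_thickness_um(flat, grid_metadata(3.2, "microct")), 32)
  sine <- generate_phantom_2d(phantom_spec(
    shape = c(72, 128), base_thickness_px = 20, amplitude_px = 6,
    spatial_period_px = 64, interface_roughness_px = 0,
    cartilage_depth_px = 24))
  expect_equal(prescribed_mean_thickness_um(sine, grid_metadata(2.56, "histology")),
               51.2, tolerance = 1e-12)
  bad <- flat; bad$thickness_field_px <- numeric(0)
  expect_error(prescribed_mean_thickness_um(bad), "thickness field")
})
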