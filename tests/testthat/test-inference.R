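test_that("tiling covers the canonical deployment geometry with 9 tiles", {
  img <- matrix(0.5, 1024, 2048)
  tl <- tile_image(img, tile_spec())
  expect_equal(nrow(tl$origins), 9)
  expect_setequal(unique(tl$origins[, 1]), c(1, 257, 513))
  expect_setequal(unique(tl$origins[, 2]), c(1, 513, 1025))
  expect_equal(tl$pad, c(0L, 0L))
})

test_that("an image equal to the window yields a single tile at the origin", {
  img <- matrix(0.2, 64, 96)
  tl <- tile_image(img, tile_spec(c(64, 96), c(32, 48)))
  expect_equal(nrow(tl$origins), 1)
  expect_equal(unname(tl$origins[1, ]), c(1, 1))
  expect_identical(tl$tiles[[1]], img)
})

test_that("tile footprints cover every pixel for random shapes", {
  set.seed(17)
  for (i in 1:20) {
    h <- sample(10:150, 1); w <- sample(10:150, 1)
    ts <- tile_spec(c(32, 48), c(sample(8:32, 1), sample(8:48, 1)))
    tl <- tile_image(matrix(0, h, w), ts)
    cov <- matrix(0, tl$padded_dim[1], tl$padded_dim[2])
    for (j in seq_len(nrow(tl$origins))) {
      ri <- tl$origins[j, 1] + 0:31; ci <- tl$origins[j, 2] + 0:47
      cov[ri, ci] <- cov[ri, ci] + 1
    }
    expect_true(all(cov >= 1))
    expect_true(all(tl$origins >= 1))
  }
})

test_that("stitching averages overlaps uniformly", {
  ts <- tile_spec(c(4, 4), c(2, 2))
  tl <- tile_image(matrix(0, 6, 6), ts)
  # constant tiles stitch to a constant map
  preds <- lapply(tl$tiles, function(t) matrix(0.7, 4, 4))
  expect_true(all(stitch_tiles(preds, tl$origins, tl$padded_dim) == 0.7))
  # two overlapping tiles with values a and b average to (a+b)/2
  or2 <- rbind(c(1, 1), c(1, 3))
  s <- stitch_tiles(list(matrix(0.2, 4, 4), matrix(0.6, 4, 4)), or2, c(4, 6))
  expect_true(all(s[, 3:4] == 0.4))
  expect_true(all(s[, 1:2] == 0.2))
  expect_true(all(s[, 5:6] == 0.6))
})

test_that("a deterministic tile-wise model stitches without seams", {
  img <- matrix(0.37, 200, 300)
  cfg <- inference_config(tiles = tile_spec(c(64, 64), c(32, 32)))
  pm <- predict_2d(img, list(fake_band_model(0.3, 0.5)), cfg)
  expect_lt(diff(range(pm$values)), 1e-6)
  expect_equal(dim(pm$values), dim(img))
})

test_that("fold ensembling is a uniform convex combination", {
  img <- matrix(0.5, 96, 96)
  cfg <- inference_config(tiles = tile_spec(c(48, 48), c(24, 24)))
  one <- predict_2d(img, list(constant_model(0.2)), cfg)
  expect_true(all(abs(one$values - 0.2) < 1e-12))
  two <- predict_2d(img, list(constant_model(0.2), constant_model(0.6)), cfg)
  expect_true(all(abs(two$values - 0.4) < 1e-12))
  set.seed(3)
  ms <- list(function(t) matrix(stats::runif(length(t)), nrow(t)),
             function(t) matrix(stats::runif(length(t), 0.3, 0.9), nrow(t)))
  em <- predict_2d(matrix(0.5, 64, 64),
                   ms, inference_config(tiles = tile_spec(c(64, 64), c(64, 64))))
  expect_true(all(em$values >= 0 & em$values <= 1))
})

test_that("images smaller than the window are reflect-padded and cropped back", {
  img <- matrix(stats::runif(20 * 30), 20, 30)
  cfg <- inference_config(tiles = tile_spec(c(64, 64), c(32, 32)))
  pm <- predict_2d(img, list(fake_band_model(0, 1)), cfg)
  expect_equal(dim(pm$values), c(20, 30))
})

test_that("volume prediction reduces to slice-wise 2D and planes average linearly", {
  set.seed(19)
  vol <- array(stats::runif(8 * 16 * 16), dim = c(8, 16, 16))
  mdl <- fake_band_model(0.2, 0.8)
  ts <- tile_spec(c(16, 16), c(16, 16))
  cor_only <- predict_volume(vol, list(mdl),
                             inference_config(tiles = ts, planes = "coronal"))
  sag_only <- predict_volume(vol, list(mdl),
                             inference_config(tiles = ts, planes = "sagittal"))
  both <- predict_volume(vol, list(mdl),
                         inference_config(tiles = ts,
                                          planes = c("coronal", "sagittal")))
  expect_equal(both$values, (cor_only$values + sag_only$values) / 2,
               tolerance = 1e-9)
  # single coronal plane equals direct slice-wise 2D prediction
  manual <- array(0, dim = dim(vol))
  for (r in seq_len(dim(vol)[2])) {
    sl <- vol[, r, ]; dim(sl) <- dim(vol)[c(1, 3)]
    manual[, r, ] <- predict_2d(sl, list(mdl), inference_config(tiles = ts))$values
  }
  expect_equal(cor_only$values, manual, tolerance = 1e-12)
  # constant-output model gives a constant volume
  cm <- predict_volume(vol, list(constant_model(0.55)),
                       inference_config(tiles = ts))
  expect_true(all(abs(cm$values - 0.55) < 1e-12))
})

test_that("thresholding uses the inclusive rule and is monotone in t", {
  expect_equal(sum(threshold_probability(matrix(0.79, 5, 5), 0.8)), 0)
  expect_equal(sum(threshold_probability(matrix(0.80, 5, 5), 0.8)), 25)
  set.seed(23)
  m <- matrix(stats::runif(400), 20, 20)
  m1 <- threshold_probability(m, 0.5)
  m2 <- threshold_probability(m, 0.8)
  expect_true(all(m2 <= m1))  # nested masks
  expect_error(threshold_probability(m, 1.2), "\\(0, 1\\)")
})

test_that("partition tiling (step = window) covers each pixel exactly once", {
  ts <- tile_spec(c(16, 16), c(16, 16))
  tl <- tile_image(matrix(seq_len(48 * 64) / (48 * 64), 48, 64), ts)
  cov <- matrix(0, tl$padded_dim[1], tl$padded_dim[2])
  for (j in seq_len(nrow(tl$origins))) {
    cov[tl$origins[j, 1] + 0:15, tl$origins[j, 2] + 0:15] <-
      cov[tl$origins[j, 1] + 0:15, tl$origins[j, 2] + 0:15] + 1
  }
  expect_true(all(cov == 1))
  # stitching then equals plain concatenation of the tiles
  st <- stitch_tiles(tl$tiles, tl$origins, tl$padded_dim)
  expect_identical(st, matrix(seq_len(48 * 64) / (48 * 64), 48, 64))
})
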