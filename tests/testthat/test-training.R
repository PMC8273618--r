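test_that("subject splitting deals round-robin and pigeonholes exactly", {
  f4 <- split_by_subject(sprintf("R%02d", 1:4), 4, seed = 1)
  expect_equal(as.integer(table(unclass(f4))), rep(1L, 4))
  f12 <- split_by_subject(sprintf("R%02d", 1:12), 4, seed = 2)
  expect_equal(as.integer(table(unclass(f12))), rep(3L, 4))
  expect_error(split_by_subject(c("a", "b"), 4), "at least 4")
})

test_that("fold assignment is deterministic and leakage-free", {
  subj <- sprintf("R%02d", 1:9)
  a <- split_by_subject(subj, 4, seed = 5)
  b <- split_by_subject(subj, 4, seed = 5)
  expect_identical(a, b)
  # every subject appears exactly once: train/validation subject sets are
  # disjoint for every fold by construction
  expect_setequal(names(a), subj)
  for (k in 1:4) {
    val <- names(a)[unclass(a) == k]
    trn <- names(a)[unclass(a) != k]
    expect_length(intersect(val, trn), 0)
  }
})

test_that("grouped splitting never leaks a subject across fold sides (random draws)", {
  set.seed(99)
  for (i in 1:200) {
    ns <- sample(4:20, 1)
    subj <- paste0("S", sample(1000, ns))
    nf <- sample(2:min(ns, 6), 1)
    f <- split_by_subject(subj, nf, seed = sample(10000, 1))
    expect_setequal(names(f), subj)
    expect_true(all(table(unclass(f)) >= 1))
    # samples inherit their subject's single fold; two records of the same
    # subject can never fall on opposite sides
    expect_true(all(!duplicated(names(f))))
  }
})

test_that("disabled augmentation is the identity and flips are involutions", {
  set.seed(11)
  img <- matrix(stats::runif(48 * 48), 48, 48)
  msk <- matrix(stats::rbinom(48 * 48, 1, 0.3), 48, 48)
  off <- augmentation_config(enabled = FALSE)
  out <- augment_pair(img, msk, off)
  expect_identical(out$image, img)
  expect_identical(out$mask, msk)
  flip_only <- augmentation_config(hflip_p = 1, vflip_p = 0, rotation_deg = 0,
                                   scale_jitter = 0, brightness = 0,
                                   contrast = 0, gamma_range = c(1, 1),
                                   noise_sd_max = 0)
  once <- augment_pair(img, msk, flip_only, seed = 1)
  twice <- augment_pair(once$image, once$mask, flip_only, seed = 1)
  expect_identical(twice$image, img)
  expect_identical(twice$mask, msk)
})

test_that("right-angle rotation of a mask is exactly invertible", {
  set.seed(12)
  msk <- matrix(stats::rbinom(40 * 40, 1, 0.4), 40, 40)
  img <- matrix(stats::runif(40 * 40), 40, 40)
  r90 <- ccmorph:::warp_pair(img, msk, 90, 1)
  back <- ccmorph:::warp_pair(r90$image, r90$mask, -90, 1)
  expect_identical(back$mask, msk)
})

test_that("geometric transforms keep masks binary and photometric ones leave them untouched", {
  set.seed(13)
  img <- matrix(stats::runif(40 * 40), 40, 40)
  msk <- matrix(stats::rbinom(40 * 40, 1, 0.3), 40, 40)
  cfg <- augmentation_config()
  for (i in 1:10) {
    out <- augment_pair(img, msk, cfg)
    expect_true(all(out$mask %in% c(0, 1)))
    expect_true(all(out$image >= 0 & out$image <= 1))
    expect_equal(dim(out$image), dim(img))
  }
  photo <- augmentation_config(hflip_p = 0, vflip_p = 0, rotation_deg = 0,
                               scale_jitter = 0)
  out <- augment_pair(img, msk, photo, seed = 3)
  expect_identical(out$mask, msk)
  expect_false(identical(out$image, img))
})

test_that("a one-epoch CV run returns a model and Dice per fold", {
  phantoms <- lapply(1:4, function(i) generate_phantom_2d(small_phantom_spec(seed = i)))
  names(phantoms) <- paste0("S", 1:4)
  recs <- sample_records(names(phantoms), names(phantoms),
                         lapply(phantoms, function(p) p$image),
                         lapply(phantoms, function(p) p$truth_mask))
  folds <- split_by_subject(recs, 4, seed = 1)
  tcfg <- train_config(n_folds = 4, epochs = 1, batch_size = 2,
                       tile_shape = c(32, 32), seed = 1,
                       augmentation = augmentation_config(enabled = FALSE),
                       model = model_config(encoder = "small", base_channels = 4,
                                            spatial_dropout_rate = 0))
  cv <- train_cv(recs, folds, tcfg)
  expect_length(cv$models, 4)
  expect_length(cv$oof_dice, 4)
  expect_true(all(cv$oof_dice >= 0 & cv$oof_dice <= 1))
  expect_true(all(vapply(cv$loss_curves, length, integer(1)) == 1))
})

test_that("identical config and seed reproduce fold assignment and epoch losses", {
  phantoms <- lapply(1:4, function(i) generate_phantom_2d(small_phantom_spec(seed = i)))
  names(phantoms) <- paste0("S", 1:4)
  recs <- sample_records(names(phantoms), names(phantoms),
                         lapply(phantoms, function(p) p$image),
                         lapply(phantoms, function(p) p$truth_mask))
  folds1 <- split_by_subject(recs, 2, seed = 3)
  folds2 <- split_by_subject(recs, 2, seed = 3)
  expect_identical(folds1, folds2)
  tcfg <- train_config(n_folds = 2, epochs = 2, batch_size = 2,
                       tile_shape = c(32, 32), seed = 7,
                       augmentation = augmentation_config(enabled = FALSE),
                       model = model_config(encoder = "small", base_channels = 2,
                                            spatial_dropout_rate = 0))
  cv1 <- train_cv(recs, folds1, tcfg)
  cv2 <- train_cv(recs, folds2, tcfg)
  expect_identical(cv1$loss_curves, cv2$loss_curves)
  expect_identical(cv1$oof_dice, cv2$oof_dice)
})

test_that("training loss trends downward after smoothing on separable phantoms", {
  phantoms <- lapply(1:4, function(i) generate_phantom_2d(small_phantom_spec(seed = 20 + i)))
  names(phantoms) <- paste0("S", 1:4)
  recs <- sample_records(names(phantoms), names(phantoms),
                         lapply(phantoms, function(p) p$image),
                         lapply(phantoms, function(p) p$truth_mask))
  folds <- split_by_subject(recs, 2, seed = 1)
  tcfg <- train_config(n_folds = 2, epochs = 12, batch_size = 2,
                       crops_per_image = 2, tile_shape = c(32, 32), seed = 2,
                       augmentation = augmentation_config(enabled = FALSE),
                       model = model_config(encoder = "small", base_channels = 4,
                                            spatial_dropout_rate = 0))
  cv <- train_cv(recs, folds, tcfg)
  for (curve in cv$loss_curves) {
    sm <- stats::filter(curve, rep(1 / 5, 5), sides = 2)
    sm <- sm[!is.na(sm)]
    expect_lt(sm[length(sm)], sm[1])          # net decline
    expect_lt(max(diff(sm)), 0.25 * (sm[1] - sm[length(sm)]) + 1e-8)
  }
})
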