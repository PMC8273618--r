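test_that("untrained models map tiles to same-shaped probability maps", {
  mdl <- build_model(model_config(encoder = "small", base_channels = 4,
                                  spatial_dropout_rate = 0), seed = 1)
  set.seed(1)
  p <- predict_tile(mdl, matrix(stats::runif(64 * 64), 64, 64))
  expect_equal(dim(p), c(64, 64))
  expect_true(all(p >= 0 & p <= 1))
})

test_that("pyramid decoder restores input resolution after final upsampling", {
  for (nrm in c("batch", "instance")) {
    mdl <- build_model(model_config(encoder = "resnet18", decoder = "pyramid",
                                    normalization = nrm, base_channels = 4),
                       seed = 2)
    p <- predict_tile(mdl, matrix(0.5, 32, 48))
    expect_equal(dim(p), c(32, 48))
    expect_true(all(p >= 0 & p <= 1))
  }
})

test_that("tile sides not divisible by the downsampling factor are rejected by name", {
  mdl <- build_model(model_config(encoder = "small", base_channels = 4), seed = 1)
  expect_error(predict_tile(mdl, matrix(0.5, 60, 64)), "8")
})

test_that("small encoder runs forward and backward on a 64x64 tile quickly", {
  mdl <- build_model(model_config(encoder = "small", base_channels = 8,
                                  spatial_dropout_rate = 0), seed = 1)
  x <- array(stats::runif(64 * 64), dim = c(64, 64, 1, 1))
  t <- array(stats::rbinom(64 * 64, 1, 0.3), dim = c(64, 64, 1, 1))
  el <- system.time({
    fw <- ccmorph:::net_forward(mdl, x, train = TRUE)
    g <- ccmorph:::tape_backward(fw$tape, fw$logit_id,
                                 ccmorph:::combined_loss_logit_grad(fw$prob, t, loss_config()),
                                 mdl$params)
  })["elapsed"]
  expect_lt(el, 5)
  expect_true(all(c("enc1.b1.conv", "out") %in% names(g)))
})

test_that("soft Jaccard matches its closed forms", {
  t1 <- matrix(1, 10, 10)
  expect_equal(soft_jaccard(t1, t1), 1, tolerance = 1e-6)
  expect_equal(soft_jaccard(matrix(0.5, 10, 10), t1), 0.5, tolerance = 1e-6)
  z <- matrix(0, 5, 5)
  expect_equal(soft_jaccard(z, z), 1)  # empty-empty agreement via eps
  expect_error(soft_jaccard(matrix(0.5, 2, 2), matrix(1, 2, 3)), "shape")
})

test_that("soft Jaccard equals the hard Jaccard on binary inputs and is symmetric", {
  set.seed(5)
  for (i in 1:10) {
    a <- matrix(stats::rbinom(100, 1, 0.4), 10, 10)
    b <- matrix(stats::rbinom(100, 1, 0.4), 10, 10)
    inter <- sum(a * b); uni <- sum(pmax(a, b))
    hard <- if (uni == 0) 1 else inter / uni
    expect_equal(soft_jaccard(a, b), hard, tolerance = 1e-5)
    expect_equal(soft_jaccard(a, b), soft_jaccard(b, a))
  }
})

test_that("combined loss matches its closed form and perfect-prediction limit", {
  t1 <- matrix(1, 8, 8)
  # constant 0.5 vs all ones at 1:1 weights: -ln(0.5) + (1 - 0.5)
  expect_equal(combined_loss(matrix(0.5, 8, 8), t1), -log(0.5) + 0.5,
               tolerance = 1e-6)
  expect_equal(combined_loss(matrix(0.5, 8, 8), t1), 1.19315, tolerance = 1e-4)
  near <- matrix(1 - 1e-7, 8, 8)
  expect_lt(combined_loss(near, t1), 1e-5)
  expect_error(combined_loss(matrix(NaN, 2, 2), matrix(1, 2, 2)), "finite")
})

test_that("loss decreases when any prediction moves towards its target", {
  set.seed(6)
  lc <- loss_config()
  for (i in 1:20) {
    p <- matrix(stats::runif(36, 0.05, 0.95), 6, 6)
    t <- matrix(stats::rbinom(36, 1, 0.5), 6, 6)
    j <- sample(36, 1)
    p2 <- p
    p2[j] <- p[j] + 0.01 * (t[j] - p[j])  # step towards the target
    expect_lte(combined_loss(p2, t, lc), combined_loss(p, t, lc))
  }
})

test_that("analytic gradients match numeric differentiation on both decoders", {
  set.seed(10)
  x <- array(stats::runif(16 * 16 * 2), dim = c(16, 16, 1, 2))
  t <- array(stats::rbinom(16 * 16 * 2, 1, 0.4), dim = c(16, 16, 1, 2))
  lc <- loss_config()
  soften <- function(m) {
    # keep logits mid-range so the clamped loss has no flat zones
    m$params[["out"]]$W <- m$params[["out"]]$W * 0.05
    m$params[["out"]]$b <- m$params[["out"]]$b * 0
    m
  }
  lossfun <- function(m, params) {
    m$params <- params
    combined_loss(ccmorph:::net_forward(m, x, train = TRUE)$prob, t, lc)
  }
  configs <- list(
    list(cfg = model_config(encoder = "small", decoder = "full_resolution_skip",
                            normalization = "batch", base_channels = 2,
                            spatial_dropout_rate = 0),
         pnames = c("enc1.b1.conv", "dec2.conv", "out", "enc3.b1.norm")),
    list(cfg = model_config(encoder = "resnet18", decoder = "pyramid",
                            normalization = "instance", base_channels = 2,
                            spatial_dropout_rate = 0),
         pnames = c("enc1.b1.conv1", "enc1.b1.proj", "lat2", "head3", "out"))
  )
  for (cc in configs) {
    m <- soften(build_model(cc$cfg, seed = 3))
    fw <- ccmorph:::net_forward(m, x, train = TRUE)
    g <- ccmorph:::tape_backward(
      fw$tape, fw$logit_id,
      ccmorph:::combined_loss_logit_grad(fw$prob, t, lc), m$params)
    for (pn in cc$pnames) {
      f <- names(m$params[[pn]])[1]
      i <- sample(length(m$params[[pn]][[f]]), 1)
      eps <- 1e-5
      pp <- m$params; pp[[pn]][[f]][i] <- pp[[pn]][[f]][i] + eps
      pm <- m$params; pm[[pn]][[f]][i] <- pm[[pn]][[f]][i] - eps
      num <- (lossfun(m, pp) - lossfun(m, pm)) / (2 * eps)
      expect_equal(g[[pn]][[f]][i], num, tolerance = 1e-4,
                   label = sprintf("grad %s.%s", pn, f))
    }
  }
})

test_that("checkpoints round-trip through disk with their config sidecar", {
  dir <- withr::local_tempdir()
  mdl <- build_model(model_config(encoder = "small", base_channels = 4), seed = 9)
  path <- file.path(dir, "fold1.ckpt")
  save_checkpoint(mdl, path)
  expect_true(file.exists(paste0(path, ".json")))
  back <- load_checkpoint(path)
  tile <- matrix(stats::runif(32 * 32), 32, 32)
  expect_identical(predict_tile(back, tile), predict_tile(mdl, tile))
  side <- jsonlite::read_json(paste0(path, ".json"))
  expect_equal(side$encoder, "small")
})
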