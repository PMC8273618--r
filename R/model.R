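#' Segmentation model configuration
#'
#' The model family is an encoder-decoder convolutional network mapping a
#' grayscale tile to a same-shaped single-channel probability map (logistic
#' output). Encoders: `"small"` (one conv block per scale, for desk-scale
#' CPU work) or residual presets with 18-/34-layer-style block counts
#' (`"resnet18"`, `"resnet34"`). Decoders: `"full_resolution_skip"` (U-Net
#' style, skip concatenation at every scale) or `"pyramid"` (FPN style,
#' lateral 1x1 projections, top-down pathway and a final upsampling).
#'
#' @param encoder `"small"`, `"resnet18"` or `"resnet34"`.
#' @param decoder `"full_resolution_skip"` or `"pyramid"`.
#' @param normalization `"batch"`, `"instance"` or `"none"`.
#' @param spatial_dropout_rate Channel-dropout rate in `[0, 1)` applied before
#'   the output projection during training.
#' @param base_channels Channel width of the first scale; deeper scales double.
#' @param pretrained_init If `TRUE`, external pretrained encoder weights are
#'   loaded when a weights file is supplied to [build_model()]; otherwise
#'   initialization is random (He) from the seed.
#' @return An object of class `cc_model_config`.
#' @export
model_config <- function(encoder = c("small", "resnet18", "resnet34"),
                         decoder = c("full_resolution_skip", "pyramid"),
                         normalization = c("batch", "instance", "none"),
                         spatial_dropout_rate = 0.2,
                         base_channels = 16L,
                         pretrained_init = FALSE) {
  encoder <- match.arg(encoder)
  decoder <- match.arg(decoder)
  normalization <- match.arg(normalization)
  if (spatial_dropout_rate < 0 || spatial_dropout_rate >= 1) {
    stop_ccm("spatial_dropout_rate must be in [0, 1)")
  }
  structure(list(encoder = encoder, decoder = decoder,
                 normalization = normalization,
                 spatial_dropout_rate = spatial_dropout_rate,
                 base_channels = as.integer(base_channels),
                 pretrained_init = isTRUE(pretrained_init)),
            class = "cc_model_config")
}

#' Loss configuration for training
#'
#' The training loss is
#' `bce_weight * BCE + jaccard_weight * (1 - soft_jaccard)`, combining the
#' stable convergence of per-pixel binary cross-entropy with the class
#' imbalance robustness of the soft Jaccard index.
#'
#' @param bce_weight,jaccard_weight Non-negative weights, not both zero.
#' @param smoothing_eps Smoothing constant of the soft Jaccard ratio.
#' @return An object of class `cc_loss_config`.
#' @export
loss_config <- function(bce_weight = 1, jaccard_weight = 1,
                        smoothing_eps = 1e-7) {
  if (bce_weight < 0 || jaccard_weight < 0 || bce_weight + jaccard_weight <= 0) {
    stop_ccm("loss weights must be non-negative and not both zero")
  }
  structure(list(bce_weight = bce_weight, jaccard_weight = jaccard_weight,
                 smoothing_eps = smoothing_eps), class = "cc_loss_config")
}

# stage block counts per encoder preset (residual presets mirror the
# 18-/34-layer designs: 2-2-2-2 and 3-4-6-3 blocks over four scales)
encoder_blocks <- function(encoder) {
  switch(encoder,
         small = c(1L, 1L, 1L, 1L),
         resnet18 = c(2L, 2L, 2L, 2L),
         resnet34 = c(3L, 4L, 6L, 3L))
}

DOWNSAMPLE_FACTOR <- 8L  # three pooling steps between the four scales

plan_architecture <- function(cfg) {
  C <- cfg$base_channels
  ch <- C * c(1L, 2L, 4L, 8L)
  blocks <- encoder_blocks(cfg$encoder)
  res <- cfg$encoder != "small"
  enc <- list()
  in_ch <- 1L
  for (s in 1:4) {
    stage <- list()
    for (b in seq_len(blocks[s])) {
      nm <- sprintf("enc%d.b%d", s, b)
      stage[[b]] <- list(name = nm, type = if (res) "res" else "conv",
                         cin = in_ch, cout = ch[s])
      in_ch <- ch[s]
    }
    enc[[s]] <- stage
  }
  list(channels = ch, encoder = enc, residual = res)
}

he_mat <- function(fan_in, fan_out) {
  matrix(stats::rnorm(fan_in * fan_out, 0, sqrt(2 / fan_in)), fan_in, fan_out)
}

init_block_params <- function(params, blk, norm) {
  if (blk$type == "conv") {
    params[[paste0(blk$name, ".conv")]] <-
      list(W = he_mat(9L * blk$cin, blk$cout), b = rep(0, blk$cout))
    if (norm != "none") {
      params[[paste0(blk$name, ".norm")]] <-
        list(gamma = rep(1, blk$cout), beta = rep(0, blk$cout))
    }
  } else {
    params[[paste0(blk$name, ".conv1")]] <-
      list(W = he_mat(9L * blk$cin, blk$cout), b = rep(0, blk$cout))
    params[[paste0(blk$name, ".conv2")]] <-
      list(W = he_mat(9L * blk$cout, blk$cout), b = rep(0, blk$cout))
    if (norm != "none") {
      params[[paste0(blk$name, ".norm1")]] <-
        list(gamma = rep(1, blk$cout), beta = rep(0, blk$cout))
      params[[paste0(blk$name, ".norm2")]] <-
        list(gamma = rep(1, blk$cout), beta = rep(0, blk$cout))
    }
    if (blk$cin != blk$cout) {
      params[[paste0(blk$name, ".proj")]] <-
        list(W = he_mat(blk$cin, blk$cout), b = rep(0, blk$cout))
    }
  }
  params
}

#' Build a segmentation model
#'
#' Creates the network described by a [model_config()] with randomly (He)
#' initialized weights drawn from `seed`. The model handle exposes
#' [predict_tile()] and is trainable with [train_cv()]. Input tiles must have
#' sides divisible by the downsampling factor (8).
#'
#' @param cfg A [model_config()].
#' @param seed Integer seed for weight initialization.
#' @param weights_file Optional RDS file with pretrained encoder parameters,
#'   used only when `cfg$pretrained_init` is `TRUE` and the file exists.
#' @return An object of class `cc_model`.
#' @export
build_model <- function(cfg = model_config(), seed = 1L, weights_file = NULL) {
  set.seed(seed)
  plan <- plan_architecture(cfg)
  ch <- plan$channels
  params <- list()
  for (stage in plan$encoder) {
    for (blk in stage) params <- init_block_params(params, blk, cfg$normalization)
  }
  if (cfg$decoder == "full_resolution_skip") {
    for (s in 3:1) {
      blk <- list(name = sprintf("dec%d", s), type = "conv",
                  cin = ch[s] + ch[s + 1], cout = ch[s])
      params <- init_block_params(params, blk, cfg$normalization)
    }
    params[["out"]] <- list(W = he_mat(ch[1], 1L), b = 0)
  } else {
    P <- cfg$base_channels
    for (s in 1:4) {
      params[[sprintf("lat%d", s)]] <- list(W = he_mat(ch[s], P), b = rep(0, P))
      params[[sprintf("head%d", s)]] <- list(W = he_mat(9L * P, P), b = rep(0, P))
    }
    params[["out"]] <- list(W = he_mat(P, 1L), b = 0)
  }
  if (cfg$pretrained_init && !is.null(weights_file) && file.exists(weights_file)) {
    pre <- readRDS(weights_file)
    common <- intersect(names(pre), names(params))
    params[common] <- pre[common]
  }
  structure(list(cfg = cfg, params = params, plan = plan,
                 state = new.env(parent = emptyenv())),
            class = "cc_model")
}

block_forward <- function(tape, params, id, blk, cfg, state) {
  if (blk$type == "conv") {
    id <- tp_conv(tape, params, id, paste0(blk$name, ".conv"), k = 3L)
    if (cfg$normalization != "none") {
      id <- tp_norm(tape, params, id, paste0(blk$name, ".norm"),
                    cfg$normalization, state)
    }
    tp_relu(tape, id)
  } else {
    idin <- id
    id <- tp_conv(tape, params, id, paste0(blk$name, ".conv1"), k = 3L)
    if (cfg$normalization != "none") {
      id <- tp_norm(tape, params, id, paste0(blk$name, ".norm1"),
                    cfg$normalization, state)
    }
    id <- tp_relu(tape, id)
    id <- tp_conv(tape, params, id, paste0(blk$name, ".conv2"), k = 3L)
    if (cfg$normalization != "none") {
      id <- tp_norm(tape, params, id, paste0(blk$name, ".norm2"),
                    cfg$normalization, state)
    }
    skip <- if (blk$cin != blk$cout) {
      tp_conv(tape, params, idin, paste0(blk$name, ".proj"), k = 1L)
    } else idin
    tp_relu(tape, tp_add(tape, id, skip))
  }
}

net_forward <- function(model, x, train = FALSE) {
  cfg <- model$cfg
  params <- model$params
  d <- dim(x)
  if (d[1] %% DOWNSAMPLE_FACTOR || d[2] %% DOWNSAMPLE_FACTOR) {
    stop_ccm("tile sides must be multiples of %d (got %dx%d)",
             DOWNSAMPLE_FACTOR, d[1], d[2])
  }
  tape <- new_tape(train)
  id <- tp_input(tape, x)
  skips <- integer(4)
  for (s in 1:4) {
    if (s > 1) id <- tp_pool2(tape, id)
    for (blk in model$plan$encoder[[s]]) {
      id <- block_forward(tape, params, id, blk, cfg, model$state)
    }
    skips[s] <- id
  }
  if (cfg$decoder == "full_resolution_skip") {
    for (s in 3:1) {
      id <- tp_up2(tape, id)
      id <- tp_concat(tape, id, skips[s])
      blk <- list(name = sprintf("dec%d", s), type = "conv")
      id <- block_forward(tape, params, id, blk, cfg, model$state)
    }
    id <- tp_spatial_dropout(tape, id, cfg$spatial_dropout_rate)
    id <- tp_conv(tape, params, id, "out", k = 1L)
  } else {
    lat <- integer(4)
    for (s in 1:4) lat[s] <- tp_conv(tape, params, skips[s], sprintf("lat%d", s), k = 1L)
    pyr <- integer(4)
    pyr[4] <- lat[4]
    for (s in 3:1) pyr[s] <- tp_add(tape, lat[s], tp_up2(tape, pyr[s + 1]))
    merged <- NULL
    for (s in 1:4) {
      h <- tp_conv(tape, params, pyr[s], sprintf("head%d", s), k = 3L)
      h <- tp_relu(tape, h)
      for (u in seq_len(s - 1)) h <- tp_up2(tape, h)
      merged <- if (is.null(merged)) h else tp_add(tape, merged, h)
    }
    merged <- tp_spatial_dropout(tape, merged, cfg$spatial_dropout_rate)
    id <- tp_conv(tape, params, merged, "out", k = 1L)
  }
  out <- tp_sigmoid(tape, id)
  list(out_id = out, logit_id = id, tape = tape, prob = tape$vals[[out]])
}

#' Predict the CC probability for one tile
#'
#' Runs the network in evaluation mode on a single grayscale tile.
#'
#' @param model A [build_model()] handle.
#' @param tile Numeric matrix in `[0, 1]`, sides divisible by 8.
#' @return Probability matrix of the same shape, values in `[0, 1]`.
#' @export
predict_tile <- function(model, tile) {
  fw <- net_forward(model, as_t4(tile), train = FALSE)
  p <- fw$prob
  matrix(p, dim(p)[1], dim(p)[2])
}

#' Soft Jaccard index
#'
#' Differentiable intersection-over-union relaxation:
#' `(sum(p * t) + eps) / (sum(p) + sum(t) - sum(p * t) + eps)`.
#' Equals the hard Jaccard index for binary predictions (up to `eps`), and 1
#' for two empty masks by the smoothed convention.
#'
#' @param pred Probability grid in `[0, 1]`.
#' @param target Binary grid of the same shape.
#' @param eps Smoothing constant.
#' @return Value in `[0, 1]`.
#' @export
soft_jaccard <- function(pred, target, eps = 1e-7) {
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target))) {
    stop_ccm("soft_jaccard: shape mismatch")
  }
  inter <- sum(pred * target)
  (inter + eps) / (sum(pred) + sum(target) - inter + eps)
}

#' Combined BCE + soft-Jaccard training loss
#'
#' `bce_weight * BCE(pred, target) + jaccard_weight * (1 - soft_jaccard)`,
#' with BCE the mean per-pixel binary cross-entropy computed from
#' probabilities clamped to `[1e-7, 1 - 1e-7]`.
#'
#' @param pred Probability grid (finite values).
#' @param target Binary grid of the same shape.
#' @param lc A [loss_config()].
#' @return Non-negative loss value.
#' @export
combined_loss <- function(pred, target, lc = loss_config()) {
  if (!all(is.finite(pred))) stop_ccm("combined_loss: non-finite predictions")
  if (!identical(dim(pred) %||% length(pred), dim(target) %||% length(target))) {
    stop_ccm("combined_loss: shape mismatch")
  }
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  bce <- -mean(target * log(p) + (1 - target) * log(1 - p))
  lc$bce_weight * bce +
    lc$jaccard_weight * (1 - soft_jaccard(pred, target, lc$smoothing_eps))
}

# gradient of combined_loss with respect to the probabilities
combined_loss_grad <- function(pred, target, lc) {
  p <- pmin(pmax(pred, 1e-7), 1 - 1e-7)
  n <- length(p)
  g_bce <- (p - target) / (p * (1 - p)) / n
  g <- lc$bce_weight * g_bce + lc$jaccard_weight * jaccard_grad(pred, target, lc)
  dim(g) <- dim(pred)
  g
}

# d(1 - soft_jaccard)/dp
jaccard_grad <- function(pred, target, lc) {
  inter <- sum(pred * target)
  denom <- sum(pred) + sum(target) - inter + lc$smoothing_eps
  num <- inter + lc$smoothing_eps
  -(target * denom - num * (1 - target)) / denom^2
}

# gradient of combined_loss with respect to the pre-sigmoid logits: the BCE
# term collapses to (p - t)/n, which stays informative where the sigmoid
# saturates; the Jaccard term is chained through the sigmoid derivative.
combined_loss_logit_grad <- function(pred, target, lc) {
  n <- length(pred)
  g <- lc$bce_weight * (pred - target) / n +
    lc$jaccard_weight * jaccard_grad(pred, target, lc) * pred * (1 - pred)
  dim(g) <- dim(pred)
  g
}

#' Save / load a model checkpoint
#'
#' Checkpoints use R's native serialized form plus a JSON sidecar holding the
#' model configuration.
#'
#' @param model A `cc_model`.
#' @param path Checkpoint path (conventionally `fold<k>.ckpt`).
#' @return `save_checkpoint`: invisibly, `path`. `load_checkpoint`: the model.
#' @export
save_checkpoint <- function(model, path) {
  st <- as.list(model$state)
  obj <- list(cfg = model$cfg, params = model$params, plan = model$plan,
              state_list = st)
  saveRDS(obj, path)
  jsonlite::write_json(unclass(model$cfg), paste0(path, ".json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  obj <- readRDS(path)
  state <- new.env(parent = emptyenv())
  for (nm in names(obj$state_list)) state[[nm]] <- obj$state_list[[nm]]
  structure(list(cfg = obj$cfg, params = obj$params, plan = obj$plan,
                 state = state), class = "cc_model")
}
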