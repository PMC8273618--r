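#' Subject-grouped fold assignment
#'
#' Subjects (not images) are assigned to folds so that no subject's images
#' ever appear in both the training and validation side of any fold: the
#' sorted unique subject list is shuffled with `seed` and dealt round-robin.
#'
#' @param records Data frame with at least a `subject_id` column (see
#'   [sample_records()]), or a character vector of subject ids.
#' @param n_folds Number of folds (>= 2), default 4.
#' @param seed Integer seed; the assignment is deterministic given the sorted
#'   subject list and the seed.
#' @return Object of class `cc_folds`: named integer vector mapping
#'   subject_id to fold index, with attribute `n_folds`.
#' @export
split_by_subject <- function(records, n_folds = 4L, seed = 1L) {
  subjects <- if (is.character(records)) records else records$subject_id
  subjects <- sort(unique(subjects))
  if (any(!nzchar(subjects))) stop_ccm("empty subject_id")
  if (length(subjects) < n_folds) {
    stop_ccm("need at least %d distinct subjects, got %d",
             n_folds, length(subjects))
  }
  set.seed(seed)
  shuffled <- sample(subjects)
  fold <- rep(seq_len(n_folds), length.out = length(shuffled))
  assignment <- setNames(fold, shuffled)
  structure(assignment[order(names(assignment))], n_folds = as.integer(n_folds),
            class = "cc_folds")
}

#' Build a sample manifest
#'
#' @param sample_id,subject_id Character vectors (recycled as needed).
#' @param image,mask Image and mask sources: file paths, or lists of
#'   in-memory [image2d()] / [binary_mask()] objects.
#' @param modality `"histology"` or `"microct"`.
#' @return A data frame (list-columns when in-memory objects are given).
#' @export
sample_records <- function(sample_id, subject_id, image, mask,
                           modality = "histology") {
  df <- data.frame(sample_id = sample_id, subject_id = subject_id,
                   modality = modality, stringsAsFactors = FALSE)
  df$image <- if (is.character(image)) image else I(image)
  df$mask <- if (is.character(mask)) mask else I(mask)
  df
}

record_image <- function(rec) {
  x <- rec$image[[1]] %||% rec$image
  if (is.character(x)) x <- read_image(x, grid_metadata(modality = rec$modality))
  if (inherits(x, "cc_image2d")) x$intensities else x
}

record_mask <- function(rec) {
  x <- rec$mask[[1]] %||% rec$mask
  if (is.character(x)) {
    img <- read_image(x, grid_metadata(modality = rec$modality))
    return((img$intensities > 0.5) * 1)
  }
  if (inherits(x, "cc_mask")) x$values else x
}

#' Augmentation configuration
#'
#' Geometric transforms (flips, rotation, scaling) are applied identically to
#' image and mask; photometric transforms (brightness, contrast, gamma,
#' noise) touch the image only. The mask is resampled nearest-neighbour so it
#' stays strictly binary. Setting `enabled = FALSE` (or all ranges to zero)
#' makes [augment_pair()] the identity.
#'
#' @param hflip_p,vflip_p Flip probabilities in `[0, 1]`.
#' @param rotation_deg Max absolute rotation (degrees, uniform).
#' @param scale_jitter Max relative scale change (uniform in `1 +/- value`).
#' @param brightness,contrast Max absolute brightness shift / relative
#'   contrast change.
#' @param gamma_range Ordered `c(lo, hi)` gamma exponent range.
#' @param noise_sd_max Max SD of added Gaussian noise (uniform in `[0, max]`).
#' @param enabled Master switch.
#' @return Object of class `cc_augmentation_config`.
#' @export
augmentation_config <- function(hflip_p = 0.5, vflip_p = 0.5,
                                rotation_deg = 15, scale_jitter = 0.1,
                                brightness = 0.2, contrast = 0.2,
                                gamma_range = c(0.8, 1.2),
                                noise_sd_max = 0.02, enabled = TRUE) {
  stopifnot(hflip_p >= 0, hflip_p <= 1, vflip_p >= 0, vflip_p <= 1,
            diff(gamma_range) >= 0)
  structure(as.list(environment()), class = "cc_augmentation_config")
}

# Inverse-mapped rotation+scale about the image centre; bilinear for the
# image, nearest for the mask, reflective out-of-bounds handling.
warp_pair <- function(img, mask, angle_deg, scale) {
  H <- nrow(img); W <- ncol(img)
  th <- angle_deg * pi / 180
  cr <- (H + 1) / 2; cc <- (W + 1) / 2
  rows <- matrix(seq_len(H), H, W) - cr
  cols <- matrix(seq_len(W), H, W, byrow = TRUE) - cc
  # inverse transform: rotate by -theta, divide by scale
  sr <- (cos(th) * rows + sin(th) * cols) / scale + cr
  sc <- (-sin(th) * rows + cos(th) * cols) / scale + cc
  r0 <- floor(sr); c0 <- floor(sc)
  fr <- sr - r0; fc <- sc - c0
  gi <- function(r, c) {
    img[cbind(reflect_index(as.vector(r), H), reflect_index(as.vector(c), W))]
  }
  out <- (1 - fr) * (1 - fc) * gi(r0, c0) + (1 - fr) * fc * gi(r0, c0 + 1) +
         fr * (1 - fc) * gi(r0 + 1, c0) + fr * fc * gi(r0 + 1, c0 + 1)
  dim(out) <- c(H, W)
  mi <- cbind(reflect_index(as.vector(round(sr)), H),
              reflect_index(as.vector(round(sc)), W))
  mout <- matrix(mask[mi], H, W)
  list(image = pmin(pmax(out, 0), 1), mask = mout)
}

#' Apply a random augmentation to an image/mask pair
#'
#' @param image Numeric matrix in `[0, 1]` (or [image2d()]).
#' @param mask 0/1 matrix of the same shape (or [binary_mask()]).
#' @param cfg An [augmentation_config()].
#' @param seed Optional integer seed for the transform draw.
#' @return List with `image` and `mask` (same types as the plain inputs).
#' @export
augment_pair <- function(image, mask, cfg = augmentation_config(), seed = NULL) {
  img <- if (inherits(image, "cc_image2d")) image$intensities else image
  msk <- if (inherits(mask, "cc_mask")) mask$values else mask
  if (!identical(dim(img), dim(msk))) stop_ccm("augment_pair: shape mismatch")
  if (!isTRUE(cfg$enabled)) return(list(image = img, mask = msk))
  if (!is.null(seed)) set.seed(seed)
  if (stats::runif(1) < cfg$hflip_p) {
    img <- img[, rev(seq_len(ncol(img)))]
    msk <- msk[, rev(seq_len(ncol(msk)))]
  }
  if (stats::runif(1) < cfg$vflip_p) {
    img <- img[rev(seq_len(nrow(img))), ]
    msk <- msk[rev(seq_len(nrow(msk))), ]
  }
  ang <- if (cfg$rotation_deg > 0) stats::runif(1, -cfg$rotation_deg, cfg$rotation_deg) else 0
  sc <- if (cfg$scale_jitter > 0) stats::runif(1, 1 - cfg$scale_jitter, 1 + cfg$scale_jitter) else 1
  if (ang != 0 || sc != 1) {
    wp <- warp_pair(img, msk, ang, sc)
    img <- wp$image; msk <- wp$mask
  }
  if (cfg$brightness > 0) img <- img + stats::runif(1, -cfg$brightness, cfg$brightness)
  if (cfg$contrast > 0) {
    f <- 1 + stats::runif(1, -cfg$contrast, cfg$contrast)
    img <- (img - mean(img)) * f + mean(img)
  }
  img <- pmin(pmax(img, 0), 1)
  if (diff(cfg$gamma_range) > 0 || cfg$gamma_range[1] != 1) {
    img <- img^stats::runif(1, cfg$gamma_range[1], cfg$gamma_range[2])
  }
  if (cfg$noise_sd_max > 0) {
    img <- img + stats::rnorm(length(img), 0, stats::runif(1, 0, cfg$noise_sd_max))
  }
  list(image = pmin(pmax(img, 0), 1), mask = msk)
}

#' Training configuration
#'
#' @param n_folds Cross-validation folds (default 4).
#' @param epochs Training epochs; conventional defaults are 100 for histology
#'   and 60 for micro-CT (`epochs = NULL` picks by `modality`).
#' @param modality Used only to resolve the default epoch count.
#' @param batch_size Images per optimization step (one random crop each).
#' @param crops_per_image Random crops drawn from each training image per
#'   epoch; raises the gradient-step count on small image sets.
#' @param learning_rate Adam learning rate.
#' @param tile_shape Training crop `c(rows, cols)`, divisible by 8.
#' @param seed Global training seed.
#' @param augmentation An [augmentation_config()].
#' @param loss A [loss_config()].
#' @param model A [model_config()].
#' @param eval_threshold Threshold for out-of-fold Dice during training
#'   (0.5; distinct from the deployment threshold of [inference_config()]).
#' @return Object of class `cc_train_config`.
#' @export
train_config <- function(n_folds = 4L, epochs = NULL,
                         modality = c("histology", "microct"),
                         batch_size = 4L, crops_per_image = 2L,
                         learning_rate = 1e-3,
                         tile_shape = c(64L, 64L), seed = 1L,
                         augmentation = augmentation_config(),
                         loss = loss_config(), model = model_config(),
                         eval_threshold = 0.5) {
  modality <- match.arg(modality)
  if (is.null(epochs)) epochs <- switch(modality, histology = 100L, microct = 60L)
  if (epochs < 1) stop_ccm("epochs must be >= 1")
  if (any(tile_shape %% DOWNSAMPLE_FACTOR != 0)) {
    stop_ccm("tile_shape sides must be multiples of %d", DOWNSAMPLE_FACTOR)
  }
  structure(list(n_folds = as.integer(n_folds), epochs = as.integer(epochs),
                 modality = modality, batch_size = as.integer(batch_size),
                 crops_per_image = as.integer(crops_per_image),
                 learning_rate = learning_rate,
                 tile_shape = as.integer(tile_shape), seed = as.integer(seed),
                 augmentation = augmentation, loss = loss, model = model,
                 eval_threshold = eval_threshold),
            class = "cc_train_config")
}

random_crop <- function(img, msk, shape) {
  H <- nrow(img); W <- ncol(img)
  th <- shape[1]; tw <- shape[2]
  if (H < th || W < tw) stop_ccm("image %dx%d smaller than tile %dx%d", H, W, th, tw)
  r0 <- sample.int(H - th + 1L, 1L)
  c0 <- sample.int(W - tw + 1L, 1L)
  list(image = img[r0 + seq_len(th) - 1L, c0 + seq_len(tw) - 1L],
       mask = msk[r0 + seq_len(th) - 1L, c0 + seq_len(tw) - 1L])
}

# tile-partition prediction of one full image with a single model (raw
# per-tile predictions, step = window), used for out-of-fold evaluation
predict_partition <- function(model, img, tile_shape) {
  ts <- tile_spec(window = tile_shape, step = tile_shape)
  tl <- tile_image(img, ts)
  preds <- lapply(tl$tiles, function(t) predict_tile(model, t))
  pm <- stitch_tiles(preds, tl$origins, tl$padded_dim)
  unpad_map(pm, tl$pad, dim(img))
}

#' Subject-grouped cross-validation training
#'
#' For each fold k, a model is trained on all subjects not assigned to fold
#' k. Each epoch visits every training image once in minibatches, taking one
#' random augmented crop per image, and optimizes the combined BCE +
#' soft-Jaccard loss with Adam. After training, the out-of-fold Dice is the
#' mean per-image Dice on fold-k images at `eval_threshold` on raw per-tile
#' predictions.
#'
#' @param records A [sample_records()] manifest.
#' @param folds A [split_by_subject()] assignment.
#' @param cfg A [train_config()].
#' @param verbose Print per-epoch losses.
#' @return List of class `cc_cv_run`: `models` (one `cc_model` per fold),
#'   `oof_dice` (per-fold out-of-fold Dice), `loss_curves` (per-fold numeric
#'   vectors of mean epoch loss), `folds`.
#' @export
train_cv <- function(records, folds, cfg = train_config(), verbose = FALSE) {
  n_folds <- attr(folds, "n_folds")
  fold_of <- unclass(folds)[records$subject_id]
  if (any(is.na(fold_of))) stop_ccm("records contain subjects missing from folds")
  models <- vector("list", n_folds)
  oof <- numeric(n_folds)
  curves <- vector("list", n_folds)
  for (k in seq_len(n_folds)) {
    tr_idx <- which(fold_of != k)
    va_idx <- which(fold_of == k)
    if (length(tr_idx) == 0 || length(va_idx) == 0) {
      stop_ccm("fold %d has an empty train or validation side", k)
    }
    tr_imgs <- lapply(tr_idx, function(i) record_image(records[i, , drop = FALSE]))
    tr_msks <- lapply(tr_idx, function(i) record_mask(records[i, , drop = FALSE]))
    if (all(vapply(tr_msks, sum, numeric(1)) == 0)) {
      warning(sprintf("fold %d: all-background training masks", k))
    }
    set.seed(cfg$seed * 1000L + k)
    model <- build_model(cfg$model, seed = cfg$seed * 1000L + k)
    ad <- adam_init(model$params)
    losses <- numeric(cfg$epochs)
    nt <- length(tr_idx)
    reps <- max(1L, cfg$crops_per_image %||% 1L)
    for (ep in seq_len(cfg$epochs)) {
      ord <- sample(rep(seq_len(nt), reps))
      nr <- length(ord)
      ep_loss <- 0
      nb <- 0L
      for (b0 in seq(1L, nr, by = cfg$batch_size)) {
        ids <- ord[b0:min(b0 + cfg$batch_size - 1L, nr)]
        xb <- array(0, dim = c(cfg$tile_shape, 1L, length(ids)))
        tb <- array(0, dim = c(cfg$tile_shape, 1L, length(ids)))
        for (j in seq_along(ids)) {
          aug <- augment_pair(tr_imgs[[ids[j]]], tr_msks[[ids[j]]],
                              cfg$augmentation)
          cr <- random_crop(aug$image, aug$mask, cfg$tile_shape)
          xb[, , 1L, j] <- cr$image
          tb[, , 1L, j] <- cr$mask
        }
        fw <- net_forward(model, xb, train = TRUE)
        loss <- combined_loss(fw$prob, tb, cfg$loss)
        dlogit <- combined_loss_logit_grad(fw$prob, tb, cfg$loss)
        grads <- tape_backward(fw$tape, fw$logit_id, dlogit, model$params)
        upd <- adam_step(model$params, grads, ad, lr = cfg$learning_rate)
        model$params <- upd$params
        ad <- upd$state
        ep_loss <- ep_loss + loss
        nb <- nb + 1L
      }
      losses[ep] <- ep_loss / nb
      if (verbose) message(sprintf("fold %d epoch %d loss %.4f", k, ep, losses[ep]))
    }
    d_sum <- 0
    for (i in va_idx) {
      img <- record_image(records[i, , drop = FALSE])
      msk <- record_mask(records[i, , drop = FALSE])
      pm <- predict_partition(model, img, cfg$tile_shape)
      d_sum <- d_sum + dice_score((pm >= cfg$eval_threshold) * 1, msk)
    }
    oof[k] <- d_sum / length(va_idx)
    models[[k]] <- model
    curves[[k]] <- losses
  }
  structure(list(models = models, oof_dice = oof, loss_curves = curves,
                 folds = folds), class = "cc_cv_run")
}
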