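#' Sliding-window tile specification
#'
#' Defaults follow the deployment geometry: a 512 x 1024 pixel window moved
#' in 256 x 512 pixel steps (50% overlap in both directions).
#'
#' @param window `c(rows, cols)` tile size.
#' @param step `c(rows, cols)` step, `0 < step <= window` componentwise.
#' @return Object of class `cc_tile_spec`.
#' @export
tile_spec <- function(window = c(512L, 1024L), step = c(256L, 512L)) {
  window <- as.integer(window); step <- as.integer(step)
  if (any(step <= 0) || any(step > window)) {
    stop_ccm("tile step must satisfy 0 < step <= window componentwise")
  }
  structure(list(window = window, step = step), class = "cc_tile_spec")
}

tile_starts <- function(n, w, s) {
  if (n <= w) return(1L)
  st <- seq.int(1L, n - w + 1L, by = s)
  # final window shifted inward so it never exceeds the bounds
  if (st[length(st)] != n - w + 1L) st <- c(st, n - w + 1L)
  st
}

#' Decompose an image into overlapping tiles
#'
#' Tiles cover every pixel; origins advance by the step, with the final
#' row/column of windows shifted inward so windows never exceed the image.
#' Images smaller than one window are reflect-padded up to the window size
#' and the applied pad is recorded (and removed again by the predictors).
#'
#' @param image Numeric matrix (or [image2d()] / probability matrix).
#' @param tiles A [tile_spec()].
#' @return List: `tiles` (list of window-sized matrices), `origins`
#'   (n x 2 matrix of 1-based row/col origins in the padded frame), `pad`
#'   (`c(rows, cols)` reflect-pad applied), `padded_dim`.
#' @export
tile_image <- function(image, tiles = tile_spec()) {
  img <- if (inherits(image, "cc_image2d")) image$intensities else image
  d <- dim(img)
  w <- tiles$window
  pad <- pmax(w - d, 0L)
  if (any(pad > 0)) {
    padded <- matrix(0, d[1] + pad[1], d[2] + pad[2])
    ri <- reflect_index(seq_len(d[1] + pad[1]), d[1])
    ci <- reflect_index(seq_len(d[2] + pad[2]), d[2])
    padded <- img[ri, ci, drop = FALSE]
    img <- padded
    d <- dim(img)
  }
  rs <- tile_starts(d[1], w[1], tiles$step[1])
  cs <- tile_starts(d[2], w[2], tiles$step[2])
  origins <- as.matrix(expand.grid(row = rs, col = cs))
  tl <- vector("list", nrow(origins))
  for (i in seq_len(nrow(origins))) {
    tl[[i]] <- img[origins[i, 1] + seq_len(w[1]) - 1L,
                   origins[i, 2] + seq_len(w[2]) - 1L, drop = FALSE]
  }
  list(tiles = tl, origins = origins, pad = pad, padded_dim = d)
}

#' Recombine tile predictions by overlap averaging
#'
#' Every pixel receives the uniform mean of all tile predictions covering it.
#'
#' @param tile_preds List of probability matrices (equal shapes, values in
#'   `[0, 1]`).
#' @param origins Origin matrix from [tile_image()].
#' @param shape `c(rows, cols)` of the output (padded) map.
#' @return Probability matrix of dimension `shape`.
#' @export
stitch_tiles <- function(tile_preds, origins, shape) {
  acc <- matrix(0, shape[1], shape[2])
  cnt <- matrix(0, shape[1], shape[2])
  w <- dim(tile_preds[[1]])
  for (i in seq_along(tile_preds)) {
    p <- tile_preds[[i]]
    if (min(p) < 0 || max(p) > 1) stop_ccm("tile prediction outside [0, 1]")
    ri <- origins[i, 1] + seq_len(w[1]) - 1L
    ci <- origins[i, 2] + seq_len(w[2]) - 1L
    acc[ri, ci] <- acc[ri, ci] + p
    cnt[ri, ci] <- cnt[ri, ci] + 1
  }
  if (any(cnt == 0)) stop_ccm("internal error: uncovered pixel after tiling")
  acc / cnt
}

unpad_map <- function(map, pad, d_orig) {
  if (all(pad == 0)) return(map)
  map[seq_len(d_orig[1]), seq_len(d_orig[2]), drop = FALSE]
}

#' Inference configuration
#'
#' @param tiles A [tile_spec()].
#' @param threshold Probability threshold in `(0, 1)`; the high default of
#'   0.8 excludes ambiguous areas from the final masks.
#' @param planes For volumes: subset of `c("coronal", "sagittal")` to average
#'   over (both by default). In the (slice, row, column) convention, coronal
#'   slices fix the row axis and sagittal slices fix the column axis; the
#'   axial plane is not used.
#' @return Object of class `cc_inference_config`.
#' @export
inference_config <- function(tiles = tile_spec(), threshold = 0.8,
                             planes = c("coronal", "sagittal")) {
  if (threshold <= 0 || threshold >= 1) stop_ccm("threshold must be in (0, 1)")
  planes <- match.arg(planes, several.ok = TRUE)
  if (length(planes) < 1) stop_ccm("at least one plane required")
  structure(list(tiles = tiles, threshold = threshold, planes = planes),
            class = "cc_inference_config")
}

model_predict_fun <- function(m) {
  if (is.function(m)) m else function(tile) predict_tile(m, tile)
}

#' Predict a full 2D probability map with a fold ensemble
#'
#' Each fold model predicts every tile; per-fold maps are stitched with
#' overlap averaging and then averaged uniformly across folds.
#'
#' @param image Numeric matrix in `[0, 1]` or [image2d()].
#' @param models List of `cc_model` handles (fold checkpoints) or plain
#'   functions `tile -> probability matrix`.
#' @param cfg An [inference_config()].
#' @return A list of class `cc_probmap`: `values` (matrix in `[0, 1]`),
#'   `meta`, `provenance` (folds and planes averaged).
#' @export
predict_2d <- function(image, models, cfg = inference_config()) {
  if (length(models) < 1) stop_ccm("predict_2d: need at least one model")
  img <- if (inherits(image, "cc_image2d")) image$intensities else image
  meta <- if (inherits(image, "cc_image2d")) image$meta else grid_metadata()
  tl <- tile_image(img, cfg$tiles)
  acc <- NULL
  for (m in models) {
    f <- model_predict_fun(m)
    preds <- lapply(tl$tiles, f)
    pm <- stitch_tiles(preds, tl$origins, tl$padded_dim)
    acc <- if (is.null(acc)) pm else acc + pm
  }
  vals <- unpad_map(acc / length(models), tl$pad, dim(img))
  structure(list(values = vals, meta = meta,
                 provenance = list(n_folds = length(models), planes = NULL)),
            class = "cc_probmap")
}

#' Predict a full 3D probability map (slice-wise, plane-averaged ensemble)
#'
#' For each requested plane, every slice along that axis is predicted with
#' [predict_2d()] and reassembled into a volume; the final map is the
#' uniform mean over all (plane, fold) members.
#'
#' @param volume 3D array in `[0, 1]` or [image_volume()], axes
#'   (slice, row, column).
#' @param models List of fold models (as in [predict_2d()]).
#' @param cfg An [inference_config()].
#' @return A `cc_probmap` whose `values` is a 3D array.
#' @export
predict_volume <- function(volume, models, cfg = inference_config()) {
  vol <- if (inherits(volume, "cc_volume")) volume$intensities else volume
  meta <- if (inherits(volume, "cc_volume")) volume$meta else
    grid_metadata(modality = "microct")
  d <- dim(vol)
  acc <- array(0, dim = d)
  for (plane in cfg$planes) {
    out <- array(0, dim = d)
    if (plane == "coronal") {
      if (d[2] < 1) stop_ccm("no slices along the coronal plane")
      for (r in seq_len(d[2])) {
        sl <- vol[, r, ]
        dim(sl) <- d[c(1, 3)]
        out[, r, ] <- predict_2d(sl, models, cfg)$values
      }
    } else {
      if (d[3] < 1) stop_ccm("no slices along the sagittal plane")
      for (cl in seq_len(d[3])) {
        sl <- vol[, , cl]
        dim(sl) <- d[c(1, 2)]
        out[, , cl] <- predict_2d(sl, models, cfg)$values
      }
    }
    acc <- acc + out
  }
  structure(list(values = acc / length(cfg$planes), meta = meta,
                 provenance = list(n_folds = length(models),
                                   planes = cfg$planes)),
            class = "cc_probmap")
}

#' Threshold a probability map into a binary mask
#'
#' Inclusive rule: a pixel whose probability equals the threshold is
#' foreground.
#'
#' @param map A `cc_probmap` or plain probability array.
#' @param t Threshold in `(0, 1)` (deployment default 0.8).
#' @return A [binary_mask()] (when metadata is available) or 0/1 array.
#' @export
threshold_probability <- function(map, t = 0.8) {
  if (t <= 0 || t >= 1) stop_ccm("threshold must be in (0, 1)")
  if (inherits(map, "cc_probmap")) {
    binary_mask((map$values >= t) * 1, map$meta)
  } else {
    (map >= t) * 1
  }
}
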