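#' Default end-to-end run configuration
#'
#' The configuration drives [run_end_to_end()]: phantom generation, grouped
#' CV training, ensemble inference, modality-specific post-processing,
#' thickness morphometry and validation. Any subset can be overridden via a
#' YAML file or a named list.
#'
#' @param modality `"histology"` (2D) or `"microct"` (3D).
#' @return Nested configuration list.
#' @export
default_run_config <- function(modality = c("histology", "microct")) {
  modality <- match.arg(modality)
  common <- list(
    run_name = paste0("demo_", modality),
    modality = modality,
    seed = 1L,
    stages = c("phantom", "train", "predict", "postprocess", "thickness",
               "validate"),
    phantom = list(n_train = 8L, n_test = 4L),
    train = list(n_folds = 4L, epochs = 20L, batch_size = 4L,
                 learning_rate = 1e-3, tile = c(64L, 64L), augment = FALSE,
                 model = list(encoder = "small",
                              decoder = "full_resolution_skip",
                              normalization = "batch", base_channels = 8L,
                              spatial_dropout_rate = 0)),
    inference = list(window = c(64L, 64L), step = c(32L, 32L),
                     threshold = 0.8, planes = c("coronal", "sagittal")),
    postprocess = list(min_region_px = 500L, median_radius_px = 12L)
  )
  if (modality == "histology") {
    common$phantom$shape <- c(128L, 192L)
    # cycled across phantoms: emulates anatomical regions of varying CC.Th
    common$phantom$base_thickness_px <- c(26, 30, 34, 38)
  } else {
    # sphere diameters stay small relative to the 64-voxel lateral extent so
    # the boundary-clipping caveat of the thickness convention is second-order
    common$phantom$shape <- c(64L, 64L, 64L)
    common$phantom$base_thickness_px <- 16
    common$phantom$amplitude_px <- 4
    common$phantom$spatial_period_px <- 64
    common$phantom$cartilage_depth_px <- 12
    common$phantom$n_train <- 4L
    common$phantom$n_test <- 1L
    common$train$epochs <- 12L
    common$train$slices_per_volume <- 4L
  }
  common
}

merge_config <- function(base, override) {
  for (nm in names(override)) {
    if (is.list(base[[nm]]) && is.list(override[[nm]])) {
      base[[nm]] <- merge_config(base[[nm]], override[[nm]])
    } else {
      base[[nm]] <- override[[nm]]
    }
  }
  base
}

load_run_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  modality <- config$modality %||% "histology"
  merge_config(default_run_config(modality), config)
}

phantom_spec_from_config <- function(cfg, seed, index = 1L) {
  args <- cfg$phantom
  args$n_train <- NULL; args$n_test <- NULL
  args$shape <- as.integer(args$shape)
  # a vector base thickness is cycled across phantoms (regional variation)
  bases <- args$base_thickness_px %||% 32
  args$base_thickness_px <- bases[(index - 1L) %% length(bases) + 1L]
  args$seed <- seed
  do.call(phantom_spec, args)
}

make_phantom_set <- function(cfg) {
  n <- cfg$phantom$n_train + cfg$phantom$n_test
  is3d <- length(cfg$phantom$shape) == 3
  gen <- if (is3d) generate_phantom_3d else generate_phantom_2d
  meta <- grid_metadata(modality = cfg$modality)
  phantoms <- lapply(seq_len(n), function(i) {
    gen(phantom_spec_from_config(cfg, seed = cfg$seed * 100L + i, index = i), meta)
  })
  names(phantoms) <- sprintf("S%02d", seq_len(n))
  list(train = phantoms[seq_len(cfg$phantom$n_train)],
       test = phantoms[cfg$phantom$n_train + seq_len(cfg$phantom$n_test)])
}

training_records <- function(train_phantoms, cfg) {
  if (cfg$modality == "histology") {
    sample_records(
      sample_id = names(train_phantoms),
      subject_id = names(train_phantoms),
      image = lapply(train_phantoms, function(p) p$image),
      mask = lapply(train_phantoms, function(p) p$truth_mask),
      modality = cfg$modality
    )
  } else {
    # train on coronal slices extracted from each training volume
    k <- cfg$train$slices_per_volume %||% 4L
    recs <- list()
    for (nm in names(train_phantoms)) {
      p <- train_phantoms[[nm]]
      d <- dim(p$image$intensities)
      rows <- round(seq(1, d[2], length.out = k))
      for (r in rows) {
        sl <- p$image$intensities[, r, ]; dim(sl) <- d[c(1, 3)]
        ms <- p$truth_mask$values[, r, ]; dim(ms) <- d[c(1, 3)]
        recs[[length(recs) + 1L]] <- sample_records(
          sample_id = sprintf("%s_r%03d", nm, r), subject_id = nm,
          image = list(image2d(sl, p$image$meta)),
          mask = list(binary_mask(ms, p$image$meta)),
          modality = cfg$modality)
      }
    }
    do.call(rbind, recs)
  }
}

train_config_from <- function(cfg) {
  m <- cfg$train$model
  train_config(
    n_folds = cfg$train$n_folds,
    epochs = cfg$train$epochs,
    modality = cfg$modality,
    batch_size = cfg$train$batch_size,
    crops_per_image = cfg$train$crops_per_image %||% 2L,
    learning_rate = cfg$train$learning_rate,
    tile_shape = as.integer(cfg$train$tile),
    seed = cfg$seed,
    augmentation = if (isTRUE(cfg$train$augment)) augmentation_config()
                   else augmentation_config(enabled = FALSE),
    model = model_config(encoder = m$encoder, decoder = m$decoder,
                         normalization = m$normalization,
                         spatial_dropout_rate = m$spatial_dropout_rate %||% 0.2,
                         base_channels = m$base_channels)
  )
}

inference_config_from <- function(cfg) {
  inference_config(
    tiles = tile_spec(window = as.integer(cfg$inference$window),
                      step = as.integer(cfg$inference$step)),
    threshold = cfg$inference$threshold,
    planes = cfg$inference$planes
  )
}

#' Post-process a predicted mask with the modality's cleaning chain
#'
#' Histology (2D): small-region removal then 2D median filtering.
#' Micro-CT (3D): largest-object sweep then 3D median filtering.
#'
#' @param mask A [binary_mask()].
#' @param modality `"histology"` or `"microct"`.
#' @param min_region_px Minimum surviving region size (histology chain).
#' @param median_radius_px Median filter radius.
#' @return The cleaned mask.
#' @export
postprocess_mask <- function(mask, modality = c("histology", "microct"),
                             min_region_px = 500, median_radius_px = 12) {
  modality <- match.arg(modality)
  if (modality == "histology") {
    mask <- remove_small_regions(mask, min_size = min_region_px)
  } else {
    mask <- keep_largest_component(mask)
  }
  median_filter_mask(mask, radius_px = median_radius_px)
}

#' Run the full phantom-to-report pipeline
#'
#' Executes the stage sequence appropriate to the configured modality:
#' phantom generation, subject-grouped CV training, tiled ensemble inference
#' (plane-averaged for volumes), probability thresholding, modality-specific
#' post-processing, local-thickness morphometry, and validation against the
#' phantom ground truth. Every stage's outputs, the resolved configuration
#' and the global seed are written into the run directory.
#'
#' @param config Path to a YAML configuration, or a named list; missing
#'   entries fall back to [default_run_config()].
#' @param out Output directory (created); defaults to a `run_name` directory
#'   under the current working directory.
#' @param seed Optional override of the configured seed.
#' @param verbose Print stage progress.
#' @return Invisibly, a list with the run directory, thickness summary table,
#'   validation report and resolved configuration.
#' @export
run_end_to_end <- function(config = list(), out = NULL, seed = NULL,
                           verbose = TRUE) {
  cfg <- load_run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  out <- out %||% file.path(getwd(), cfg$run_name)
  if (!dir.exists(out)) dir.create(out, recursive = TRUE)
  log_lines <- character(0)
  say <- function(stage, msg) {
    line <- sprintf("[%s] [%s] %s", format(Sys.time(), "%H:%M:%S"), stage, msg)
    log_lines <<- c(log_lines, line)
    if (verbose) message(line)
  }
  run_stage <- function(stage, fun) {
    if (!(stage %in% cfg$stages)) {
      say(stage, "skipped")
      return(NULL)
    }
    say(stage, "start")
    res <- tryCatch(fun(), error = function(e) {
      writeLines(log_lines, file.path(out, "run.log"))
      stop_ccm("stage '%s' failed: %s (artifacts kept in %s)",
               stage, conditionMessage(e), out)
    })
    say(stage, "done")
    res
  }
  jsonlite::write_json(cfg, file.path(out, "resolved_config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  is3d <- cfg$modality == "microct"
  env <- new.env()

  run_stage("phantom", function() {
    env$ph <- make_phantom_set(cfg)
  })
  run_stage("train", function() {
    recs <- training_records(env$ph$train, cfg)
    folds <- split_by_subject(recs, cfg$train$n_folds, seed = cfg$seed)
    env$cv <- train_cv(recs, folds, train_config_from(cfg))
    say("train", sprintf("out-of-fold Dice: %s",
                         paste(sprintf("%.3f", env$cv$oof_dice), collapse = " ")))
  })
  run_stage("predict", function() {
    icfg <- inference_config_from(cfg)
    env$prob <- lapply(env$ph$test, function(p) {
      if (is3d) predict_volume(p$image, env$cv$models, icfg)
      else predict_2d(p$image, env$cv$models, icfg)
    })
    env$raw_masks <- lapply(env$prob, threshold_probability,
                            t = cfg$inference$threshold)
  })
  run_stage("postprocess", function() {
    env$masks <- lapply(env$raw_masks, postprocess_mask,
                        modality = cfg$modality,
                        min_region_px = cfg$postprocess$min_region_px,
                        median_radius_px = cfg$postprocess$median_radius_px)
  })
  run_stage("thickness", function() {
    env$summaries <- lapply(names(env$masks), function(nm) {
      m <- env$masks[[nm]]
      if (sum(m$values) == 0) {
        warning(sprintf("sample %s: empty mask after post-processing", nm))
        return(structure(list(mean_um = NA_real_, median_um = NA_real_,
                              max_um = NA_real_, sd_um = NA_real_,
                              n_foreground = 0L,
                              pixel_size_um = m$meta$pixel_size_um,
                              sample_id = nm, region = cfg$modality),
                         class = "cc_thickness_summary"))
      }
      summarize_thickness(local_thickness(m), sample_id = nm,
                          region = cfg$modality)
    })
    write_summary_table(env$summaries, file.path(out, "summary.csv"))
  })
  run_stage("validate", function() {
    truths <- lapply(env$ph$test, function(p) p$truth_mask)
    rep <- out_of_fold_report(env$masks, truths,
                              pixel_size_um = grid_metadata(
                                modality = cfg$modality)$pixel_size_um)
    prescribed <- vapply(env$ph$test, prescribed_mean_thickness_um, numeric(1))
    recovered <- vapply(env$summaries, function(s) s$mean_um, numeric(1))
    names(recovered) <- vapply(env$summaries, function(s) s$sample_id, character(1))
    recovered <- recovered[names(prescribed)]
    ok <- !is.na(recovered)
    ba <- if (sum(ok) >= 2) bland_altman(recovered[ok], prescribed[ok]) else NULL
    env$report <- list(
      mean_dice = rep$mean_dice,
      per_sample = rep$per_sample,
      prescribed_um = as.list(prescribed),
      recovered_um = as.list(recovered),
      recovery_rel_error = as.list(abs(recovered - prescribed) / prescribed),
      bland_altman = if (!is.null(ba)) unclass(ba) else NULL,
      seed = cfg$seed
    )
    jsonlite::write_json(env$report, file.path(out, "report.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         dataframe = "rows")
    utils::write.csv(rep$per_sample, file.path(out, "agreement.csv"),
                     row.names = FALSE, quote = FALSE)
  })
  writeLines(log_lines, file.path(out, "run.log"))
  run_info <- list(run_name = cfg$run_name, seed = cfg$seed,
                   modality = cfg$modality, stages = cfg$stages,
                   r_version = R.version.string,
                   package_version = as.character(utils::packageVersion("ccmorph")))
  jsonlite::write_json(run_info, file.path(out, "run.json"), auto_unbox = TRUE)
  invisible(list(out = out, summaries = env$summaries %||% NULL,
                 report = env$report %||% NULL, config = cfg,
                 cv = env$cv %||% NULL, masks = env$masks %||% NULL,
                 phantoms = env$ph %||% NULL))
}

#' Scaled 2D phantom study: parameter recovery end to end
#'
#' Runs the complete histology-style experiment at desk scale: generates
#' phantoms whose base CC thickness cycles over `bases` (emulating anatomical
#' regions of varying thickness), trains the small model under
#' subject-grouped cross-validation on the training subjects, then recovers
#' mean CC.Th through the full pipeline (tiled ensemble inference,
#' thresholding, small-region removal, median filtering, local thickness).
#' Held-out phantoms are predicted with the full fold ensemble; training
#' phantoms with their out-of-fold model only, so every recovery is made by
#' a model that never saw that subject.
#'
#' @param seed Integer seed controlling phantom generation and training.
#' @param n_train,n_test Numbers of training and held-out subjects.
#' @param bases Base thicknesses (px) cycled across phantoms.
#' @param epochs Training epochs for the small model.
#' @param threshold Deployment probability threshold.
#' @param verbose Print progress.
#' @return A list: `per_phantom` data frame (sample, role, base_px, dice,
#'   prescribed_um, recovered_um, rel_error), `heldout_mean_dice`,
#'   `pearson` (prescribed vs recovered over all phantoms), `bland_altman`
#'   (recovered minus prescribed, um), `oof_dice` (per training fold).
#' @export
phantom_study_2d <- function(seed = 1L, n_train = 8L, n_test = 4L,
                             bases = c(26, 30, 34, 38), epochs = 20L,
                             threshold = 0.8, verbose = FALSE) {
  n <- n_train + n_test
  phantoms <- lapply(seq_len(n), function(i) {
    generate_phantom_2d(phantom_spec(
      base_thickness_px = bases[(i - 1L) %% length(bases) + 1L],
      seed = seed * 100L + i))
  })
  names(phantoms) <- sprintf("S%02d", seq_len(n))
  train_ph <- phantoms[seq_len(n_train)]
  test_ph <- phantoms[n_train + seq_len(n_test)]

  recs <- sample_records(names(train_ph), names(train_ph),
                         lapply(train_ph, function(p) p$image),
                         lapply(train_ph, function(p) p$truth_mask))
  folds <- split_by_subject(recs, 4L, seed = seed)
  tcfg <- train_config(
    n_folds = 4L, epochs = epochs, batch_size = 4L, crops_per_image = 6L,
    tile_shape = c(64L, 64L),
    seed = seed, augmentation = augmentation_config(enabled = FALSE),
    model = model_config(encoder = "small", decoder = "full_resolution_skip",
                         normalization = "batch", base_channels = 8L,
                         spatial_dropout_rate = 0))
  cv <- train_cv(recs, folds, tcfg, verbose = verbose)

  icfg <- inference_config(tiles = tile_spec(c(64L, 64L), c(32L, 32L)),
                           threshold = threshold)
  eval_one <- function(ph, models) {
    pm <- predict_2d(ph$image, models, icfg)
    clean <- postprocess_mask(threshold_probability(pm, threshold), "histology")
    rec <- if (sum(clean$values) == 0) NA_real_ else
      summarize_thickness(local_thickness(clean))$mean_um
    c(dice = dice_score(clean, ph$truth_mask), recovered = rec)
  }
  rows <- list()
  fold_map <- unclass(folds)
  for (nm in names(phantoms)) {
    ph <- phantoms[[nm]]
    held_out <- nm %in% names(test_ph)
    models <- if (held_out) cv$models else cv$models[fold_map[[nm]]]
    ev <- eval_one(ph, models)
    pre <- prescribed_mean_thickness_um(ph)
    rows[[nm]] <- data.frame(
      sample = nm, role = if (held_out) "heldout" else "train_oof",
      base_px = phantoms[[nm]]$spec$base_thickness_px,
      dice = unname(ev["dice"]), prescribed_um = pre,
      recovered_um = unname(ev["recovered"]),
      rel_error = abs(unname(ev["recovered"]) - pre) / pre,
      stringsAsFactors = FALSE)
    if (verbose) message(sprintf("%s (%s): dice %.3f, recovered %.1f / %.1f um",
                                 nm, rows[[nm]]$role, rows[[nm]]$dice,
                                 rows[[nm]]$recovered_um, pre))
  }
  per <- do.call(rbind, rows)
  held <- per[per$role == "heldout", ]
  ok <- !is.na(per$recovered_um)
  if (any(!ok)) warning(sprintf("%d phantom(s) yielded an empty mask", sum(!ok)))
  pc <- pearson_cor(per$prescribed_um[ok], per$recovered_um[ok])
  ba <- bland_altman(per$recovered_um[ok], per$prescribed_um[ok])
  list(per_phantom = per, heldout_mean_dice = mean(held$dice),
       pearson = pc, bland_altman = ba, oof_dice = cv$oof_dice)
}
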