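#' Grid metadata for images and volumes
#'
#' Physical metadata carried with every image, volume, mask, probability map
#' and thickness map in the pipeline. The axis convention for volumes is
#' (slice, row, column); pixels are isotropic.
#'
#' When `pixel_size_um` is not supplied, the modality default is used:
#' 3.2 um for `"microct"` and 2.56 um for `"histology"`.
#'
#' @param pixel_size_um Positive pixel edge length in micrometres, or `NULL`
#'   to apply the modality default.
#' @param modality One of `"histology"`, `"microct"`.
#' @return An object of class `cc_meta` with fields `pixel_size_um`,
#'   `modality` and `axis_order`.
#' @export
#' @examples
#' grid_metadata(modality = "microct")$pixel_size_um  # 3.2
grid_metadata <- function(pixel_size_um = NULL, modality = c("histology", "microct")) {
  modality <- match.arg(modality)
  if (is.null(pixel_size_um)) {
    pixel_size_um <- switch(modality, microct = 3.2, histology = 2.56)
  }
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1 ||
      !is.finite(pixel_size_um) || pixel_size_um <= 0) {
    stop_ccm("pixel_size_um must be a single positive number")
  }
  structure(
    list(pixel_size_um = pixel_size_um, modality = modality,
         axis_order = c("slice", "row", "column")),
    class = "cc_meta"
  )
}

#' Construct a 2D image object
#'
#' Intensities live in `[0, 1]` regardless of the on-disk bit depth.
#'
#' @param intensities Numeric matrix with finite values in `[0, 1]`.
#' @param meta A [grid_metadata()] object.
#' @return An object of class `cc_image2d`.
#' @export
image2d <- function(intensities, meta = grid_metadata()) {
  if (!is.matrix(intensities)) stop_ccm("intensities must be a matrix")
  if (!all(is.finite(intensities))) stop_ccm("intensities must be finite")
  if (min(intensities) < 0 || max(intensities) > 1) {
    stop_ccm("intensities must lie in [0, 1]")
  }
  structure(list(intensities = intensities, meta = meta), class = "cc_image2d")
}

#' Construct a 3D image volume
#'
#' @param intensities 3D numeric array, axes (slice, row, column), finite
#'   values in `[0, 1]`, at least one slice.
#' @param meta A [grid_metadata()] object.
#' @return An object of class `cc_volume`.
#' @export
image_volume <- function(intensities, meta = grid_metadata(modality = "microct")) {
  if (!is.array(intensities) || length(dim(intensities)) != 3) {
    stop_ccm("intensities must be a 3D array (slice, row, column)")
  }
  if (dim(intensities)[1] < 1) stop_ccm("volume needs at least one slice")
  if (!all(is.finite(intensities))) stop_ccm("intensities must be finite")
  if (min(intensities) < 0 || max(intensities) > 1) {
    stop_ccm("intensities must lie in [0, 1]")
  }
  structure(list(intensities = intensities, meta = meta), class = "cc_volume")
}

#' Construct a binary mask
#'
#' @param values Matrix or 3D array containing only 0 and 1.
#' @param meta A [grid_metadata()] object.
#' @return An object of class `cc_mask`.
#' @export
binary_mask <- function(values, meta = grid_metadata()) {
  if (is.null(dim(values))) stop_ccm("mask must be a matrix or 3D array")
  if (!is_binary(values)) stop_ccm("mask values must be strictly 0/1")
  storage.mode(values) <- "double"
  structure(list(values = values, meta = meta), class = "cc_mask")
}

mask_dim <- function(mask) length(dim(mask$values))

read_gray <- function(path) {
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop_ccm("unsupported image format '%s' (PNG/TIFF only): %s", ext, path)
  )
  # Multi-channel input: drop alpha, average colour channels to luminance.
  if (length(dim(px)) == 3) {
    nc <- dim(px)[3]
    if (nc %in% c(2L, 4L)) px <- px[, , -nc, drop = FALSE]
    px <- apply(px, c(1, 2), mean)
  }
  px
}

#' Read a single grayscale image
#'
#' PNG and TIFF (8/16-bit) are supported; intensities are rescaled so the bit
#' depth maximum maps to exactly 1.0. Colour images are averaged to luminance.
#'
#' @param path File path.
#' @param meta A [grid_metadata()] object attached to the result.
#' @return A [image2d()] object.
#' @export
read_image <- function(path, meta = grid_metadata()) {
  if (!file.exists(path)) stop_ccm("image not found: %s", path)
  image2d(read_gray(path), meta)
}

#' Write a grayscale 2D image
#'
#' @param image A [image2d()] object or numeric matrix in `[0, 1]`.
#' @param path Output path; extension selects PNG or TIFF.
#' @param bits Bit depth, 8 or 16.
#' @export
write_image <- function(image, path, bits = 8) {
  m <- if (inherits(image, "cc_image2d")) image$intensities else image
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    png::writePNG(m, path, dpi = NULL)
  } else if (ext %in% c("tif", "tiff")) {
    tiff::writeTIFF(m, path, bits.per.sample = as.integer(bits))
  } else {
    stop_ccm("unsupported image format '%s': %s", ext, path)
  }
  invisible(path)
}

stack_files <- function(directory_or_pattern) {
  if (dir.exists(directory_or_pattern)) {
    files <- list.files(directory_or_pattern,
                        pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                        full.names = TRUE)
  } else {
    files <- Sys.glob(directory_or_pattern)
  }
  # Lexicographic (C locale) order; the phantom writer zero-pads indices so
  # lexicographic equals numeric order.
  files[order(basename(files), method = "radix")]
}

#' Read a directory of per-slice images as a volume
#'
#' Slices are assembled in lexicographic filename order; all slices must share
#' the same shape. Intensities are rescaled to `[0, 1]` by the input bit-depth
#' maximum.
#'
#' @param directory_or_pattern Directory containing slice images, or a glob
#'   pattern.
#' @param meta A [grid_metadata()] object for the volume.
#' @return A [image_volume()] object with axes (slice, row, column).
#' @export
read_image_stack <- function(directory_or_pattern,
                             meta = grid_metadata(modality = "microct")) {
  files <- stack_files(directory_or_pattern)
  if (length(files) == 0) {
    stop_ccm("no slice images found in %s", directory_or_pattern)
  }
  slices <- lapply(files, read_gray)
  shp <- dim(slices[[1]])
  bad <- which(!vapply(slices, function(s) identical(dim(s), shp), logical(1)))
  if (length(bad)) {
    stop_ccm("slice shape mismatch at %s (expected %dx%d)",
             basename(files[bad[1]]), shp[1], shp[2])
  }
  vol <- array(0, dim = c(length(slices), shp))
  for (i in seq_along(slices)) vol[i, , ] <- slices[[i]]
  image_volume(vol, meta)
}

#' Read a directory of per-slice masks as a 3D binary mask
#'
#' @inheritParams read_image_stack
#' @return A [binary_mask()] object (3D). Values above 0.5 map to 1.
#' @export
read_mask_stack <- function(directory_or_pattern,
                            meta = grid_metadata(modality = "microct")) {
  vol <- read_image_stack(directory_or_pattern, meta)
  binary_mask((vol$intensities > 0.5) * 1, meta)
}

#' Write a 3D mask as a stack of 8-bit slice images
#'
#' One image per slice, foreground 255, background 0, zero-padded slice index
#' in the filename so lexicographic order equals slice order.
#'
#' @param mask A 3D [binary_mask()].
#' @param directory Output directory (created if missing).
#' @param prefix Filename prefix.
#' @param format `"png"` or `"tif"`.
#' @return Invisibly, the vector of written file paths.
#' @export
write_mask_stack <- function(mask, directory, prefix = "slice_", format = "png") {
  if (!inherits(mask, "cc_mask") || mask_dim(mask) != 3) {
    stop_ccm("write_mask_stack expects a 3D binary mask")
  }
  if (!dir.exists(directory)) dir.create(directory, recursive = TRUE)
  n <- dim(mask$values)[1]
  paths <- character(n)
  for (i in seq_len(n)) {
    p <- file.path(directory, sprintf("%s%04d.%s", prefix, i - 1L, format))
    ok <- tryCatch({ write_image(mask$values[i, , ], p, bits = 8); TRUE },
                   error = function(e) {
                     stop_ccm("failed writing slice %d to %s: %s",
                              i, p, conditionMessage(e))
                   })
    paths[i] <- p
  }
  invisible(paths)
}

#' Write thickness summaries as a CSV table
#'
#' @param rows A list of [summarize_thickness()] results; each element may
#'   carry `sample_id` and `region` attributes or list fields.
#' @param path Output CSV path.
#' @return Invisibly, the data frame written.
#' @export
write_summary_table <- function(rows, path) {
  df <- summary_table(rows)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(df)
}

#' Assemble thickness summaries into a data frame
#'
#' @inheritParams write_summary_table
#' @return A data frame with columns sample_id, region, n_foreground,
#'   mean_um, median_um, max_um, sd_um, pixel_size_um.
#' @export
summary_table <- function(rows) {
  cols <- c("sample_id", "region", "n_foreground", "mean_um", "median_um",
            "max_um", "sd_um", "pixel_size_um")
  if (length(rows) == 0) {
    df <- as.data.frame(setNames(rep(list(numeric(0)), length(cols)), cols))
    df$sample_id <- character(0)
    df$region <- character(0)
    return(df[cols])
  }
  do.call(rbind, lapply(rows, function(s) {
    data.frame(
      sample_id = s$sample_id %||% NA_character_,
      region = s$region %||% NA_character_,
      n_foreground = s$n_foreground,
      mean_um = s$mean_um, median_um = s$median_um,
      max_um = s$max_um, sd_um = s$sd_um,
      pixel_size_um = s$pixel_size_um,
      stringsAsFactors = FALSE
    )
  }))
}
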