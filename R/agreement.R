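#' Dice score between two binary masks
#'
#' `2|A n B| / (|A| + |B|)`. Two empty masks agree perfectly (Dice 1) by
#' convention.
#'
#' @param a,b [binary_mask()] objects or plain 0/1 arrays of equal shape.
#' @return Dice score in `[0, 1]`.
#' @export
dice_score <- function(a, b) {
  va <- if (inherits(a, "cc_mask")) a$values else a
  vb <- if (inherits(b, "cc_mask")) b$values else b
  if (!identical(dim(va), dim(vb))) stop_ccm("dice_score: shape mismatch")
  sa <- sum(va); sb <- sum(vb)
  if (sa + sb == 0) return(1)
  2 * sum(va * vb) / (sa + sb)
}

#' Two-tailed Pearson correlation
#'
#' Sample correlation with the two-tailed p-value from the t transform
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (as computed by [stats::cor.test()]).
#'
#' @param x,y Numeric vectors of equal length, `n >= 3`, non-zero variance.
#' @return A list with `r` and `p_two_tailed`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop_ccm("pearson_cor: length mismatch")
  if (length(x) < 3) stop_ccm("pearson_cor: need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop_ccm("pearson_cor: zero variance in input")
  }
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p_two_tailed = ct$p.value)
}

#' Bland-Altman method agreement
#'
#' For paired measurements a and b, the differences `d = a - b` give the
#' bias (mean difference), the SD of differences (sample SD, n-1
#' denominator), and the 95% limits of agreement `bias +/- 1.96 * SD`.
#' When `n >= 3`, the Pearson correlation of a with b is included.
#'
#' @param a,b Numeric vectors of equal length, `n >= 2`.
#' @return A list of class `cc_agreement`: `bias`, `sd_diff`, `loa_low`,
#'   `loa_high`, `n`, and (when defined) `r`, `p_two_tailed`.
#' @export
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 18, 33))  # bias -1, sd sqrt(7)
bland_altman <- function(a, b) {
  if (length(a) != length(b)) stop_ccm("bland_altman: length mismatch")
  if (length(a) < 2) stop_ccm("bland_altman: need n >= 2")
  d <- a - b
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  res <- list(bias = bias, sd_diff = sd_diff,
              loa_low = bias - 1.96 * sd_diff,
              loa_high = bias + 1.96 * sd_diff,
              n = length(a), r = NA_real_, p_two_tailed = NA_real_)
  if (length(a) >= 3 && stats::sd(a) > 0 && stats::sd(b) > 0) {
    pc <- pearson_cor(a, b)
    res$r <- pc$r
    res$p_two_tailed <- pc$p_two_tailed
  }
  structure(res, class = "cc_agreement")
}

#' Out-of-fold validation report
#'
#' Compares predicted masks with their gold-standard counterparts: the
#' per-image Dice is averaged within each sample and then over samples, and
#' per-sample mean thickness from predicted vs truth masks is fed to a
#' Pearson correlation (when it is defined).
#'
#' @param predictions Named list of predicted [binary_mask()]s (or 0/1
#'   arrays), one per image.
#' @param truths Named list of gold-standard masks with the same names.
#' @param grouping Character vector mapping each image name to a sample id
#'   (same names as `predictions`); defaults to one sample per image.
#' @param pixel_size_um Pixel size used for the thickness correlation.
#' @return A list with `per_image` (data frame: image, sample, dice),
#'   `per_sample` (data frame: sample, dice, mean_th_pred_um,
#'   mean_th_truth_um), `mean_dice`, `thickness_r`, `thickness_p`, and
#'   `thickness_constant` (TRUE when the correlation is undefined because
#'   thickness does not vary across samples).
#' @export
out_of_fold_report <- function(predictions, truths, grouping = NULL,
                               pixel_size_um = 2.56) {
  nms <- names(predictions)
  if (is.null(nms) || !setequal(nms, names(truths))) {
    stop_ccm("out_of_fold_report: predictions and truths must share names")
  }
  if (is.null(grouping)) grouping <- setNames(nms, nms)
  if (!all(nms %in% names(grouping))) {
    stop_ccm("out_of_fold_report: unpaired sample in grouping")
  }
  meta <- grid_metadata(pixel_size_um, "histology")
  per_image <- data.frame(
    image = nms,
    sample = unname(grouping[nms]),
    dice = vapply(nms, function(n) dice_score(predictions[[n]], truths[[n]]),
                  numeric(1)),
    stringsAsFactors = FALSE
  )
  th_mean <- function(m) {
    v <- if (inherits(m, "cc_mask")) m$values else m
    if (sum(v) == 0) return(NA_real_)
    summarize_thickness(local_thickness(binary_mask(v, meta)))$mean_um
  }
  per_image$th_pred <- vapply(nms, function(n) th_mean(predictions[[n]]), numeric(1))
  per_image$th_truth <- vapply(nms, function(n) th_mean(truths[[n]]), numeric(1))
  agg <- function(col) tapply(per_image[[col]], per_image$sample, mean)
  per_sample <- data.frame(
    sample = names(agg("dice")),
    dice = as.numeric(agg("dice")),
    mean_th_pred_um = as.numeric(agg("th_pred")),
    mean_th_truth_um = as.numeric(agg("th_truth")),
    stringsAsFactors = FALSE
  )
  mean_dice <- mean(per_sample$dice)
  ok <- stats::complete.cases(per_sample[, c("mean_th_pred_um", "mean_th_truth_um")])
  r <- NA_real_; p <- NA_real_; constant <- FALSE
  if (sum(ok) >= 3) {
    x <- per_sample$mean_th_truth_um[ok]
    y <- per_sample$mean_th_pred_um[ok]
    if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      constant <- TRUE
    } else {
      pc <- pearson_cor(x, y)
      r <- pc$r; p <- pc$p_two_tailed
    }
  }
  list(per_image = per_image[, c("image", "sample", "dice")],
       per_sample = per_sample, mean_dice = mean_dice,
       thickness_r = r, thickness_p = p, thickness_constant = constant)
}
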