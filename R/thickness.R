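#' Exact squared Euclidean distance transform
#'
#' For every foreground element, the squared Euclidean distance to the nearest
#' background element centre. Everything outside the image is treated as
#' background (the grid is conceptually surrounded by a background layer), so
#' distances near the border are limited by the border.
#'
#' Values are exact integers (sums of squared integer offsets), computed by a
#' per-axis scan over all displacements; this exactness is what allows the
#' strict-inequality comparisons in [local_thickness()] to be unambiguous.
#'
#' @param mask Numeric/logical matrix or 3D array; non-zero = foreground.
#' @return An array of the same shape with squared distances (0 on background).
#' @export
#' @examples
#' m <- matrix(1, 5, 5)
#' sqedt(m)[3, 3]  # 9: nearest outside-the-grid background centre is 3 away
sqedt <- function(mask) {
  d <- dim(mask)
  if (is.null(d)) stop_ccm("mask must be a matrix or 3D array")
  # one-layer background pad realises the outside-is-background convention
  dp <- d + 2L
  D <- array(Inf, dim = dp)
  idx <- lapply(d, function(n) 1L + seq_len(n))
  D <- do.call(`[<-`, c(list(D), idx, list(ifelse(mask != 0, Inf, 0))))
  # set pad ring to 0
  ring <- array(TRUE, dim = dp)
  ring <- do.call(`[<-`, c(list(ring), idx, list(FALSE)))
  D[ring] <- 0
  # per-axis exact 1D distance transform by scanning all displacements;
  # squared Euclidean distance is separable so sequential axis passes are exact
  for (ax in seq_along(dp)) {
    n <- dp[ax]
    Dn <- D
    for (k in seq_len(n - 1L)) {
      k2 <- k * k
      # once k^2 exceeds every current value, larger offsets cannot improve
      if (!anyNA(Dn) && !any(is.infinite(Dn)) && k2 > max(Dn)) break
      Dn <- pmin(Dn, shift_array(D, ax, k, fill = Inf) + k2)
      Dn <- pmin(Dn, shift_array(D, ax, -k, fill = Inf) + k2)
    }
    D <- Dn
  }
  out <- do.call(`[`, c(list(D), idx, list(drop = FALSE)))
  if (length(d) == 2) dim(out) <- d
  out
}

# coordinates of foreground elements as an n x ndim integer matrix
fg_coords <- function(mask) {
  which(mask != 0, arr.ind = TRUE)
}

#' Local thickness by discrete circle/sphere fitting
#'
#' Implements the Hildebrand-Ruegsegger definition on the discrete grid: the
#' thickness at a foreground element p is the diameter of the largest
#' inscribed disc (2D) or sphere (3D) that contains p and lies fully inside
#' the structure. Concretely, with `EDT(c)` the Euclidean distance from c to
#' the nearest background element centre (outside the image counts as
#' background),
#'
#'   tau(p) = 2 * max( EDT(c) : c foreground, ||p - c|| < EDT(c) )
#'
#' The implementation reduces candidate centres to the distance ridge by an
#' exact ball-containment test (a centre is dropped only when its ball is
#' contained in a retained neighbour's ball), then paints the surviving balls
#' in decreasing radius order. The result is identical -- bitwise -- to the
#' brute-force definition in [brute_force_thickness()].
#'
#' @param mask A [binary_mask()] or plain 0/1 matrix / 3D array with at least
#'   one foreground element.
#' @param meta [grid_metadata()] carried to the output (taken from the mask
#'   when it is a `cc_mask`).
#' @return A list of class `cc_thickness_map`: `values` (thickness in pixels,
#'   0 on background) and `meta`.
#' @export
local_thickness <- function(mask, meta = NULL) {
  v <- if (inherits(mask, "cc_mask")) mask$values else mask
  meta <- meta %||% (if (inherits(mask, "cc_mask")) mask$meta else grid_metadata())
  if (sum(v) == 0) stop_ccm("local_thickness: mask has no foreground")
  d <- dim(v)
  r2 <- sqedt(v)
  keep <- ridge_candidates(v, r2)
  cand <- which(keep, arr.ind = TRUE)
  cr2 <- r2[keep]
  ord <- order(cr2, decreasing = TRUE)
  cand <- cand[ord, , drop = FALSE]
  cr2 <- cr2[ord]
  tau2 <- array(0, dim = d)
  offs_cache <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(cand))) {
    tau2 <- paint_ball(tau2, cand[i, ], cr2[i], d, offs_cache)
  }
  vals <- 2 * sqrt(tau2)
  vals[v == 0] <- 0
  structure(list(values = vals, meta = meta), class = "cc_thickness_map")
}

# Drop candidate c when a 1-neighbourhood element c' has
#   sqrt(r2') >= sqrt(r2) + ||e||   (ball containment, exact integer test).
# Dominance forces r2' > r2 strictly, so removing all dominated candidates at
# once cannot remove a whole chain.
ridge_candidates <- function(v, r2) {
  d <- dim(v)
  nd <- length(d)
  keep <- v != 0
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  for (i in seq_len(nrow(offs))) {
    e <- offs[i, ]
    e2 <- sum(e * e)
    r2n <- r2
    for (ax in seq_len(nd)) {
      if (e[ax] != 0) r2n <- shift_array(r2n, ax, -e[ax], fill = 0)
    }
    # containment: r2n >= r2 + e2 + 2*sqrt(r2*e2), tested in exact integers
    lhs <- r2n - r2 - e2
    dom <- lhs >= 0 & (lhs * lhs >= 4 * r2 * e2) & r2n > 0
    keep <- keep & !dom
  }
  keep & (v != 0)
}

# tau2[p] <- max(tau2[p], r2) for all p with ||p - centre||^2 < r2
paint_ball <- function(tau2, centre, r2, d, cache) {
  key <- as.character(r2)
  offs <- cache[[key]]
  if (is.null(offs)) {
    rr <- ceiling(sqrt(r2)) - 1L  # strict inequality: offsets with ||o||^2 < r2
    g <- expand.grid(rep(list(seq.int(-rr, rr)), length(d)))
    g <- as.matrix(g)
    g <- g[rowSums(g * g) < r2, , drop = FALSE]
    offs <- g
    cache[[key]] <- offs
  }
  pts <- sweep(offs, 2, centre, `+`)
  inb <- rep(TRUE, nrow(pts))
  for (ax in seq_along(d)) {
    inb <- inb & pts[, ax] >= 1L & pts[, ax] <= d[ax]
  }
  pts <- pts[inb, , drop = FALSE]
  if (length(d) == 2) {
    lin <- pts[, 1] + (pts[, 2] - 1L) * d[1]
  } else {
    lin <- pts[, 1] + (pts[, 2] - 1L) * d[1] + (pts[, 3] - 1L) * d[1] * d[2]
  }
  tau2[lin] <- pmax(tau2[lin], r2)
  tau2
}

#' Brute-force local thickness (verification oracle)
#'
#' A literal evaluation of the discrete definition in [local_thickness()]:
#' for every foreground centre c, every foreground element p with
#' `||p - c|| < EDT(c)` receives at least `2 * EDT(c)`. Quadratic in the
#' foreground size; guarded to at most `max_fg` foreground elements.
#'
#' @inheritParams local_thickness
#' @param max_fg Guard on the foreground size.
#' @return A `cc_thickness_map`, bitwise-identical to [local_thickness()].
#' @export
brute_force_thickness <- function(mask, meta = NULL, max_fg = 10000) {
  v <- if (inherits(mask, "cc_mask")) mask$values else mask
  meta <- meta %||% (if (inherits(mask, "cc_mask")) mask$meta else grid_metadata())
  if (sum(v) == 0) stop_ccm("brute_force_thickness: mask has no foreground")
  fg <- fg_coords(v)
  if (nrow(fg) > max_fg) {
    stop_ccm("foreground size %d exceeds oracle guard %d", nrow(fg), max_fg)
  }
  r2 <- sqedt(v)
  cr2 <- r2[fg]
  tau2 <- numeric(nrow(fg))
  for (i in seq_len(nrow(fg))) {
    dd <- rep(0, nrow(fg))
    for (ax in seq_len(ncol(fg))) {
      dd <- dd + (fg[, ax] - fg[i, ax])^2
    }
    covered <- dd < cr2[i]
    tau2[covered] <- pmax(tau2[covered], cr2[i])
  }
  out <- array(0, dim = dim(v))
  out[fg] <- 2 * sqrt(tau2)
  structure(list(values = out, meta = meta), class = "cc_thickness_map")
}

#' Summary statistics of a thickness map
#'
#' Statistics are taken over foreground elements only and converted to
#' micrometres with the map's pixel size. The standard deviation is the
#' population SD over foreground elements.
#'
#' @param tmap A `cc_thickness_map` from [local_thickness()].
#' @param sample_id,region Optional labels carried into summary tables.
#' @return A list of class `cc_thickness_summary` with `mean_um`,
#'   `median_um`, `max_um`, `sd_um`, `n_foreground`, `pixel_size_um`.
#' @export
summarize_thickness <- function(tmap, sample_id = NULL, region = NULL) {
  px <- tmap$meta$pixel_size_um
  vals <- tmap$values[tmap$values > 0]
  if (length(vals) == 0) stop_ccm("summarize_thickness: empty thickness map")
  um <- vals * px
  structure(list(
    mean_um = mean(um),
    median_um = stats::median(um),
    max_um = max(um),
    sd_um = sqrt(mean((um - mean(um))^2)),
    n_foreground = length(vals),
    pixel_size_um = px,
    sample_id = sample_id,
    region = region
  ), class = "cc_thickness_summary")
}

#' Per-sample mean thickness across sections/slices
#'
#' Thickness values from multiple histology sections or uCT slices of the
#' same sample are combined as the unweighted mean of the per-section means.
#'
#' @param per_slice List of `cc_thickness_summary` objects.
#' @return Mean of the per-slice `mean_um` values, in um.
#' @export
sample_mean_thickness <- function(per_slice) {
  if (length(per_slice) == 0) stop_ccm("sample_mean_thickness: empty list")
  mean(vapply(per_slice, function(s) s$mean_um, numeric(1)))
}
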