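#' Connected-component labelling of a binary mask
#'
#' Components are found on the voxel adjacency graph (8-neighbourhood in 2D,
#' 26-neighbourhood in 3D by default; 4/6 when `connectivity = "minimal"`).
#'
#' @param mask [binary_mask()] or plain 0/1 matrix / 3D array.
#' @param connectivity `"maximal"` (8 / 26) or `"minimal"` (4 / 6).
#' @return Integer array of the mask's shape: 0 on background, component id
#'   (1-based, in order of first linear index) on foreground.
#' @export
label_components <- function(mask, connectivity = c("maximal", "minimal")) {
  connectivity <- match.arg(connectivity)
  v <- if (inherits(mask, "cc_mask")) mask$values else mask
  d <- dim(v)
  nd <- length(d)
  lab <- array(0L, dim = d)
  fg <- which(v != 0)
  if (length(fg) == 0) return(lab)
  # vertex id = rank of the linear index among foreground elements
  vid <- array(0L, dim = d)
  vid[fg] <- seq_along(fg)
  offs <- as.matrix(expand.grid(rep(list(-1:1), nd)))
  offs <- offs[rowSums(offs != 0) > 0, , drop = FALSE]
  if (connectivity == "minimal") {
    offs <- offs[rowSums(offs != 0) == 1, , drop = FALSE]
  }
  # keep one direction of each offset pair (undirected edges)
  first_nz <- apply(offs, 1, function(o) o[which(o != 0)[1]])
  offs <- offs[first_nz > 0, , drop = FALSE]
  edges <- integer(0)
  for (i in seq_len(nrow(offs))) {
    o <- offs[i, ]
    nb <- vid
    for (ax in seq_len(nd)) {
      if (o[ax] != 0) nb <- shift_array(nb, ax, o[ax], fill = 0L)
    }
    pair <- vid != 0L & nb != 0L
    if (any(pair)) edges <- c(edges, rbind(vid[pair], nb[pair]))
  }
  g <- igraph::make_graph(edges, n = length(fg), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber components by their first (smallest) linear foreground index
  firsts <- tapply(seq_along(fg), comp, min)
  ids <- as.integer(names(firsts))
  renum <- integer(max(ids))
  renum[ids[order(firsts)]] <- seq_along(ids)
  lab[fg] <- renum[comp]
  lab
}

#' Remove small connected regions from a 2D mask
#'
#' Components with fewer than `min_size` pixels are removed; components of
#' size `min_size` or larger are kept, so large but disconnected pieces of
#' the calcified cartilage layer survive. "Smaller than" is strict: a
#' component of exactly `min_size` pixels survives.
#'
#' @param mask 2D [binary_mask()] (or 0/1 matrix).
#' @param min_size Minimum surviving component size in pixels (default 500).
#' @param connectivity Passed to [label_components()].
#' @return A mask of the same type as the input.
#' @export
remove_small_regions <- function(mask, min_size = 500, connectivity = "maximal") {
  v <- if (inherits(mask, "cc_mask")) mask$values else mask
  lab <- label_components(v, connectivity)
  if (max(lab) == 0) return(mask)
  sizes <- tabulate(lab[lab > 0])
  keep_ids <- which(sizes >= min_size)
  out <- (lab %in% keep_ids) * 1
  dim(out) <- dim(v)
  rewrap_mask(mask, out)
}

#' Keep only the largest connected component (sweep)
#'
#' Retains the component with the greatest element count, removing false
#' positives far from the calcified cartilage layer. Ties are broken by the
#' smallest first linear (slice, row, column) coordinate, deterministically.
#'
#' @param mask [binary_mask()] (2D or 3D) or plain 0/1 array.
#' @param connectivity Passed to [label_components()].
#' @return A mask of the same type as the input.
#' @export
keep_largest_component <- function(mask, connectivity = "maximal") {
  v <- if (inherits(mask, "cc_mask")) mask$values else mask
  lab <- label_components(v, connectivity)
  if (max(lab) == 0) {
    warning("keep_largest_component: empty mask")
    return(mask)
  }
  sizes <- tabulate(lab[lab > 0])
  # which.max returns the first maximum; labels are ordered by first linear
  # coordinate, so ties resolve to the lexicographically smallest component
  big <- which.max(sizes)
  out <- (lab == big) * 1
  dim(out) <- dim(v)
  rewrap_mask(mask, out)
}

#' Binary median (majority) filter with a Euclidean disc/ball footprint
#'
#' Each element is replaced by the majority value within the disc (2D) or
#' ball (3D) of the given radius, `||d|| <= radius`. Boundaries are handled
#' by reflection. An exact 50/50 split resolves to foreground, which avoids
#' eroding thin structures. Counting is done by FFT convolution with the
#' binary footprint and rounded back to exact integers.
#'
#' @param mask [binary_mask()] (2D or 3D) or plain 0/1 array.
#' @param radius_px Footprint radius in pixels (default 12); 0 is identity.
#' @return A mask of the same type as the input.
#' @export
median_filter_mask <- function(mask, radius_px = 12) {
  v <- if (inherits(mask, "cc_mask")) mask$values else mask
  if (radius_px < 0) stop_ccm("radius must be >= 0")
  if (radius_px == 0) return(mask)
  d <- dim(v)
  r <- as.integer(radius_px)
  nd <- length(d)
  g <- as.matrix(expand.grid(rep(list(seq.int(-r, r)), nd)))
  inside <- rowSums(g * g) <= r * r
  m <- sum(inside)
  counts <- fft_count(v, g[inside, , drop = FALSE], r)
  out <- (2 * counts >= m) * 1
  dim(out) <- d
  rewrap_mask(mask, out)
}

# Count foreground elements of `v` within the footprint (offset list `offs`)
# around every element, with reflective boundary, via FFT convolution.
fft_count <- function(v, offs, r) {
  d <- dim(v)
  vp <- pad_reflect(v, r)
  dp <- dim(vp)
  K <- array(0, dim = dp)
  # place footprint wrapped around the origin so circular convolution aligns
  for (i in seq_len(nrow(offs))) {
    pos <- ((as.integer(offs[i, ]) %% dp) + dp) %% dp + 1L
    K <- do.call(`[<-`, c(list(K), as.list(pos), list(1)))
  }
  Fv <- stats::fft(vp)
  Fk <- stats::fft(K)
  conv <- Re(stats::fft(Fv * Conj(Fk), inverse = TRUE)) / prod(dp)
  counts <- crop_pad(conv, r, d)
  round(counts)
}

rewrap_mask <- function(template, values) {
  if (inherits(template, "cc_mask")) binary_mask(values, template$meta) else values
}
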