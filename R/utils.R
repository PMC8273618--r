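#' @keywords internal
"_PACKAGE"

# Shift an array along one axis by k (positive = towards higher indices),
# filling vacated positions with `fill`. Used by the exact distance transform
# and the neighbourhood scans; works for matrices and 3D arrays.
shift_array <- function(x, axis, k, fill = Inf) {
  d <- dim(x)
  if (is.null(d)) d <- length(x)
  n <- d[axis]
  if (k == 0) return(x)
  out <- array(fill, dim = d)
  src <- seq_len(n - abs(k))
  if (k > 0) {
    idx_to <- src + k
    idx_from <- src
  } else {
    idx_to <- src
    idx_from <- src - k
  }
  ix_to <- rep(list(quote(expr = )), length(d))
  ix_from <- ix_to
  ix_to[[axis]] <- idx_to
  ix_from[[axis]] <- idx_from
  out <- do.call(`[<-`, c(list(out), ix_to, list(do.call(`[`, c(list(x), ix_from, list(drop = FALSE))))))
  out
}

# Map arbitrary integer positions onto 1..n by mirror reflection about the
# edges (triangle wave of period 2n-2, border not duplicated).
reflect_index <- function(j, n) {
  if (n == 1L) return(rep(1L, length(j)))
  m <- (j - 1L) %% (2L * n - 2L)
  ifelse(m < n, m + 1L, 2L * n - 1L - m)
}

# Pad an array by `r` on every side of every dimension, by reflection.
pad_reflect <- function(x, r) {
  d <- dim(x)
  idx <- lapply(d, function(n) reflect_index(seq.int(1L - r, n + r), n))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

# Crop the central region after padding by r.
crop_pad <- function(x, r, d_orig) {
  idx <- lapply(d_orig, function(n) r + seq_len(n))
  do.call(`[`, c(list(x), idx, list(drop = FALSE)))
}

stop_ccm <- function(...) stop(sprintf(...), call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

is_binary <- function(x) all(x %in% c(0, 1))
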