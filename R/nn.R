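# Compact CNN engine: reverse-mode autodiff over a small set of image ops.
# Tensors are 4D arrays [H, W, C, N]. A forward pass records nodes on a tape;
# tape_backward() walks it in reverse accumulating parameter gradients.
# Convolutions are im2col + BLAS matrix multiply.

new_tape <- function(train = FALSE) {
  e <- new.env(parent = emptyenv())
  e$vals <- list()
  e$nodes <- list()
  e$train <- train
  e$n <- 0L
  e
}

tp_push <- function(tape, val, op, inputs = integer(0), pname = NULL, cache = NULL) {
  tape$n <- tape$n + 1L
  tape$vals[[tape$n]] <- val
  tape$nodes[[tape$n]] <- list(op = op, inputs = inputs, pname = pname,
                               cache = cache)
  tape$n
}

tp_input <- function(tape, x) tp_push(tape, x, "input")

as_t4 <- function(x) {
  if (is.matrix(x)) dim(x) <- c(dim(x), 1L, 1L)
  x
}

# ---- convolution ------------------------------------------------------------

im2col3 <- function(x) {
  d <- dim(x); H <- d[1]; W <- d[2]; Ci <- d[3]; N <- d[4]
  xp <- array(0, dim = c(H + 2L, W + 2L, Ci, N))
  xp[1L + seq_len(H), 1L + seq_len(W), , ] <- x
  P <- matrix(0, H * W * N, 9L * Ci)
  kk <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    kk <- kk + 1L
    blk <- aperm(xp[dr + seq_len(H), dc + seq_len(W), , , drop = FALSE],
                 c(1, 2, 4, 3))
    P[, (kk - 1L) * Ci + seq_len(Ci)] <- matrix(blk, H * W * N, Ci)
  }
  P
}

col2im3 <- function(dP, H, W, Ci, N) {
  dxp <- array(0, dim = c(H + 2L, W + 2L, Ci, N))
  kk <- 0L
  for (dc in 0:2) for (dr in 0:2) {
    kk <- kk + 1L
    blk <- aperm(array(dP[, (kk - 1L) * Ci + seq_len(Ci)], dim = c(H, W, N, Ci)),
                 c(1, 2, 4, 3))
    dxp[dr + seq_len(H), dc + seq_len(W), , ] <-
      dxp[dr + seq_len(H), dc + seq_len(W), , , drop = FALSE] + blk
  }
  dxp[1L + seq_len(H), 1L + seq_len(W), , , drop = FALSE]
}

# pname refers to params[[pname]] = list(W = [k2*Ci, Co], b = [Co])
tp_conv <- function(tape, params, id, pname, k = 3L) {
  force(id)
  x <- tape$vals[[id]]
  d <- dim(x); H <- d[1]; W <- d[2]; Ci <- d[3]; N <- d[4]
  P <- if (k == 1L) matrix(aperm(x, c(1, 2, 4, 3)), H * W * N, Ci) else im2col3(x)
  pr <- params[[pname]]
  out <- P %*% pr$W
  out <- out + rep(pr$b, each = H * W * N)
  Co <- length(pr$b)
  y <- aperm(array(out, dim = c(H, W, N, Co)), c(1, 2, 4, 3))
  cache <- list(k = k, xdim = d)
  if (tape$train) cache$P <- P
  tp_push(tape, y, "conv", id, pname, cache)
}

bw_conv <- function(node, dy, params) {
  d <- node$cache$xdim; H <- d[1]; W <- d[2]; Ci <- d[3]; N <- d[4]
  Co <- dim(dy)[3]
  dYf <- matrix(aperm(dy, c(1, 2, 4, 3)), H * W * N, Co)
  pr <- params[[node$pname]]
  dW <- crossprod(node$cache$P, dYf)
  db <- colSums(dYf)
  dP <- dYf %*% t(pr$W)
  dx <- if (node$cache$k == 1L) {
    aperm(array(dP, dim = c(H, W, N, Ci)), c(1, 2, 4, 3))
  } else {
    col2im3(dP, H, W, Ci, N)
  }
  list(dinputs = list(dx), dparams = setNames(list(list(W = dW, b = db)),
                                              node$pname))
}

# ---- elementwise ------------------------------------------------------------

tp_relu <- function(tape, id) {
  force(id)  # inner calls may grow the tape before we read it
  x <- tape$vals[[id]]
  y <- pmax(x, 0)
  tp_push(tape, y, "relu", id, cache = if (tape$train) (x > 0))
}

bw_relu <- function(node, dy, params) list(dinputs = list(dy * node$cache))

tp_sigmoid <- function(tape, id) {
  force(id)
  y <- 1 / (1 + exp(-tape$vals[[id]]))
  tp_push(tape, y, "sigmoid", id, cache = if (tape$train) y)
}

bw_sigmoid <- function(node, dy, params) {
  y <- node$cache
  list(dinputs = list(dy * y * (1 - y)))
}

tp_add <- function(tape, id1, id2) {
  force(id1); force(id2)
  tp_push(tape, tape$vals[[id1]] + tape$vals[[id2]], "add", c(id1, id2))
}

bw_add <- function(node, dy, params) list(dinputs = list(dy, dy))

tp_concat <- function(tape, id1, id2) {
  force(id1); force(id2)
  a <- tape$vals[[id1]]; b <- tape$vals[[id2]]
  d <- dim(a)
  y <- array(0, dim = c(d[1], d[2], d[3] + dim(b)[3], d[4]))
  y[, , seq_len(d[3]), ] <- a
  y[, , d[3] + seq_len(dim(b)[3]), ] <- b
  tp_push(tape, y, "concat", c(id1, id2), cache = c(d[3], dim(b)[3]))
}

bw_concat <- function(node, dy, params) {
  c1 <- node$cache[1]; c2 <- node$cache[2]
  list(dinputs = list(dy[, , seq_len(c1), , drop = FALSE],
                      dy[, , c1 + seq_len(c2), , drop = FALSE]))
}

# ---- resampling -------------------------------------------------------------

tp_pool2 <- function(tape, id) {
  force(id)
  x <- tape$vals[[id]]
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stop_ccm("pool2: odd spatial size %dx%d", d[1], d[2])
  ir <- list(seq(1L, d[1], 2L), seq(2L, d[1], 2L))
  ic <- list(seq(1L, d[2], 2L), seq(2L, d[2], 2L))
  s <- vector("list", 4L)
  kk <- 0L
  for (a in 1:2) for (b in 1:2) {
    kk <- kk + 1L
    s[[kk]] <- x[ir[[a]], ic[[b]], , , drop = FALSE]
  }
  y <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  tp_push(tape, y, "pool2", id,
          cache = if (tape$train) list(s = s, y = y, xdim = d))
}

bw_pool2 <- function(node, dy, params) {
  ca <- node$cache
  d <- ca$xdim
  dx <- array(0, dim = d)
  assigned <- array(FALSE, dim = dim(ca$y))
  ir <- list(seq(1L, d[1], 2L), seq(2L, d[1], 2L))
  ic <- list(seq(1L, d[2], 2L), seq(2L, d[2], 2L))
  kk <- 0L
  for (a in 1:2) for (b in 1:2) {
    kk <- kk + 1L
    sel <- (ca$s[[kk]] == ca$y) & !assigned
    dx[ir[[a]], ic[[b]], , ] <- dy * sel
    assigned <- assigned | sel
  }
  list(dinputs = list(dx))
}

tp_up2 <- function(tape, id) {
  force(id)
  x <- tape$vals[[id]]
  d <- dim(x)
  y <- x[rep(seq_len(d[1]), each = 2L), rep(seq_len(d[2]), each = 2L), , ,
         drop = FALSE]
  tp_push(tape, y, "up2", id, cache = d)
}

bw_up2 <- function(node, dy, params) {
  d <- node$cache
  dd <- dim(dy)
  dx <- dy[seq(1L, dd[1], 2L), seq(1L, dd[2], 2L), , , drop = FALSE] +
        dy[seq(2L, dd[1], 2L), seq(1L, dd[2], 2L), , , drop = FALSE] +
        dy[seq(1L, dd[1], 2L), seq(2L, dd[2], 2L), , , drop = FALSE] +
        dy[seq(2L, dd[1], 2L), seq(2L, dd[2], 2L), , , drop = FALSE]
  list(dinputs = list(dx))
}

# ---- normalization ----------------------------------------------------------

# batch: statistics over (H, W, N) per channel, with running stats for eval;
# instance: statistics over (H, W) per (channel, sample), no running stats.
tp_norm <- function(tape, params, id, pname, type, state, eps = 1e-5,
                    momentum = 0.1) {
  force(id)
  x <- tape$vals[[id]]
  d <- dim(x); H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  pr <- params[[pname]]
  if (type == "batch") {
    xm <- matrix(aperm(x, c(1, 2, 4, 3)), H * W * N, C)
    if (tape$train) {
      mu <- colMeans(xm)
      va <- colMeans(xm^2) - mu^2
      st <- state[[pname]]
      if (is.null(st)) st <- list(mean = mu * 0, var = mu * 0 + 1)
      st$mean <- (1 - momentum) * st$mean + momentum * mu
      st$var <- (1 - momentum) * st$var + momentum * va
      state[[pname]] <- st
    } else {
      st <- state[[pname]]
      mu <- if (is.null(st)) rep(0, C) else st$mean
      va <- if (is.null(st)) rep(1, C) else st$var
    }
    sd_ <- sqrt(va + eps)
    xhat <- sweep(sweep(xm, 2, mu), 2, sd_, `/`)
    ym <- sweep(sweep(xhat, 2, pr$gamma, `*`), 2, pr$beta, `+`)
    y <- aperm(array(ym, dim = c(H, W, N, C)), c(1, 2, 4, 3))
    cache <- if (tape$train) list(type = type, xhat = xhat, sd = sd_, d = d)
  } else {
    xm <- matrix(x, H * W, C * N)
    mu <- colMeans(xm)
    va <- colMeans(xm^2) - mu^2
    sd_ <- sqrt(va + eps)
    xhat <- sweep(sweep(xm, 2, mu), 2, sd_, `/`)
    gam <- rep(pr$gamma, times = N)
    bet <- rep(pr$beta, times = N)
    ym <- sweep(sweep(xhat, 2, gam, `*`), 2, bet, `+`)
    y <- array(ym, dim = d)
    cache <- if (tape$train) list(type = type, xhat = xhat, sd = sd_, d = d)
  }
  tp_push(tape, y, "norm", id, pname, cache)
}

bw_norm <- function(node, dy, params) {
  ca <- node$cache
  d <- ca$d; H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  pr <- params[[node$pname]]
  if (ca$type == "batch") {
    dym <- matrix(aperm(dy, c(1, 2, 4, 3)), H * W * N, C)
    dgamma <- colSums(dym * ca$xhat)
    dbeta <- colSums(dym)
    dxhat <- sweep(dym, 2, pr$gamma, `*`)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * ca$xhat)
    dxm <- sweep(sweep(dxhat, 2, m1) - sweep(ca$xhat, 2, m2, `*`),
                 2, ca$sd, `/`)
    dx <- aperm(array(dxm, dim = c(H, W, N, C)), c(1, 2, 4, 3))
  } else {
    dym <- matrix(dy, H * W, C * N)
    dgamma <- rowSums(matrix(colSums(dym * ca$xhat), C, N))
    dbeta <- rowSums(matrix(colSums(dym), C, N))
    gam <- rep(pr$gamma, times = N)
    dxhat <- sweep(dym, 2, gam, `*`)
    m1 <- colMeans(dxhat)
    m2 <- colMeans(dxhat * ca$xhat)
    dxm <- sweep(sweep(dxhat, 2, m1) - sweep(ca$xhat, 2, m2, `*`), 2, ca$sd, `/`)
    dx <- array(dxm, dim = d)
  }
  list(dinputs = list(dx),
       dparams = setNames(list(list(gamma = dgamma, beta = dbeta)), node$pname))
}

# ---- spatial dropout --------------------------------------------------------

tp_spatial_dropout <- function(tape, id, rate) {
  force(id)
  x <- tape$vals[[id]]
  if (!tape$train || rate <= 0) return(tp_push(tape, x, "identity", id))
  d <- dim(x)
  keep <- array(rep(stats::runif(d[3] * d[4]) >= rate, each = d[1] * d[2]),
                dim = d) / (1 - rate)
  tp_push(tape, x * keep, "dropout", id, cache = keep)
}

bw_dropout <- function(node, dy, params) list(dinputs = list(dy * node$cache))
bw_identity <- function(node, dy, params) list(dinputs = list(dy))

BW_DISPATCH <- list(conv = bw_conv, relu = bw_relu, sigmoid = bw_sigmoid,
                    add = bw_add, concat = bw_concat, pool2 = bw_pool2,
                    up2 = bw_up2, norm = bw_norm, dropout = bw_dropout,
                    identity = bw_identity)

tape_backward <- function(tape, out_id, dout, params) {
  grads_v <- vector("list", tape$n)
  grads_p <- list()
  grads_v[[out_id]] <- dout
  for (i in rev(seq_len(tape$n))) {
    g <- grads_v[[i]]
    if (is.null(g)) next
    node <- tape$nodes[[i]]
    if (node$op == "input") next
    res <- BW_DISPATCH[[node$op]](node, g, params)
    for (j in seq_along(node$inputs)) {
      id <- node$inputs[j]
      grads_v[[id]] <- if (is.null(grads_v[[id]])) res$dinputs[[j]] else
        grads_v[[id]] + res$dinputs[[j]]
    }
    if (!is.null(res$dparams)) {
      for (pn in names(res$dparams)) {
        if (is.null(grads_p[[pn]])) {
          grads_p[[pn]] <- res$dparams[[pn]]
        } else {
          for (f in names(res$dparams[[pn]])) {
            grads_p[[pn]][[f]] <- grads_p[[pn]][[f]] + res$dparams[[pn]][[f]]
          }
        }
      }
    }
    grads_v[[i]] <- NULL
    tape$vals[[i]] <- NA  # release memory as we go
  }
  grads_p
}

# ---- Adam -------------------------------------------------------------------

adam_init <- function(params) {
  st <- list(t = 0L, m = list(), v = list())
  for (pn in names(params)) {
    st$m[[pn]] <- lapply(params[[pn]], function(a) a * 0)
    st$v[[pn]] <- lapply(params[[pn]], function(a) a * 0)
  }
  st
}

adam_step <- function(params, grads, st, lr = 1e-3, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  st$t <- st$t + 1L
  bc1 <- 1 - beta1^st$t
  bc2 <- 1 - beta2^st$t
  for (pn in names(grads)) {
    for (f in names(grads[[pn]])) {
      g <- grads[[pn]][[f]]
      st$m[[pn]][[f]] <- beta1 * st$m[[pn]][[f]] + (1 - beta1) * g
      st$v[[pn]][[f]] <- beta2 * st$v[[pn]][[f]] + (1 - beta2) * g * g
      mhat <- st$m[[pn]][[f]] / bc1
      vhat <- st$v[[pn]][[f]] / bc2
      params[[pn]][[f]] <- params[[pn]][[f]] - lr * mhat / (sqrt(vhat) + eps)
    }
  }
  list(params = params, state = st)
}
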