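## Minimal CNN machinery used by the counting network and the yield
## regressor.  Convolution is im2col + one BLAS matrix product; every layer
## carries a hand-derived backward pass; optimization is Adam.  Tensors are
## height x width x channel arrays (column-major), weights for a k x k
## convolution are a (k*k*C_in) x C_out matrix whose rows follow the
## as.vector order of a (k, k, C_in) patch.

.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(h, w, c, k, pad) {
  key <- paste(h, w, c, k, pad, sep = "x")
  m <- .im2col_cache[[key]]
  if (!is.null(m)) return(m)
  hp <- h + 2L * pad; wp <- w + 2L * pad
  ## output pixel (y, x) 0-based, y fastest (column-major output)
  oy <- rep(0:(h - 1L), times = w)
  ox <- rep(0:(w - 1L), each = h)
  cols <- vector("list", k * k * c)
  j <- 1L
  for (cc in 0:(c - 1L)) {
    for (dx in 0:(k - 1L)) {
      for (dy in 0:(k - 1L)) {
        cols[[j]] <- (cc * wp + ox + dx) * hp + (oy + dy) + 1L
        j <- j + 1L
      }
    }
  }
  m <- do.call(cbind, cols)
  .im2col_cache[[key]] <- m
  m
}

pad_array <- function(x, pad) {
  if (pad == 0L) return(x)
  d <- dim(x)
  out <- array(0, dim = c(d[1] + 2L * pad, d[2] + 2L * pad, d[3]))
  out[(pad + 1L):(pad + d[1]), (pad + 1L):(pad + d[2]), ] <- x
  out
}

conv_init <- function(k, c_in, c_out, seed = NULL, zero = FALSE) {
  n_in <- k * k * c_in
  w <- if (zero) matrix(0, n_in, c_out) else
    matrix(stats::rnorm(n_in * c_out, 0, sqrt(2 / n_in)), n_in, c_out)
  list(W = w, b = numeric(c_out), k = k, c_in = c_in, c_out = c_out)
}

conv_forward <- function(x, layer, pad = (layer$k - 1L) %/% 2L) {
  d <- dim(x)
  xp <- pad_array(x, pad)
  idx <- im2col_index(d[1], d[2], d[3], layer$k, pad)
  xcol <- matrix(xp[idx], nrow = nrow(idx))
  out_mat <- xcol %*% layer$W
  out_mat <- sweep(out_mat, 2L, layer$b, "+")
  list(out = array(out_mat, dim = c(d[1], d[2], layer$c_out)),
       cache = list(xcol = xcol, idx = idx, dim_in = d, pad = pad))
}

conv_backward <- function(dout, layer, cache) {
  d <- cache$dim_in
  dmat <- matrix(dout, nrow = d[1] * d[2])
  dW <- crossprod(cache$xcol, dmat)
  db <- colSums(dmat)
  dxcol <- tcrossprod(dmat, layer$W)
  hp <- d[1] + 2L * cache$pad; wp <- d[2] + 2L * cache$pad
  dxp <- numeric(hp * wp * d[3])
  for (j in seq_len(ncol(dxcol))) {
    ii <- cache$idx[, j]
    dxp[ii] <- dxp[ii] + dxcol[, j]
  }
  dxp <- array(dxp, dim = c(hp, wp, d[3]))
  dx <- if (cache$pad > 0L) {
    dxp[(cache$pad + 1L):(cache$pad + d[1]),
        (cache$pad + 1L):(cache$pad + d[2]), , drop = FALSE]
  } else dxp
  list(dx = dx, dW = dW, db = db)
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, cache = mask)
}

relu_backward <- function(dout, mask) dout * mask

## 2x2 max pooling, stride 2; input height/width must be even
maxpool_forward <- function(x) {
  d <- dim(x)
  if (d[1] %% 2L || d[2] %% 2L) stop_contract("maxpool needs even spatial size")
  ro <- seq(1L, d[1], by = 2L); co <- seq(1L, d[2], by = 2L)
  a <- x[ro, co, , drop = FALSE];       b <- x[ro + 1L, co, , drop = FALSE]
  cc <- x[ro, co + 1L, , drop = FALSE]; dd <- x[ro + 1L, co + 1L, , drop = FALSE]
  m1 <- pmax(a, b); m2 <- pmax(cc, dd)
  out <- pmax(m1, m2)
  which4 <- array(1L, dim = dim(a))
  which4[b >= a] <- 2L
  which4[(m2 > m1) & (cc >= dd)] <- 3L
  which4[(m2 > m1) & (dd > cc)] <- 4L
  list(out = out, cache = list(which4 = which4, dim_in = d))
}

maxpool_backward <- function(dout, cache) {
  d <- cache$dim_in
  dx <- array(0, dim = d)
  ro <- seq(1L, d[1], by = 2L); co <- seq(1L, d[2], by = 2L)
  w4 <- cache$which4
  sel <- function(code, dr, dc) {
    m <- dout * (w4 == code)
    dx[ro + dr, co + dc, ] <<- dx[ro + dr, co + dc, , drop = FALSE] + m
  }
  sel(1L, 0L, 0L); sel(2L, 1L, 0L); sel(3L, 0L, 1L); sel(4L, 1L, 1L)
  dx
}

linear_init <- function(n_in, n_out, seed = NULL, zero = FALSE) {
  w <- if (zero) matrix(0, n_in, n_out) else
    matrix(stats::rnorm(n_in * n_out, 0, sqrt(2 / n_in)), n_in, n_out)
  list(W = w, b = numeric(n_out))
}

linear_forward <- function(x, layer) {
  ## x: vector or matrix (batch rows)
  xm <- if (is.matrix(x)) x else matrix(x, nrow = 1L)
  list(out = sweep(xm %*% layer$W, 2L, layer$b, "+"), cache = xm)
}

linear_backward <- function(dout, layer, cache) {
  list(dx = tcrossprod(dout, layer$W),
       dW = crossprod(cache, dout),
       db = colSums(dout))
}

sigmoid <- function(x) 1 / (1 + exp(-x))

## Adam over a flat named list of parameter arrays ---------------------------

adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-3, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (is.null(g)) next
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g * g
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

## flatten/unflatten conv+linear layer params into one named list
collect_params <- function(layers) {
  out <- list()
  for (nm in names(layers)) {
    out[[paste0(nm, ".W")]] <- layers[[nm]]$W
    out[[paste0(nm, ".b")]] <- layers[[nm]]$b
  }
  out
}

assign_params <- function(layers, flat) {
  for (nm in names(layers)) {
    layers[[nm]]$W <- flat[[paste0(nm, ".W")]]
    layers[[nm]]$b <- flat[[paste0(nm, ".b")]]
  }
  layers
}
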