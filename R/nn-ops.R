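# Minimal vectorized CNN engine.
#
# Tensor layout: activations are 4-D arrays (H, W, C, N); dense activations
# are matrices (N, features). Convolutions are stride-1 with "same"
# zero-padding and odd kernels, implemented as im2col + BLAS matmul; the
# input gradient reuses the forward kernel with a flipped, in/out-transposed
# weight tensor, which is exact for this configuration.

# cache of im2col index matrices keyed by (H, W, C, k)
.im2col_cache <- new.env(parent = emptyenv())

im2col_index <- function(H, W, C, k) {
  key <- paste(H, W, C, k, sep = "x")
  got <- .im2col_cache[[key]]
  if (!is.null(got)) return(got)
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  # transposed layout: patch element (di, dj, c) fastest down rows, output
  # pixel (i, j) across columns, so per-image writes are contiguous
  base <- as.vector(outer(seq_len(H), (seq_len(W) - 1L) * Hp, "+"))
  off <- as.vector(outer(
    as.vector(outer(seq_len(k) - 1L, (seq_len(k) - 1L) * Hp, "+")),
    (seq_len(C) - 1L) * Hp * (W + 2L * p), "+"
  ))
  M <- outer(off, base, "+")
  .im2col_cache[[key]] <- M
  M
}

# x: (H, W, C, N) -> transposed patch matrix (k*k*C, H*W*N), columns grouped
# by image
im2col <- function(x, k, pad_value = 0) {
  d <- dim(x)
  H <- d[1]; W <- d[2]; C <- d[3]; N <- d[4]
  p <- (k - 1L) %/% 2L
  Hp <- H + 2L * p
  Wp <- W + 2L * p
  M <- im2col_index(H, W, C, k)
  xp <- array(pad_value, c(Hp, Wp, C, N))
  xp[p + seq_len(H), p + seq_len(W), , ] <- x
  dim(xp) <- NULL
  Pt <- matrix(0, k * k * C, H * W * N)
  span <- Hp * Wp * C
  cols <- seq_len(H * W)
  for (n in seq_len(N)) {
    Pt[, cols + (n - 1L) * H * W] <- xp[M + (n - 1L) * span]
  }
  Pt
}

# forward convolution; returns (H, W, Cout, N) plus the transposed patch
# matrix for reuse in the backward pass
conv2d_forward <- function(x, W_arr, b, keep_patches = FALSE) {
  d <- dim(x)
  k <- dim(W_arr)[1]
  Pt <- im2col(x, k)
  Wm <- matrix(W_arr, k * k * dim(W_arr)[3], dim(W_arr)[4])
  Y <- crossprod(Pt, Wm)
  Y <- Y + rep(b, each = nrow(Y))
  out <- aperm(array(Y, c(d[1], d[2], d[4], ncol(Wm))), c(1, 2, 4, 3))
  if (keep_patches) list(out = out, patches = Pt) else list(out = out)
}

conv2d_backward <- function(dout, x_patches, W_arr, x_dim, compute_dx = TRUE) {
  d <- x_dim
  k <- dim(W_arr)[1]
  Cout <- dim(W_arr)[4]
  dY <- matrix(aperm(dout, c(1, 2, 4, 3)), d[1] * d[2] * d[4], Cout)
  dW <- array(x_patches %*% dY, dim(W_arr))
  db <- colSums(dY)
  if (!compute_dx) return(list(dW = dW, db = db, dx = NULL))
  # input gradient = convolution of dout with flipped, transposed kernel
  Wt <- aperm(W_arr[k:1, k:1, , , drop = FALSE], c(1, 2, 4, 3))
  dx <- conv2d_forward(dout, Wt, rep(0, dim(Wt)[4]))$out
  list(dW = dW, db = db, dx = dx)
}

# 2x2 max-pool, stride 2; H, W even
maxpool2_forward <- function(x) {
  d <- dim(x)
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  s1 <- x[io, jo, , , drop = FALSE]
  s2 <- x[ie, jo, , , drop = FALSE]
  s3 <- x[io, je, , , drop = FALSE]
  s4 <- x[ie, je, , , drop = FALSE]
  m <- pmax(s1, s2, s3, s4)
  list(out = m, slices = list(s1, s2, s3, s4), in_dim = d)
}

maxpool2_backward <- function(dout, cache) {
  d <- cache$in_dim
  io <- seq(1L, d[1], 2L); ie <- io + 1L
  jo <- seq(1L, d[2], 2L); je <- jo + 1L
  m <- pmax(cache$slices[[1]], cache$slices[[2]],
            cache$slices[[3]], cache$slices[[4]])
  taken <- array(FALSE, dim(m))
  dx <- array(0, d)
  put <- list(list(io, jo), list(ie, jo), list(io, je), list(ie, je))
  for (s in 1:4) {
    hit <- (cache$slices[[s]] == m) & !taken  # ties routed to first slice
    taken <- taken | hit
    dx[put[[s]][[1]], put[[s]][[2]], , ] <- dout * hit
  }
  dx
}

relu_forward <- function(x) {
  mask <- x > 0
  list(out = x * mask, mask = mask)
}

dropout_forward <- function(x, rate, train) {
  if (!train || rate <= 0) return(list(out = x, mask = NULL))
  mask <- array((stats::runif(length(x)) >= rate) / (1 - rate), dim(x))
  list(out = x * mask, mask = mask)
}

dense_forward <- function(x, W, b) {
  x %*% W + rep(b, each = nrow(x))
}

dense_backward <- function(dout, x, W) {
  list(dW = crossprod(x, dout), db = colSums(dout), dx = tcrossprod(dout, W))
}

# He-uniform initialization: U(-limit, limit), limit = sqrt(6 / fan_in)
he_uniform <- function(dims, fan_in) {
  lim <- sqrt(6 / fan_in)
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Glorot-uniform: U(-limit, limit), limit = sqrt(6 / (fan_in + fan_out))
glorot_uniform <- function(dims, fan_in, fan_out) {
  lim <- sqrt(6 / (fan_in + fan_out))
  array(stats::runif(prod(dims), -lim, lim), dims)
}

# Adam update; state is a list of (m, v) mirroring the flattened param list
adam_step <- function(params, grads, state, lr, t,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  for (nm in names(grads)) {
    g <- grads[[nm]]
    if (is.null(state[[nm]])) {
      state[[nm]] <- list(m = g * 0, v = g * 0)
    }
    st <- state[[nm]]
    st$m <- beta1 * st$m + (1 - beta1) * g
    st$v <- beta2 * st$v + (1 - beta2) * g^2
    mh <- st$m / (1 - beta1^t)
    vh <- st$v / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mh / (sqrt(vh) + eps)
    state[[nm]] <- st
  }
  list(params = params, state = state)
}
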