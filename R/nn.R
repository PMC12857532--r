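# Minimal dense/convolutional/attention layer stack with manual
# backpropagation. The policy networks are small enough that plain BLAS-backed
# matrix algebra is sufficient; every layer exposes a forward that caches what
# its backward needs. Gradients are verified against finite differences in the
# test suite.

.nn_eps <- 1e-5

# ---- dense ----
dense_f <- function(x, W, b) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  list(out = x %*% W + rep(b, each = nrow(x)), x = x)
}

dense_b <- function(cache, W, dout) {
  if (is.null(dim(dout))) dout <- matrix(dout, 1)
  list(dx = tcrossprod(dout, W), dW = crossprod(cache$x, dout),
       db = colSums(dout))
}

# ---- layer normalization over features (per row) ----
layernorm_f <- function(x, g, b) {
  if (is.null(dim(x))) x <- matrix(x, 1)
  mu <- rowMeans(x)
  v <- rowMeans(x^2) - mu^2
  sd <- sqrt(v + .nn_eps)
  xh <- (x - mu) / sd  # length-nrow vectors recycle down columns: per-row ops
  n <- nrow(x)
  list(out = xh * rep(g, each = n) + rep(b, each = n), xh = xh, sd = sd)
}

layernorm_b <- function(cache, g, dout) {
  if (is.null(dim(dout))) dout <- matrix(dout, 1)
  dxh <- dout * rep(g, each = nrow(dout))
  m1 <- rowMeans(dxh)
  m2 <- rowMeans(dxh * cache$xh)
  dx <- (dxh - m1 - cache$xh * m2) / cache$sd
  list(dx = dx, dg = colSums(dout * cache$xh), db = colSums(dout))
}

# ---- batch-style normalization over rows (per channel column) ----
batchnorm_f <- function(x, g, b) {
  n <- nrow(x)
  mu <- colMeans(x)
  v <- colMeans(x^2) - mu^2
  sd <- sqrt(v + .nn_eps)
  xh <- (x - rep(mu, each = n)) * rep(1 / sd, each = n)
  list(out = xh * rep(g, each = n) + rep(b, each = n), xh = xh, sd = sd)
}

batchnorm_b <- function(cache, g, dout) {
  n <- nrow(dout)
  dxh <- dout * rep(g, each = n)
  m1 <- colMeans(dxh)
  m2 <- colMeans(dxh * cache$xh)
  dx <- (dxh - rep(m1, each = n) - cache$xh * rep(m2, each = n)) *
    rep(1 / cache$sd, each = n)
  list(dx = dx, dg = colSums(dout * cache$xh), db = colSums(dout))
}

relu_f <- function(x) list(out = pmax(x, 0), mask = x > 0)
relu_b <- function(cache, dout) dout * cache$mask

# ---- 3D convolution via im2col ----
# neighbour index table for a 3x3x3 kernel with zero padding 1; voxels are in
# column-major array order; out-of-grid neighbours map to the zero pad row
conv_index <- function(shape, stride = 1L) {
  ax <- lapply(shape, function(n) seq(1L, n, by = stride))
  out_shape <- vapply(ax, length, integer(1))
  ctr <- expand.grid(x = ax[[1]], y = ax[[2]], z = ax[[3]], KEEP.OUT.ATTRS = FALSE)
  offs <- expand.grid(ox = -1:1, oy = -1:1, oz = -1:1, KEEP.OUT.ATTRS = FALSE)
  n_out <- nrow(ctr)
  pad <- prod(shape) + 1L
  idx <- matrix(pad, n_out, 27L)
  for (o in seq_len(27L)) {
    px <- ctr$x + offs$ox[o]
    py <- ctr$y + offs$oy[o]
    pz <- ctr$z + offs$oz[o]
    ok <- px >= 1L & px <= shape[1] & py >= 1L & py <= shape[2] &
      pz >= 1L & pz <= shape[3]
    idx[ok, o] <- px[ok] + shape[1] * (py[ok] - 1L) +
      shape[1] * shape[2] * (pz[ok] - 1L)
  }
  # for a fixed offset the scatter targets are distinct (except the pad row),
  # so backward accumulation can use direct indexed assignment
  list(idx = idx, valid = idx != pad, out_shape = out_shape,
       n_in = prod(shape))
}

conv3d_f <- function(x, W, b, ci) {
  cin <- ncol(x)
  xp <- rbind(x, 0)
  xcol <- matrix(0, nrow(ci$idx), 27L * cin)
  for (o in seq_len(27L)) {
    xcol[, (o - 1L) * cin + seq_len(cin)] <- xp[ci$idx[, o], , drop = FALSE]
  }
  list(out = xcol %*% W + rep(b, each = nrow(xcol)), xcol = xcol, cin = cin)
}

conv3d_b <- function(cache, W, ci, dout, need_dx = TRUE) {
  cin <- cache$cin
  dW <- crossprod(cache$xcol, dout)
  db <- colSums(dout)
  if (!need_dx) return(list(dx = NULL, dW = dW, db = db))
  dxcol <- tcrossprod(dout, W)
  dx <- matrix(0, ci$n_in, cin)
  for (o in seq_len(27L)) {
    v <- ci$valid[, o]
    rows <- ci$idx[v, o]
    dx[rows, ] <- dx[rows, , drop = FALSE] +
      dxcol[v, (o - 1L) * cin + seq_len(cin), drop = FALSE]
  }
  list(dx = dx, dW = dW, db = db)
}

# ---- multi-head self-attention over tokens (T x d) ----
mha_f <- function(x, Wq, Wk, Wv, Wo, bo, n_heads) {
  d <- ncol(Wq)
  dh <- d / n_heads
  Q <- x %*% Wq; K <- x %*% Wk; V <- x %*% Wv
  H <- matrix(0, nrow(x), d)
  heads <- vector("list", n_heads)
  for (i in seq_len(n_heads)) {
    cols <- (i - 1) * dh + seq_len(dh)
    Z <- Q[, cols, drop = FALSE] %*% t(K[, cols, drop = FALSE]) / sqrt(dh)
    Z <- Z - apply(Z, 1, max)
    A <- exp(Z)
    A <- A / rowSums(A)
    H[, cols] <- A %*% V[, cols, drop = FALSE]
    heads[[i]] <- A
  }
  out <- H %*% Wo + rep(bo, each = nrow(x))
  list(out = out, Q = Q, K = K, V = V, H = H, heads = heads, x = x)
}

mha_b <- function(cache, Wq, Wk, Wv, Wo, n_heads, dout) {
  d <- ncol(Wq)
  dh <- d / n_heads
  dWo <- t(cache$H) %*% dout
  dbo <- colSums(dout)
  dH <- dout %*% t(Wo)
  dQ <- matrix(0, nrow(cache$x), d)
  dK <- matrix(0, nrow(cache$x), d)
  dV <- matrix(0, nrow(cache$x), d)
  for (i in seq_len(n_heads)) {
    cols <- (i - 1) * dh + seq_len(dh)
    A <- cache$heads[[i]]
    dHi <- dH[, cols, drop = FALSE]
    dV[, cols] <- t(A) %*% dHi
    dA <- dHi %*% t(cache$V[, cols, drop = FALSE])
    dZ <- (dA - rowSums(dA * A)) * A
    dQ[, cols] <- dZ %*% cache$K[, cols, drop = FALSE] / sqrt(dh)
    dK[, cols] <- t(dZ) %*% cache$Q[, cols, drop = FALSE] / sqrt(dh)
  }
  dx <- dQ %*% t(Wq) + dK %*% t(Wk) + dV %*% t(Wv)
  list(dx = dx, dWq = t(cache$x) %*% dQ, dWk = t(cache$x) %*% dK,
       dWv = t(cache$x) %*% dV, dWo = dWo, dbo = dbo)
}

softplus <- function(x) ifelse(x > 30, x, log1p(exp(pmin(x, 30))))
softplus_grad <- function(x) 1 / (1 + exp(-x))

# ---- Adam optimizer with global gradient-norm clipping ----
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0), t = 0L)
}

adam_step <- function(params, grads, state, lr = 1e-4, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 1.0) {
  gn <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(clip) && gn > clip) grads <- lapply(grads, function(g) g * clip / gn)
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    params[[nm]] <- params[[nm]] -
      lr * (state$m[[nm]] / bc1) / (sqrt(state$v[[nm]] / bc2) + eps)
  }
  list(params = params, state = state)
}

# zero-filled gradient accumulator matching a parameter list
zero_grads <- function(params) lapply(params, function(p) p * 0)

add_grads <- function(acc, g) {
  for (nm in names(g)) acc[[nm]] <- acc[[nm]] + g[[nm]]
  acc
}

scale_grads <- function(g, s) lapply(g, function(x) x * s)
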