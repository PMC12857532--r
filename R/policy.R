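#' Build a tandem policy network (MLC or MU role)
#'
#' Both networks share the same topology: a volumetric encoder (3x3x3
#' convolution, batch-normalized and rectified, a residual convolution block,
#' a strided convolution, global average pooling) extracting 3D dose/anatomy
#' features, in parallel with a vector encoder (token projection plus learned
#' positions, multi-head self-attention over the machine-parameter tokens
#' with a residual connection, layer normalization, dense stack) over the
#' current machine parameters; the two feature vectors feed a shared dense
#' trunk from which three heads branch: the action means (tanh-squashed and
#' scaled to the leaf travel range for the MLC role; softplus, hence strictly
#' positive, for the MU role), the log standard deviations (linear), and a
#' scalar state-value estimate (linear). The actor and critic share the trunk
#' and differ only in output layers.
#'
#' The MLC network acts per control point: its volumetric state is the
#' beam's-eye-view-aligned dose with PTV and OAR masks, its vector state the
#' current CP's 52 leaf positions plus MU (tokenized per leaf pair), and its
#' action head has 52 outputs. The MU network acts globally: cumulative dose
#' plus full anatomy, one token per control point (52 leaves + MU), and one
#' MU output per CP (172 with the default arc).
#'
#' Channel/width choices per scale are capacity knobs, not contract; the
#' topology and head activations are fixed.
#'
#' @param role `"mlc"` or `"mu"`.
#' @param scale `"toy"` (small filters, desk-scale grids) or `"clinical"`
#'   (48x48x128 / 48x128x128 volumetric states, 172 CPs).
#' @param vol_shape Volumetric input shape; defaults by role and scale.
#' @param n_cp Number of control points (MU output size; MU tokens).
#' @param machine A `vmat_machine` (leaf count, travel range for scaling).
#' @param seed Integer seed for parameter initialization (deterministic).
#' @param log_std_init Initial log standard deviation bias.
#' @return A `vmat_network` holding `params`, the architecture config, and
#'   cached convolution index tables.
#' @export
build_network <- function(role = c("mlc", "mu"), scale = c("toy", "clinical"),
                          vol_shape = NULL, n_cp = NULL,
                          machine = machine_model(), seed = 0,
                          log_std_init = -0.7) {
  role <- match.arg(role)
  scale <- match.arg(scale)
  np <- machine$leaf_pairs
  if (is.null(n_cp)) n_cp <- if (scale == "clinical") 172L else 24L
  if (is.null(vol_shape)) {
    vol_shape <- if (scale == "clinical") {
      if (role == "mlc") c(48L, 48L, 128L) else c(48L, 128L, 128L)
    } else c(16L, 16L, 16L)
  }
  widths <- if (scale == "clinical") {
    list(c1 = 16L, c2 = 32L, d = 32L, d_vec = 64L, trunk = 128L, heads = 4L)
  } else {
    list(c1 = 8L, c2 = 16L, d = if (role == "mlc") 8L else 16L,
         d_vec = 16L, trunk = 32L, heads = 2L)
  }
  if (role == "mlc") {
    out_dim <- 2L * np
    tok_T <- np + 1L   # one token per leaf pair + one MU token
    tok_F <- 2L
    mean_activation <- "tanh"
    mean_scale <- machine$field_half_width
  } else {
    out_dim <- as.integer(n_cp)
    tok_T <- as.integer(n_cp) # one token per control point
    tok_F <- 2L * np + 1L
    mean_activation <- "softplus"
    mean_scale <- 1
  }
  cfg <- c(widths, list(role = role, scale = scale, vol_shape = vol_shape,
                        vol_channels = 3L, out_dim = out_dim, tok_T = tok_T,
                        tok_F = tok_F, mean_activation = mean_activation,
                        mean_scale = mean_scale, n_cp = as.integer(n_cp),
                        log_std_init = log_std_init, seed = as.integer(seed)))
  ci1 <- conv_index(vol_shape, 2L)
  cir <- conv_index(ci1$out_shape, 1L)
  ci2 <- conv_index(ci1$out_shape, 2L)
  he <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(2 / nr)), nr, nc)
  xav <- function(nr, nc) matrix(stats::rnorm(nr * nc, sd = sqrt(1 / nr)), nr, nc)
  params <- with_seed(as.integer(seed) + 7451L, {
    d <- widths$d
    list(
      conv1_W = he(27L * 3L, widths$c1), conv1_b = numeric(widths$c1),
      bn1_g = rep(1, widths$c1), bn1_b = numeric(widths$c1),
      rcA_W = he(27L * widths$c1, widths$c1), rcA_b = numeric(widths$c1),
      rbnA_g = rep(1, widths$c1), rbnA_b = numeric(widths$c1),
      rcB_W = he(27L * widths$c1, widths$c1), rcB_b = numeric(widths$c1),
      rbnB_g = rep(1, widths$c1), rbnB_b = numeric(widths$c1),
      conv2_W = he(27L * widths$c1, widths$c2), conv2_b = numeric(widths$c2),
      bn2_g = rep(1, widths$c2), bn2_b = numeric(widths$c2),
      tok_W = xav(tok_F, d), tok_b = numeric(d),
      pos_E = matrix(stats::rnorm(tok_T * d, sd = 0.02), tok_T, d),
      att_Wq = xav(d, d), att_Wk = xav(d, d), att_Wv = xav(d, d),
      att_Wo = xav(d, d), att_bo = numeric(d),
      ln1_g = rep(1, d), ln1_b = numeric(d),
      vec_W = he(d, widths$d_vec), vec_b = numeric(widths$d_vec),
      ln2_g = rep(1, widths$d_vec), ln2_b = numeric(widths$d_vec),
      trunk_W = he(widths$c2 + widths$d_vec, widths$trunk),
      trunk_b = numeric(widths$trunk),
      ln3_g = rep(1, widths$trunk), ln3_b = numeric(widths$trunk),
      mean_W = xav(widths$trunk, out_dim) * 0.1, mean_b = numeric(out_dim),
      lstd_W = xav(widths$trunk, out_dim) * 0.01,
      lstd_b = rep(log_std_init, out_dim),
      val_W = xav(widths$trunk, 1L) * 0.1, val_b = 0
    )
  })
  net <- list(cfg = cfg, params = params, ci1 = ci1, cir = cir, ci2 = ci2)
  class(net) <- "vmat_network"
  net
}

#' @export
print.vmat_network <- function(x, ...) {
  cat(sprintf("%s policy network (%s scale): vol %s, %d tokens x %d, out %d, %d parameters\n",
              toupper(x$cfg$role), x$cfg$scale,
              paste(x$cfg$vol_shape, collapse = "x"),
              x$cfg$tok_T, x$cfg$tok_F, x$cfg$out_dim, net_num_params(x)))
  invisible(x)
}

#' Number of trainable parameters of a network
#' @param net A `vmat_network`.
#' @return Integer parameter count.
#' @export
net_num_params <- function(net) {
  sum(vapply(net$params, length, integer(1)))
}

#' Layer/shape manifest of a network
#' @param net A `vmat_network`.
#' @return data.frame of parameter tensors and shapes.
#' @export
net_summary <- function(net) {
  data.frame(param = names(net$params),
             shape = vapply(net$params, function(p) {
               paste(if (is.null(dim(p))) length(p) else dim(p), collapse = "x")
             }, character(1)),
             size = vapply(net$params, length, integer(1)),
             row.names = NULL)
}

# bounds applied to the raw log-std head output for numeric stability
.log_std_bounds <- c(-5, 2)

#' Forward pass of a policy network
#'
#' Deterministic given parameters and input. Returns the policy output used
#' by sampling and the PPO update: the action means on action scale (cm for
#' MLC, MU for MU), the (clamped) log standard deviations, and the value
#' estimate; with `cache = TRUE` the intermediates needed by
#' [net_backward()].
#'
#' @param net A `vmat_network` (methods may exist for other policy classes).
#' @param state List with `vol` (`n_voxel x 3` matrix of the volumetric
#'   channels, column-major voxel order) and `vec` (`tok_T x tok_F` token
#'   matrix).
#' @param cache Keep intermediates for backprop.
#' @return List `mean`, `log_std`, `value` (and `cache`).
#' @export
net_forward <- function(net, state, cache = FALSE) {
  UseMethod("net_forward")
}

#' @rdname net_forward
#' @export
net_forward.vmat_network <- function(net, state, cache = FALSE) {
  p <- net$params
  f1 <- conv3d_f(state$vol, p$conv1_W, p$conv1_b, net$ci1)
  b1 <- batchnorm_f(f1$out, p$bn1_g, p$bn1_b)
  r1 <- relu_f(b1$out)
  fa <- conv3d_f(r1$out, p$rcA_W, p$rcA_b, net$cir)
  ba <- batchnorm_f(fa$out, p$rbnA_g, p$rbnA_b)
  ra <- relu_f(ba$out)
  fb <- conv3d_f(ra$out, p$rcB_W, p$rcB_b, net$cir)
  bb <- batchnorm_f(fb$out, p$rbnB_g, p$rbnB_b)
  res <- bb$out + r1$out
  rr <- relu_f(res)
  f2 <- conv3d_f(rr$out, p$conv2_W, p$conv2_b, net$ci2)
  b2 <- batchnorm_f(f2$out, p$bn2_g, p$bn2_b)
  r2 <- relu_f(b2$out)
  fvol <- colMeans(r2$out)
  tk <- dense_f(state$vec, p$tok_W, p$tok_b)
  tok <- tk$out + p$pos_E
  at <- mha_f(tok, p$att_Wq, p$att_Wk, p$att_Wv, p$att_Wo, p$att_bo,
              net$cfg$heads)
  rsum <- tok + at$out
  l1 <- layernorm_f(rsum, p$ln1_g, p$ln1_b)
  pv <- colMeans(l1$out)
  vd <- dense_f(pv, p$vec_W, p$vec_b)
  l2 <- layernorm_f(vd$out, p$ln2_g, p$ln2_b)
  rv <- relu_f(l2$out)
  z0 <- c(fvol, as.vector(rv$out))
  td <- dense_f(z0, p$trunk_W, p$trunk_b)
  l3 <- layernorm_f(td$out, p$ln3_g, p$ln3_b)
  rz <- relu_f(l3$out)
  z <- as.vector(rz$out)
  md <- dense_f(z, p$mean_W, p$mean_b)
  u <- as.vector(md$out)
  mean_act <- switch(net$cfg$mean_activation, tanh = tanh(u), softplus = softplus(u))
  ld <- dense_f(z, p$lstd_W, p$lstd_b)
  log_std_raw <- as.vector(ld$out)
  log_std <- pmin(pmax(log_std_raw, .log_std_bounds[1]), .log_std_bounds[2])
  vl <- dense_f(z, p$val_W, p$val_b)
  out <- list(mean = mean_act * net$cfg$mean_scale, log_std = log_std,
              value = as.vector(vl$out))
  if (cache) {
    out$cache <- list(f1 = f1, b1 = b1, r1 = r1, fa = fa, ba = ba, ra = ra,
                      fb = fb, bb = bb, rr = rr, f2 = f2, b2 = b2, r2 = r2,
                      tk = tk, at = at, l1 = l1, vd = vd, l2 = l2, rv = rv,
                      td = td, l3 = l3, rz = rz, md = md, ld = ld, vl = vl,
                      u = u, log_std_raw = log_std_raw, z = z, z0 = z0,
                      n_tok = nrow(state$vec))
  }
  out
}

#' Backward pass of a policy network
#'
#' Backpropagates gradients supplied with respect to the action-scale mean,
#' the (clamped) log standard deviation, and the value, returning a gradient
#' list matching `net$params`.
#'
#' @param net A `vmat_network`.
#' @param cache Cache from `net_forward(..., cache = TRUE)`.
#' @param d_mean,d_log_std Numeric vectors (`out_dim`).
#' @param d_value Scalar.
#' @return Named list of parameter gradients.
#' @export
net_backward <- function(net, cache, d_mean, d_log_std, d_value) {
  p <- net$params
  g <- list()
  act_grad <- switch(net$cfg$mean_activation,
                     tanh = 1 - tanh(cache$u)^2,
                     softplus = softplus_grad(cache$u))
  du <- d_mean * net$cfg$mean_scale * act_grad
  in_range <- cache$log_std_raw > .log_std_bounds[1] &
    cache$log_std_raw < .log_std_bounds[2]
  dls <- d_log_std * in_range
  bm <- dense_b(cache$md, p$mean_W, du)
  g$mean_W <- bm$dW; g$mean_b <- bm$db
  bl <- dense_b(cache$ld, p$lstd_W, dls)
  g$lstd_W <- bl$dW; g$lstd_b <- bl$db
  bv <- dense_b(cache$vl, p$val_W, d_value)
  g$val_W <- bv$dW; g$val_b <- bv$db
  dz <- as.vector(bm$dx + bl$dx + bv$dx)
  drz <- relu_b(cache$rz, matrix(dz, 1))
  bl3 <- layernorm_b(cache$l3, p$ln3_g, drz)
  g$ln3_g <- bl3$dg; g$ln3_b <- bl3$db
  btd <- dense_b(cache$td, p$trunk_W, bl3$dx)
  g$trunk_W <- btd$dW; g$trunk_b <- btd$db
  dz0 <- as.vector(btd$dx)
  c2 <- net$cfg$c2
  dfvol <- dz0[seq_len(c2)]
  dfvec <- dz0[c2 + seq_len(net$cfg$d_vec)]
  # vector branch
  drv <- relu_b(cache$rv, matrix(dfvec, 1))
  bl2 <- layernorm_b(cache$l2, p$ln2_g, drv)
  g$ln2_g <- bl2$dg; g$ln2_b <- bl2$db
  bvd <- dense_b(cache$vd, p$vec_W, bl2$dx)
  g$vec_W <- bvd$dW; g$vec_b <- bvd$db
  n_tok <- cache$n_tok
  dl1 <- matrix(as.vector(bvd$dx), n_tok, length(bvd$dx), byrow = TRUE) / n_tok
  bl1 <- layernorm_b(cache$l1, p$ln1_g, dl1)
  g$ln1_g <- bl1$dg; g$ln1_b <- bl1$db
  drsum <- bl1$dx
  bat <- mha_b(cache$at, p$att_Wq, p$att_Wk, p$att_Wv, p$att_Wo,
               net$cfg$heads, drsum)
  g$att_Wq <- bat$dWq; g$att_Wk <- bat$dWk; g$att_Wv <- bat$dWv
  g$att_Wo <- bat$dWo; g$att_bo <- bat$dbo
  dtok <- drsum + bat$dx
  g$pos_E <- dtok
  btk <- dense_b(cache$tk, p$tok_W, dtok)
  g$tok_W <- btk$dW; g$tok_b <- btk$db
  # volumetric branch
  n2 <- nrow(cache$r2$out)
  dr2 <- matrix(dfvol, n2, c2, byrow = TRUE) / n2
  dr2 <- relu_b(cache$r2, dr2)
  bb2 <- batchnorm_b(cache$b2, p$bn2_g, dr2)
  g$bn2_g <- bb2$dg; g$bn2_b <- bb2$db
  bf2 <- conv3d_b(cache$f2, p$conv2_W, net$ci2, bb2$dx)
  g$conv2_W <- bf2$dW; g$conv2_b <- bf2$db
  drr <- relu_b(cache$rr, bf2$dx)
  # residual: gradient flows into both the block output and the skip
  bbb <- batchnorm_b(cache$bb, p$rbnB_g, drr)
  g$rbnB_g <- bbb$dg; g$rbnB_b <- bbb$db
  bfb <- conv3d_b(cache$fb, p$rcB_W, net$cir, bbb$dx)
  g$rcB_W <- bfb$dW; g$rcB_b <- bfb$db
  dra <- relu_b(cache$ra, bfb$dx)
  bba <- batchnorm_b(cache$ba, p$rbnA_g, dra)
  g$rbnA_g <- bba$dg; g$rbnA_b <- bba$db
  bfa <- conv3d_b(cache$fa, p$rcA_W, net$cir, bba$dx)
  g$rcA_W <- bfa$dW; g$rcA_b <- bfa$db
  dr1 <- relu_b(cache$r1, bfa$dx + drr)
  bb1 <- batchnorm_b(cache$b1, p$bn1_g, dr1)
  g$bn1_g <- bb1$dg; g$bn1_b <- bb1$db
  bf1 <- conv3d_b(cache$f1, p$conv1_W, net$ci1, bb1$dx, need_dx = FALSE)
  g$conv1_W <- bf1$dW; g$conv1_b <- bf1$db
  g[names(net$params)]
}

#' Log-density of a diagonal Gaussian policy
#' @param action,mean,log_std Numeric vectors of equal length.
#' @return Scalar log-probability.
#' @export
gaussian_log_prob <- function(action, mean, log_std) {
  sum(-0.5 * log(2 * pi) - log_std - 0.5 * ((action - mean) / exp(log_std))^2)
}

#' Sample (or take) an action from a policy output
#'
#' In training mode each component is drawn from an independent Gaussian with
#' the predicted mean and `exp(log_std)`; at inference the mean action is
#' used directly. The returned log-probability is the diagonal-Gaussian
#' log-density of the returned action.
#'
#' @param out Policy output from [net_forward()].
#' @param mode `"train"` (sample) or `"infer"` (mean).
#' @return List `action`, `log_prob`.
#' @export
sample_action <- function(out, mode = c("train", "infer")) {
  mode <- match.arg(mode)
  action <- if (mode == "train") {
    out$mean + exp(out$log_std) * stats::rnorm(length(out$mean))
  } else {
    out$mean
  }
  list(action = action, log_prob = gaussian_log_prob(action, out$mean, out$log_std))
}

#' Entropy of the diagonal Gaussian policy
#'
#' Sum over action components of `1/2 log(2 pi e) + log_std`.
#' @param out Policy output from [net_forward()].
#' @return Scalar entropy (nats).
#' @export
policy_entropy <- function(out) {
  sum(0.5 * log(2 * pi * exp(1)) + out$log_std)
}

#' Save / load network parameters as JSON text
#'
#' Checkpoints store the architecture config and all parameter tensors at
#' full precision, plus a content hash of the config for compatibility
#' checks on load.
#' @param net A `vmat_network`.
#' @param path File path.
#' @export
write_network <- function(net, path) {
  cfg <- net$cfg
  obj <- list(format = "vmatrl-net-v1", cfg = cfg,
              params = lapply(net$params, function(p) {
                list(dim = if (is.null(dim(p))) length(p) else dim(p),
                     data = as.vector(p))
              }))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' @rdname write_network
#' @param machine A `vmat_machine` matching the saved config.
#' @return `read_network` returns the `vmat_network`.
#' @export
read_network <- function(path, machine = machine_model()) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(obj$format) || obj$format != "vmatrl-net-v1") stop("not a vmatrl network file")
  cfg <- obj$cfg
  net <- build_network(role = cfg$role, scale = cfg$scale,
                       vol_shape = as.integer(unlist(cfg$vol_shape)),
                       n_cp = cfg$n_cp, machine = machine, seed = cfg$seed,
                       log_std_init = cfg$log_std_init)
  for (nm in names(net$params)) {
    p <- obj$params[[nm]]
    v <- as.numeric(unlist(p$data))
    dm <- as.integer(unlist(p$dim))
    net$params[[nm]] <- if (length(dm) > 1) array(v, dim = dm) else v
  }
  net
}
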