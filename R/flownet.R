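# RAFT-style optical-flow estimator. Two frames pass through a shared-weight
# residual feature encoder to 1/8 resolution; visual similarity is the
# all-pairs correlation volume C[ij, kl] = sum_h g(I1)_ijh * g(I2)_klh,
# pooled over the kl dimensions into a 4-level pyramid (kernels 1, 2, 4, 8)
# that keeps full resolution in ij. A ConvGRU update operator repeatedly
# looks up correlation features around the current flow estimate and emits an
# update df; the flow starts at zero and the final iterate is upsampled
# bilinearly to full resolution. Training backpropagates each iterate's loss
# through its own update step (truncated backpropagation through time; the
# hidden state, incoming flow and lookup coordinates are treated as constants
# at iteration boundaries), with gradients reaching the correlation volume
# and both encoders.

#' Flow network configuration
#'
#' @param encoder_filters six residual-block widths; blocks 1, 3 and 5
#'   downsample by 2 (total 1/8).
#' @param corr_pool_kernels pooling kernels of the correlation pyramid.
#' @param lookup_radius correlation lookup radius (px at 1/8 resolution).
#' @param iterations recurrent refinement iterations.
#' @param gamma exponential weighting of the per-iterate sequence loss.
#' @param learning_rate,fine_tune_lr AdamW learning rates (pre-train /
#'   fine-tune).
#' @param batch_size_pretrain,batch_size_finetune batch sizes.
#' @param betas AdamW moment coefficients.
#' @param hidden_dim,context_dim,motion_dim update-operator widths.
#' @return a `flow_config` list.
#' @export
flow_config <- function(encoder_filters = c(64, 64, 128, 128, 192, 192),
                        corr_pool_kernels = c(1, 2, 4, 8),
                        lookup_radius = 4L, iterations = 12L, gamma = 0.8,
                        learning_rate = 2e-4, fine_tune_lr = 1e-4,
                        batch_size_pretrain = 12L, batch_size_finetune = 6L,
                        betas = c(0.9, 0.999),
                        hidden_dim = 96L, context_dim = 64L, motion_dim = 64L) {
  if (length(encoder_filters) != 6) stop_input("encoder_filters must have 6 entries")
  if (iterations < 1) stop_input("iterations must be >= 1")
  if (!(gamma > 0 && gamma <= 1)) stop_input("gamma must lie in (0, 1]")
  structure(list(encoder_filters = as.integer(encoder_filters),
                 downsample_factor = 8L,
                 corr_pool_kernels = as.integer(corr_pool_kernels),
                 lookup_radius = as.integer(lookup_radius),
                 iterations = as.integer(iterations), gamma = gamma,
                 learning_rate = learning_rate, fine_tune_lr = fine_tune_lr,
                 batch_size_pretrain = as.integer(batch_size_pretrain),
                 batch_size_finetune = as.integer(batch_size_finetune),
                 betas = betas, hidden_dim = as.integer(hidden_dim),
                 context_dim = as.integer(context_dim),
                 motion_dim = as.integer(motion_dim)),
            class = "flow_config")
}

ENC_STRIDES <- c(2L, 1L, 2L, 1L, 2L, 1L)

new_res_block <- function(cin, cout, stride) {
  b <- list(c1 = new_conv2d(cin, cout, 3), c2 = new_conv2d(cout, cout, 3))
  if (stride > 1 || cin != cout) b$proj <- new_conv2d(cin, cout, 1)
  b
}

#' Build a RAFT-style motion estimation model
#'
#' @param config a [flow_config()].
#' @param seed RNG seed for weight initialization.
#' @return a `raft_model`.
#' @examples
#' cfg <- flow_config(encoder_filters = c(4, 4, 6, 6, 8, 8), lookup_radius = 2,
#'                    iterations = 2, hidden_dim = 8, context_dim = 8, motion_dim = 8)
#' model <- build_raft(cfg, seed = 1)
#' est <- estimate_flow(model, matrix(0.5, 16, 16), matrix(0.5, 16, 16))
#' dim(est$final)
#' @export
build_raft <- function(config, seed = 0L) {
  stopifnot(inherits(config, "flow_config"))
  fl <- config$encoder_filters
  corr_dim <- length(config$corr_pool_kernels) * (2 * config$lookup_radius + 1)^2
  params <- with_seed(seed, {
    p <- list()
    for (net in c("fnet", "cnet")) {
      cin <- 1L
      for (l in 1:6) {
        p[[sprintf("%s.b%d", net, l)]] <- NULL # placeholder for ordering
        blk <- new_res_block(cin, fl[l], ENC_STRIDES[l])
        p[[sprintf("%s.b%d.c1", net, l)]] <- blk$c1
        p[[sprintf("%s.b%d.c2", net, l)]] <- blk$c2
        if (!is.null(blk$proj)) p[[sprintf("%s.b%d.proj", net, l)]] <- blk$proj
        cin <- fl[l]
      }
    }
    p[["fnet.out"]] <- new_conv2d(fl[6], fl[6], 1)
    p[["cnet.out"]] <- new_conv2d(fl[6], config$hidden_dim + config$context_dim, 1)
    p[["menc"]] <- new_conv2d(corr_dim + 2L, config$motion_dim, 3)
    xdim <- config$motion_dim + config$context_dim
    p[["gru.z"]] <- new_conv2d(config$hidden_dim + xdim, config$hidden_dim, 3)
    p[["gru.r"]] <- new_conv2d(config$hidden_dim + xdim, config$hidden_dim, 3)
    p[["gru.q"]] <- new_conv2d(config$hidden_dim + xdim, config$hidden_dim, 3)
    p[["head1"]] <- new_conv2d(config$hidden_dim, config$hidden_dim, 3)
    p[["head2"]] <- new_conv2d(config$hidden_dim, 2L, 3)
    p[Filter(function(nm) !is.null(p[[nm]]), names(p))]
  })
  structure(list(config = config, params = params, seed = seed),
            class = "raft_model")
}

#' @export
print.raft_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<raft_model> filters %s, hidden %d, %d lookup levels (r = %d), %s parameters\n",
              paste(x$config$encoder_filters, collapse = ","), x$config$hidden_dim,
              length(x$config$corr_pool_kernels), x$config$lookup_radius,
              format(np, big.mark = ",")))
  invisible(x)
}

res_block_fwd <- function(x, p, prefix, stride) {
  c1 <- conv2d_fwd(x, p[[paste0(prefix, ".c1")]], stride = stride)
  r1 <- relu_fwd(c1$out)
  c2 <- conv2d_fwd(r1$out, p[[paste0(prefix, ".c2")]], stride = 1L)
  has_proj <- !is.null(p[[paste0(prefix, ".proj")]])
  sc <- if (has_proj) conv2d_fwd(x, p[[paste0(prefix, ".proj")]], stride = stride, pad = 0L)
  else list(out = x, cache = NULL)
  s <- c2$out + sc$out
  r2 <- relu_fwd(s)
  list(out = r2$out, cache = list(c1 = c1$cache, r1 = r1$cache, c2 = c2$cache,
                                  sc = sc$cache, r2 = r2$cache, has_proj = has_proj))
}

res_block_bwd <- function(dout, p, prefix, cache, grads) {
  ds <- relu_bwd(dout, cache$r2)
  b2 <- conv2d_bwd(ds, p[[paste0(prefix, ".c2")]], cache$c2)
  grads <- acc_grad(grads, paste0(prefix, ".c2"), b2$dW, b2$db)
  dr1 <- relu_bwd(b2$dx, cache$r1)
  b1 <- conv2d_bwd(dr1, p[[paste0(prefix, ".c1")]], cache$c1)
  grads <- acc_grad(grads, paste0(prefix, ".c1"), b1$dW, b1$db)
  dx <- b1$dx
  if (cache$has_proj) {
    bp <- conv2d_bwd(ds, p[[paste0(prefix, ".proj")]], cache$sc)
    grads <- acc_grad(grads, paste0(prefix, ".proj"), bp$dW, bp$db)
    dx <- dx + bp$dx
  } else {
    dx <- dx + ds
  }
  list(dx = dx, grads = grads)
}

encoder_fwd <- function(p, net, img) {
  x <- array(img, c(1, dim(img)))
  caches <- vector("list", 7)
  for (l in 1:6) {
    fb <- res_block_fwd(x, p, sprintf("%s.b%d", net, l), ENC_STRIDES[l])
    caches[[l]] <- fb$cache
    x <- fb$out
  }
  fo <- conv2d_fwd(x, p[[paste0(net, ".out")]], stride = 1L, pad = 0L)
  caches[[7]] <- fo$cache
  list(out = fo$out, caches = caches)
}

encoder_bwd <- function(p, net, dout, caches, grads) {
  bo <- conv2d_bwd(dout, p[[paste0(net, ".out")]], caches[[7]])
  grads <- acc_grad(grads, paste0(net, ".out"), bo$dW, bo$db)
  dx <- bo$dx
  for (l in 6:1) {
    rb <- res_block_bwd(dx, p, sprintf("%s.b%d", net, l), caches[[l]], grads)
    grads <- rb$grads
    dx <- rb$dx
  }
  list(dx = dx, grads = grads)
}

#' All-pairs correlation pyramid
#'
#' Level 0 holds the channel dot product between every pair of feature
#' positions of the two maps; the `kl` (target) dimensions are then average
#' pooled with kernels 1, 2, 4, 8 while the `ij` (source) dimension keeps
#' full resolution.
#'
#' @param feat1,feat2 `C x h x w` feature arrays.
#' @param n_levels number of pyramid levels.
#' @return a `correlation_pyramid`: list `levels` (each `(h*w) x hl x wl`,
#'   source positions ravelled column-major), `h`, `w`.
#' @export
correlation_volume <- function(feat1, feat2, n_levels = 4L) {
  if (!all(dim(feat1) == dim(feat2))) stop_shape("feature maps differ in shape")
  cc <- dim(feat1)[1]; h <- dim(feat1)[2]; w <- dim(feat1)[3]
  f1 <- matrix(feat1, cc); f2 <- matrix(feat2, cc)
  c0 <- crossprod(f1, f2) # (h*w) x (h*w)
  levels <- list(array(c0, c(h * w, h, w)))
  for (l in seq_len(n_levels - 1)) {
    v <- levels[[l]]
    hl <- dim(v)[2]; wl <- dim(v)[3]
    if (hl < 2 || wl < 2) { levels[[l + 1]] <- v; next }
    oi <- seq(1, hl - 1, 2); oj <- seq(1, wl - 1, 2)
    levels[[l + 1]] <- (v[, oi, oj, drop = FALSE] + v[, oi + 1, oj, drop = FALSE] +
                          v[, oi, oj + 1, drop = FALSE] + v[, oi + 1, oj + 1, drop = FALSE]) / 4
  }
  structure(list(levels = levels, h = h, w = w), class = "correlation_pyramid")
}

# Backward of the pyramid pooling: push level gradients down to level 0.
pyramid_bwd <- function(dlevels, h, w) {
  for (l in length(dlevels):2) {
    v <- dlevels[[l]]
    tgt <- dlevels[[l - 1]]
    hl <- dim(tgt)[2]; wl <- dim(tgt)[3]
    if (dim(v)[2] == hl && dim(v)[3] == wl) { # degenerate copied level
      dlevels[[l - 1]] <- tgt + v
      next
    }
    oi <- seq(1, hl - 1, 2); oj <- seq(1, wl - 1, 2)
    q <- v / 4
    tgt[, oi, oj] <- tgt[, oi, oj, drop = FALSE] + q
    tgt[, oi + 1, oj] <- tgt[, oi + 1, oj, drop = FALSE] + q
    tgt[, oi, oj + 1] <- tgt[, oi, oj + 1, drop = FALSE] + q
    tgt[, oi + 1, oj + 1] <- tgt[, oi + 1, oj + 1, drop = FALSE] + q
    dlevels[[l - 1]] <- tgt
  }
  matrix(dlevels[[1]], h * w)
}

#' Correlation feature lookup
#'
#' For every source position, samples each pyramid level bilinearly in a
#' `(2r+1)^2` window centred on the flow-displaced target position (scaled to
#' the level's resolution); out-of-bounds taps contribute zero. Level and
#' window features are concatenated, giving `n_levels * (2r+1)^2` channels.
#'
#' @param pyramid a `correlation_pyramid`.
#' @param flow current flow at 1/8 resolution, `2 x h x w`.
#' @param radius lookup radius `r`.
#' @return list `out` (features `[n_levels*(2r+1)^2, h, w]`) and `cache` for
#'   the backward pass.
#' @export
corr_lookup <- function(pyramid, flow, radius) {
  h <- pyramid$h; w <- pyramid$w
  n_l <- length(pyramid$levels)
  win <- (2 * radius + 1)^2
  out <- array(0, c(n_l * win, h, w))
  s_idx <- seq_len(h * w)
  gx <- rep(0:(w - 1), each = h); gy <- rep(0:(h - 1), times = w)
  fx <- as.vector(flow[1, , ]); fy <- as.vector(flow[2, , ])
  taps <- vector("list", n_l * win * 4)
  ti <- 0L
  ch <- 0L
  for (l in seq_len(n_l)) {
    vol <- pyramid$levels[[l]]
    hl <- dim(vol)[2]; wl <- dim(vol)[3]
    sc <- 2^(l - 1)
    cx <- (gx + fx) / sc; cy <- (gy + fy) / sc
    for (dy in -radius:radius) for (dx in -radius:radius) {
      ch <- ch + 1L
      sx <- cx + dx; sy <- cy + dy
      x0 <- floor(sx); y0 <- floor(sy)
      fxx <- sx - x0; fyy <- sy - y0
      acc <- numeric(h * w)
      for (tap in 1:4) {
        xx <- x0 + (tap - 1) %% 2; yy <- y0 + (tap - 1) %/% 2
        wt <- (if ((tap - 1) %% 2 == 0) 1 - fxx else fxx) *
          (if ((tap - 1) %/% 2 == 0) 1 - fyy else fyy)
        ok <- xx >= 0 & xx <= (wl - 1) & yy >= 0 & yy <= (hl - 1) & wt != 0
        if (any(ok)) {
          idx <- cbind(s_idx[ok], yy[ok] + 1, xx[ok] + 1)
          acc[ok] <- acc[ok] + wt[ok] * vol[idx]
          ti <- ti + 1L
          taps[[ti]] <- list(level = l, channel = ch, idx = idx, wt = wt[ok], sel = which(ok))
        }
      }
      out[ch, , ] <- matrix(acc, h, w)
    }
  }
  list(out = out, cache = list(taps = taps[seq_len(ti)], n_l = n_l, h = h, w = w,
                               level_dims = lapply(pyramid$levels, dim)))
}

corr_lookup_bwd <- function(dout, cache) {
  dlevels <- lapply(cache$level_dims, function(d) array(0, d))
  dmat <- matrix(dout, dim(dout)[1])
  for (tp in cache$taps) {
    g <- dmat[tp$channel, tp$sel] * tp$wt
    dlevels[[tp$level]][tp$idx] <- dlevels[[tp$level]][tp$idx] + g
  }
  pyramid_bwd(dlevels, cache$h, cache$w)
}

concat_c <- function(a, b) {
  out <- array(0, c(dim(a)[1] + dim(b)[1], dim(a)[2], dim(a)[3]))
  out[seq_len(dim(a)[1]), , ] <- a
  out[dim(a)[1] + seq_len(dim(b)[1]), , ] <- b
  out
}

gru_fwd <- function(p, h, x) {
  hx <- concat_c(h, x)
  cz <- conv2d_fwd(hx, p[["gru.z"]])
  z <- sigmoid(cz$out)
  cr <- conv2d_fwd(hx, p[["gru.r"]])
  r <- sigmoid(cr$out)
  rh <- r * h
  rhx <- concat_c(rh, x)
  cq <- conv2d_fwd(rhx, p[["gru.q"]])
  q <- tanh(cq$out)
  hn <- (1 - z) * h + z * q
  list(out = hn, cache = list(h = h, x = x, z = z, r = r, q = q,
                              cz = cz$cache, cr = cr$cache, cq = cq$cache))
}

gru_bwd <- function(dhn, p, cache, grads) {
  nh <- dim(cache$h)[1]
  dz <- dhn * (cache$q - cache$h)
  dq <- dhn * cache$z
  dh <- dhn * (1 - cache$z)
  dcq <- dq * (1 - cache$q^2)
  bq <- conv2d_bwd(dcq, p[["gru.q"]], cache$cq)
  grads <- acc_grad(grads, "gru.q", bq$dW, bq$db)
  drh <- bq$dx[seq_len(nh), , , drop = FALSE]
  dx <- bq$dx[-seq_len(nh), , , drop = FALSE]
  dr <- drh * cache$h
  dh <- dh + drh * cache$r
  dcz <- dz * cache$z * (1 - cache$z)
  bz <- conv2d_bwd(dcz, p[["gru.z"]], cache$cz)
  grads <- acc_grad(grads, "gru.z", bz$dW, bz$db)
  dcr <- dr * cache$r * (1 - cache$r)
  br <- conv2d_bwd(dcr, p[["gru.r"]], cache$cr)
  grads <- acc_grad(grads, "gru.r", br$dW, br$db)
  dhx <- bz$dx + br$dx
  dh <- dh + dhx[seq_len(nh), , , drop = FALSE]
  dx <- dx + dhx[-seq_len(nh), , , drop = FALSE]
  list(dh = dh, dx = dx, grads = grads)
}

# Full forward pass. Returns iterates at 1/8 and full resolution plus caches
# needed for the truncated backward pass.
raft_forward <- function(model, frame1, frame2, iterations, keep_cache = FALSE) {
  p <- model$params; cfg <- model$config
  hh <- nrow(frame1); ww <- ncol(frame1)
  if (hh %% 8 != 0 || ww %% 8 != 0)
    stop_shape("frame size %dx%d must be divisible by 8", hh, ww)
  if (!all(dim(frame1) == dim(frame2))) stop_shape("frames differ in shape")
  f1 <- encoder_fwd(p, "fnet", frame1)
  f2 <- encoder_fwd(p, "fnet", frame2)
  cn <- encoder_fwd(p, "cnet", frame1)
  nh <- cfg$hidden_dim
  h0 <- tanh(cn$out[seq_len(nh), , , drop = FALSE])
  ctx_pre <- cn$out[-seq_len(nh), , , drop = FALSE]
  ctx <- pmax(ctx_pre, 0)
  cc <- dim(f1$out)[1]
  pyr <- correlation_volume(f1$out, f2$out, n_levels = length(cfg$corr_pool_kernels))
  # scale like 1/sqrt(C) for stable updates (absorbed nowhere else)
  pyr$levels <- lapply(pyr$levels, function(v) v / sqrt(cc))
  h8 <- dim(f1$out)[2]; w8 <- dim(f1$out)[3]
  flow8 <- array(0, c(2, h8, w8))
  hstate <- h0
  iter_caches <- list()
  flows_full <- list()
  flows8 <- list()
  for (it in seq_len(iterations)) {
    lk <- corr_lookup(pyr, flow8, cfg$lookup_radius)
    mi <- concat_c(lk$out, flow8)
    mc <- conv2d_fwd(mi, p[["menc"]])
    mr <- relu_fwd(mc$out)
    x <- concat_c(mr$out, ctx)
    g <- gru_fwd(p, hstate, x)
    hd1 <- conv2d_fwd(g$out, p[["head1"]])
    hr1 <- relu_fwd(hd1$out)
    hd2 <- conv2d_fwd(hr1$out, p[["head2"]])
    flow8 <- flow8 + hd2$out
    up <- bilinear_resize_fwd(flow8, hh, ww)
    flows_full[[it]] <- up$out * 8
    flows8[[it]] <- flow8
    if (keep_cache)
      iter_caches[[it]] <- list(lk = lk$cache, mc = mc$cache, mr = mr$cache,
                                gru = g$cache, hd1 = hd1$cache, hr1 = hr1$cache,
                                hd2 = hd2$cache, up = up$cache)
    hstate <- g$out
  }
  list(flows_full = flows_full, flows8 = flows8,
       cache = if (keep_cache) list(iters = iter_caches, f1 = f1, f2 = f2, cn = cn,
                                    ctx_mask = ctx_pre > 0, nh = nh, cc = cc,
                                    h8 = h8, w8 = w8) else NULL)
}

#' Estimate the optical flow between two frames
#'
#' Runs the recurrent estimator and returns every iterate at full resolution.
#' With `iterations = 0` the estimate is the zero initialization `f_0 = 0`.
#'
#' @param model a `raft_model`.
#' @param frame_t,frame_t1 grayscale `H x W` matrices in `[0, 1]`, `H` and
#'   `W` divisible by 8.
#' @param iterations refinement iterations (default from the config).
#' @return a `flow_estimate`: list `iterates` (list of [flow_field()]s) and
#'   `final`.
#' @export
estimate_flow <- function(model, frame_t, frame_t1,
                          iterations = model$config$iterations) {
  frame_t <- as.matrix(frame_t); frame_t1 <- as.matrix(frame_t1)
  if (iterations == 0) {
    z <- flow_field(array(0, c(dim(frame_t), 2)))
    return(structure(list(iterates = list(), final = z), class = "flow_estimate"))
  }
  fw <- raft_forward(model, frame_t, frame_t1, iterations)
  iterates <- lapply(fw$flows_full, function(f)
    flow_field(array(c(f[1, , ], f[2, , ]), c(dim(f)[2], dim(f)[3], 2))))
  structure(list(iterates = iterates, final = iterates[[length(iterates)]]),
            class = "flow_estimate")
}

#' Sequence loss over flow iterates
#'
#' `sum_i gamma^(N-i) * mean_px || f_gt - f_i ||_2`: each iterate pays the
#' per-pixel mean Euclidean end-point distance to the ground truth, with
#' exponentially increasing weight so the final iterate carries weight 1.
#'
#' @param flows a `flow_estimate`, or list of `H x W x 2` arrays.
#' @param gt ground-truth [flow_field()].
#' @param gamma exponential weight (default 0.8).
#' @return scalar loss.
#' @export
sequence_loss <- function(flows, gt, gamma = 0.8) {
  if (inherits(flows, "flow_estimate")) flows <- flows$iterates
  n <- length(flows)
  if (n < 1) stop_input("need at least one flow iterate")
  loss <- 0
  for (i in seq_len(n)) {
    f <- flows[[i]]
    if (!all(dim(f) == dim(gt))) stop_shape("iterate %d shape differs from ground truth", i)
    ei <- mean(sqrt((f[, , 1] - gt[, , 1])^2 + (f[, , 2] - gt[, , 2])^2))
    loss <- loss + gamma^(n - i) * ei
  }
  loss
}

# dL/df for one iterate of the sequence loss (full resolution, [2, H, W]).
epe_loss_grad <- function(flow_chw, gt, weight, eps = 1e-9) {
  du <- flow_chw[1, , ] - gt[, , 1]
  dv <- flow_chw[2, , ] - gt[, , 2]
  nrm <- sqrt(du^2 + dv^2 + eps)
  n <- length(du)
  list(loss = weight * mean(sqrt(du^2 + dv^2)),
       d = array(rbind(as.vector(weight * du / nrm / n),
                       as.vector(weight * dv / nrm / n)), dim(flow_chw)))
}

# Truncated backward pass for one frame pair; returns grads and the loss.
raft_backward <- function(model, fw, gt, gamma) {
  p <- model$params; cfg <- model$config
  n <- length(fw$flows_full)
  cache <- fw$cache
  grads <- list()
  for (nm in names(p)) {
    grads[[paste0(nm, ".W")]] <- p[[nm]]$W * 0
    grads[[paste0(nm, ".b")]] <- p[[nm]]$b * 0
  }
  dC0 <- matrix(0, cache$h8 * cache$w8, cache$h8 * cache$w8)
  dctx <- 0
  loss <- 0
  for (it in seq_len(n)) {
    wgt <- gamma^(n - it)
    lg <- epe_loss_grad(fw$flows_full[[it]], gt, wgt)
    loss <- loss + lg$loss
    ic <- cache$iters[[it]]
    dflow8 <- bilinear_resize_bwd(lg$d * 8, ic$up)
    # flow8 accumulates over iterations, but earlier iterates are detached:
    # the gradient drives this iteration's update df only
    ddf <- dflow8
    bh2 <- conv2d_bwd(ddf, p[["head2"]], ic$hd2)
    grads <- acc_grad(grads, "head2", bh2$dW, bh2$db)
    dhr1 <- relu_bwd(bh2$dx, ic$hr1)
    bh1 <- conv2d_bwd(dhr1, p[["head1"]], ic$hd1)
    grads <- acc_grad(grads, "head1", bh1$dW, bh1$db)
    gb <- gru_bwd(bh1$dx, p, ic$gru, grads)
    grads <- gb$grads
    nm_ <- cfg$motion_dim
    dmr <- gb$dx[seq_len(nm_), , , drop = FALSE]
    dctx <- dctx + gb$dx[-seq_len(nm_), , , drop = FALSE]
    dmc <- relu_bwd(dmr, ic$mr)
    bm <- conv2d_bwd(dmc, p[["menc"]], ic$mc)
    grads <- acc_grad(grads, "menc", bm$dW, bm$db)
    corr_dim <- dim(bm$dx)[1] - 2L
    dcorr <- bm$dx[seq_len(corr_dim), , , drop = FALSE]
    dC0 <- dC0 + corr_lookup_bwd(dcorr, ic$lk)
  }
  # correlation volume -> encoders (the 1/sqrt(C) scaling is part of the map)
  f1m <- matrix(cache$f1$out, cache$cc)
  f2m <- matrix(cache$f2$out, cache$cc)
  dC0 <- dC0 / sqrt(cache$cc)
  df1 <- array(f2m %*% t(dC0), dim(cache$f1$out))
  df2 <- array(f1m %*% dC0, dim(cache$f2$out))
  eb1 <- encoder_bwd(p, "fnet", df1, cache$f1$caches, grads)
  grads <- eb1$grads
  eb2 <- encoder_bwd(p, "fnet", df2, cache$f2$caches, grads)
  grads <- eb2$grads
  # context branch: relu-masked gradient; the tanh h0 branch is detached with
  # the hidden state, so its slice receives zero
  dcn <- array(0, dim(cache$cn$out))
  dcn[-seq_len(cache$nh), , ] <- dctx * cache$ctx_mask[, , , drop = TRUE]
  ebc <- encoder_bwd(p, "cnet", dcn, cache$cn$caches, grads)
  grads <- ebc$grads
  list(grads = grads, loss = loss)
}

#' Train the flow network
#'
#' AdamW on the sequence loss with truncated backpropagation through the
#' recurrent iterations. Deterministic for a fixed seed.
#'
#' @param model a `raft_model`.
#' @param items flow items from [make_training_items()] (elements `frame1`,
#'   `frame2`, `flow`).
#' @param iterations optimizer steps.
#' @param seed RNG seed for batch sampling.
#' @param lr learning rate (defaults to the fine-tune rate).
#' @param batch_size pairs per step.
#' @param flow_iterations recurrent iterations during training.
#' @return list `model` and `history`.
#' @export
train_flow <- function(model, items, iterations, seed = 1L,
                       lr = model$config$fine_tune_lr,
                       batch_size = model$config$batch_size_finetune,
                       flow_iterations = model$config$iterations) {
  stopifnot(inherits(model, "raft_model"))
  if (!length(items)) stop_input("empty training set")
  if (iterations == 0) return(list(model = model, history = numeric(0)))
  history <- numeric(iterations)
  with_seed(seed, {
    state <- NULL
    for (it in seq_len(iterations)) {
      sel <- sample.int(length(items), min(batch_size, length(items)))
      grads <- NULL
      loss_acc <- 0
      for (s in sel) {
        itm <- items[[s]]
        fw <- raft_forward(model, itm$frame1, itm$frame2, flow_iterations,
                           keep_cache = TRUE)
        bw <- raft_backward(model, fw, itm$flow, model$config$gamma)
        g <- lapply(bw$grads, function(x) x / length(sel))
        grads <- if (is.null(grads)) g else Map("+", grads, g)
        loss_acc <- loss_acc + bw$loss / length(sel)
      }
      history[it] <- loss_acc
      flat <- unlist_params(model$params)
      st <- adamw_step(flat, grads, state, lr, betas = model$config$betas)
      state <- st$state
      model$params <- relist_params(st$params, model$params)
    }
  })
  list(model = model, history = history)
}

#' Ground-truth flow oracle
#'
#' Returns the phantom's analytic flows unchanged: a plug-in satisfying the
#' estimator interface with zero end-point error, used to validate the
#' tracking and strain stages independently of any trained model.
#'
#' @param phantom a `phantom_sequence`.
#' @return list of [flow_field()]s.
#' @export
oracle_estimator <- function(phantom) {
  stopifnot(inherits(phantom, "phantom_sequence"))
  phantom$flows
}

#' Wrap a raft model (or the oracle) as a frame-pair estimator function
#'
#' The pipeline accepts any function `(frame_t, frame_t1) -> H x W x 2`
#' displacement array, enabling alternative estimator back-ends.
#'
#' @param model a `raft_model`.
#' @param iterations refinement iterations.
#' @return a function of two frames returning a [flow_field()].
#' @export
as_estimator <- function(model, iterations = model$config$iterations) {
  force(model); force(iterations)
  function(frame_t, frame_t1) estimate_flow(model, frame_t, frame_t1, iterations)$final
}
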