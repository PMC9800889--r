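# The 3D cardiac segmentation network (3D-CSN): a U-net style encoder-decoder
# over 3-frame volumes. Each encoder level applies two 3x3x3 convolutions
# (each followed by ReLU) and a max pooling; each decoder level an
# upconvolution, a skip concatenation and two 3x3x3 convolutions. Pooling and
# upconvolution act on the spatial axes only (2x2x1): a 3-frame temporal axis
# cannot be halved repeatedly, so the stated 2x2x2 pooling is reduced to its
# spatial part while the 3x3x3 kernels still mix adjacent frames at full
# temporal resolution.

#' Segmentation network configuration
#'
#' @param in_frames frames per input volume (3).
#' @param levels encoder/decoder depth; the image size must be divisible by
#'   `2^levels`.
#' @param base_filters channels of the first level, doubling per level.
#' @param image_size `(H, W)` input size contract.
#' @param classes output classes (background, myocardium).
#' @param learning_rate,batch_size,momentum SGD-with-momentum settings.
#' @return a `seg_config` list.
#' @export
seg_config <- function(in_frames = 3L, levels = 4L, base_filters = 32L,
                       image_size = c(256L, 256L), classes = 2L,
                       learning_rate = 2e-4, batch_size = 6L, momentum = 0.9) {
  if (in_frames < 1) stop_input("in_frames must be >= 1")
  if (any(image_size %% 2^levels != 0))
    stop_shape("image_size %s must be divisible by 2^levels = %d",
               paste(image_size, collapse = "x"), 2^levels)
  structure(list(in_frames = as.integer(in_frames), levels = as.integer(levels),
                 base_filters = as.integer(base_filters),
                 image_size = as.integer(image_size), classes = as.integer(classes),
                 learning_rate = learning_rate, batch_size = as.integer(batch_size),
                 momentum = momentum),
            class = "seg_config")
}

#' Build a 3D cardiac segmentation network
#'
#' Weights are He-initialized from the given seed; two builds with the same
#' configuration and seed are identical.
#'
#' @param config a [seg_config()].
#' @param seed RNG seed for weight initialization.
#' @return a `csn_model` (list of `config`, `params`, `seed`).
#' @examples
#' cfg <- seg_config(levels = 2, base_filters = 4, image_size = c(16, 16))
#' model <- build_3dcsn(cfg, seed = 1)
#' pred <- predict_volume(model, array(0.5, c(16, 16, 3)))
#' dim(pred$probabilities)
#' @export
build_3dcsn <- function(config, seed = 0L) {
  stopifnot(inherits(config, "seg_config"))
  L <- config$levels; base <- config$base_filters
  ch <- base * 2^(0:L) # level channels, ch[L+1] = bottleneck
  params <- with_seed(seed, {
    p <- list()
    cin <- 1L
    for (l in seq_len(L)) {
      p[[sprintf("enc%da", l)]] <- new_conv3d(cin, ch[l])
      p[[sprintf("enc%db", l)]] <- new_conv3d(ch[l], ch[l])
      cin <- ch[l]
    }
    p[["bota"]] <- new_conv3d(ch[L], ch[L + 1])
    p[["botb"]] <- new_conv3d(ch[L + 1], ch[L + 1])
    for (l in rev(seq_len(L))) {
      above <- if (l == L) ch[L + 1] else ch[l + 1]
      p[[sprintf("up%d", l)]] <- new_upconv(above, ch[l])
      p[[sprintf("dec%da", l)]] <- new_conv3d(2L * ch[l], ch[l])
      p[[sprintf("dec%db", l)]] <- new_conv3d(ch[l], ch[l])
    }
    p[["out"]] <- new_conv3d(ch[1], config$classes, k = c(1L, 1L, 1L))
    p
  })
  structure(list(config = config, params = params, seed = seed),
            class = "csn_model")
}

#' @export
print.csn_model <- function(x, ...) {
  np <- sum(vapply(x$params, function(p) length(p$W) + length(p$b), numeric(1)))
  cat(sprintf("<csn_model> %d levels, base %d, %s px, %s parameters\n",
              x$config$levels, x$config$base_filters,
              paste(x$config$image_size, collapse = "x"),
              format(np, big.mark = ",")))
  invisible(x)
}

seg_check_input <- function(config, x) {
  d <- dim(x)
  if (d[1] != 1 || d[2] != config$in_frames)
    stop_shape("expected a 1 x %d x H x W volume", config$in_frames)
  if (any(d[3:4] %% 2^config$levels != 0))
    stop_shape("spatial size %dx%d is not divisible by 2^levels = %d",
               d[3], d[4], 2^config$levels)
}

# Forward pass; x is [1, D, H, W]. Returns logits and (optionally) caches.
seg_forward <- function(model, x, keep_cache = FALSE) {
  p <- model$params; L <- model$config$levels
  seg_check_input(model$config, x)
  cache <- list()
  cur <- x
  skips <- list()
  for (l in seq_len(L)) {
    c1 <- conv3d_fwd(cur, p[[sprintf("enc%da", l)]]); r1 <- relu_fwd(c1$out)
    c2 <- conv3d_fwd(r1$out, p[[sprintf("enc%db", l)]]); r2 <- relu_fwd(c2$out)
    pl <- maxpool_hw_fwd(r2$out)
    skips[[l]] <- r2$out
    if (keep_cache) cache[[sprintf("enc%d", l)]] <- list(c1 = c1$cache, r1 = r1$cache,
                                                         c2 = c2$cache, r2 = r2$cache,
                                                         pool = pl$cache)
    cur <- pl$out
  }
  b1 <- conv3d_fwd(cur, p$bota); br1 <- relu_fwd(b1$out)
  b2 <- conv3d_fwd(br1$out, p$botb); br2 <- relu_fwd(b2$out)
  if (keep_cache) cache$bot <- list(c1 = b1$cache, r1 = br1$cache,
                                    c2 = b2$cache, r2 = br2$cache)
  cur <- br2$out
  for (l in rev(seq_len(L))) {
    up <- upconv_hw_fwd(cur, p[[sprintf("up%d", l)]])
    cat_in <- array(0, dim(up$out) + c(dim(skips[[l]])[1], 0, 0, 0))
    n_skip <- dim(skips[[l]])[1]
    cat_in[seq_len(n_skip), , , ] <- skips[[l]]
    cat_in[n_skip + seq_len(dim(up$out)[1]), , , ] <- up$out
    d1 <- conv3d_fwd(cat_in, p[[sprintf("dec%da", l)]]); dr1 <- relu_fwd(d1$out)
    d2 <- conv3d_fwd(dr1$out, p[[sprintf("dec%db", l)]]); dr2 <- relu_fwd(d2$out)
    if (keep_cache) cache[[sprintf("dec%d", l)]] <- list(up = up$cache, n_skip = n_skip,
                                                         c1 = d1$cache, r1 = dr1$cache,
                                                         c2 = d2$cache, r2 = dr2$cache)
    cur <- dr2$out
  }
  out <- conv3d_fwd(cur, p$out)
  if (keep_cache) cache$out <- out$cache
  list(logits = out$out, cache = cache)
}

# Backward pass through seg_forward; returns the flat gradient list.
seg_backward <- function(model, dlogits, cache) {
  p <- model$params; L <- model$config$levels
  grads <- list()
  for (nm in names(p)) {
    grads[[paste0(nm, ".W")]] <- p[[nm]]$W * 0
    grads[[paste0(nm, ".b")]] <- p[[nm]]$b * 0
  }
  bw <- conv3d_bwd(dlogits, p$out, cache$out)
  grads <- acc_grad(grads, "out", bw$dW, bw$db)
  dcur <- bw$dx
  dskips <- list()
  for (l in seq_len(L)) {
    cc <- cache[[sprintf("dec%d", l)]]
    dd2 <- relu_bwd(dcur, cc$r2)
    b2 <- conv3d_bwd(dd2, p[[sprintf("dec%db", l)]], cc$c2)
    grads <- acc_grad(grads, sprintf("dec%db", l), b2$dW, b2$db)
    dd1 <- relu_bwd(b2$dx, cc$r1)
    b1 <- conv3d_bwd(dd1, p[[sprintf("dec%da", l)]], cc$c1)
    grads <- acc_grad(grads, sprintf("dec%da", l), b1$dW, b1$db)
    n_skip <- cc$n_skip
    dskips[[l]] <- b1$dx[seq_len(n_skip), , , , drop = FALSE]
    dup <- b1$dx[n_skip + seq_len(dim(b1$dx)[1] - n_skip), , , , drop = FALSE]
    bu <- upconv_hw_bwd(dup, p[[sprintf("up%d", l)]], cc$up)
    grads <- acc_grad(grads, sprintf("up%d", l), bu$dW, bu$db)
    dcur <- bu$dx
  }
  cc <- cache$bot
  db2 <- relu_bwd(dcur, cc$r2)
  b2 <- conv3d_bwd(db2, p$botb, cc$c2)
  grads <- acc_grad(grads, "botb", b2$dW, b2$db)
  db1 <- relu_bwd(b2$dx, cc$r1)
  b1 <- conv3d_bwd(db1, p$bota, cc$c1)
  grads <- acc_grad(grads, "bota", b1$dW, b1$db)
  dcur <- b1$dx
  for (l in rev(seq_len(L))) {
    cc <- cache[[sprintf("enc%d", l)]]
    dpool <- maxpool_hw_bwd(dcur, cc$pool)
    dpool <- dpool + dskips[[l]]
    dd2 <- relu_bwd(dpool, cc$r2)
    b2 <- conv3d_bwd(dd2, p[[sprintf("enc%db", l)]], cc$c2)
    grads <- acc_grad(grads, sprintf("enc%db", l), b2$dW, b2$db)
    dd1 <- relu_bwd(b2$dx, cc$r1)
    b1 <- conv3d_bwd(dd1, p[[sprintf("enc%da", l)]], cc$c1)
    grads <- acc_grad(grads, sprintf("enc%da", l), b1$dW, b1$db)
    dcur <- b1$dx
  }
  grads
}

#' Segment one 3-frame volume
#'
#' @param model a `csn_model`, or a function mapping an `H x W x 3` volume to
#'   a `classes x 3 x H x W` probability array (estimator plug-in).
#' @param volume `H x W x 3` intensity array in `[0, 1]`.
#' @return a `seg_prediction`: `probabilities` (`classes x 3 x H x W`,
#'   summing to 1 over classes at every voxel) and `mask` (`H x W x 3` argmax
#'   labels, 1 = myocardium).
#' @export
predict_volume <- function(model, volume) {
  if (is.function(model)) {
    probs <- model(volume)
  } else {
    x <- array(aperm(volume, c(3, 1, 2)), c(1, dim(volume)[3], dim(volume)[1], dim(volume)[2]))
    probs <- softmax_classes(seg_forward(model, x)$logits)
  }
  lab <- array(0L, dim(probs)[c(3, 4, 2)])
  for (t in seq_len(dim(probs)[2]))
    lab[, , t] <- matrix(as.integer(probs[2, t, , ] >= probs[1, t, , ]),
                         dim(probs)[3], dim(probs)[4])
  structure(list(probabilities = probs, mask = lab), class = "seg_prediction")
}

# Loss and gradient from logits; target is [D, H, W] integer labels in {0, 1}.
dice_ce_from_logits <- function(logits, target, eps = 1e-7) {
  co <- dim(logits)[1]
  n <- prod(dim(logits)[-1])
  y <- array(0, dim(logits))
  y[1, , , ] <- 1 - target
  y[2, , , ] <- target
  p <- softmax_classes(logits)
  ce <- -sum(y * log(pmax(p, 1e-12))) / n
  num <- den <- numeric(co)
  for (c in seq_len(co)) {
    num[c] <- 2 * sum(p[c, , , ] * y[c, , , ]) + eps
    den[c] <- sum(p[c, , , ]) + sum(y[c, , , ]) + eps
  }
  dice <- num / den
  loss <- ce + (1 - mean(dice))
  # gradient wrt probabilities, then chain through the softmax
  g <- array(0, dim(logits))
  for (c in seq_len(co))
    g[c, , , ] <- -(1 / co) * (2 * y[c, , , ] * den[c] - num[c]) / den[c]^2
  g <- g - y / pmax(p, 1e-12) / n
  gm <- matrix(g, co); pm <- matrix(p, co)
  dz <- pm * sweep(gm, 2, colSums(gm * pm))
  list(loss = loss, dlogits = array(dz, dim(logits)),
       ce = ce, dice = mean(dice))
}

#' Dice + cross-entropy segmentation loss
#'
#' Mean voxel cross-entropy plus one minus the mean soft Dice overlap across
#' classes: zero for a one-hot correct prediction, `ln 2` cross-entropy for a
#' uniform binary prediction.
#'
#' @param prediction a `seg_prediction`, or a `classes x D x H x W`
#'   probability array.
#' @param target `H x W x D` (or `D x H x W`) integer labels in `{0, 1}`.
#' @return scalar loss with attributes `ce` and `dice`.
#' @export
dice_ce_loss <- function(prediction, target, eps = 1e-7) {
  probs <- if (inherits(prediction, "seg_prediction")) prediction$probabilities else prediction
  dp <- dim(probs)
  target <- as.array(target)
  if (length(dim(target)) == 3 && all(dim(target) == dp[c(3, 4, 2)]))
    target <- aperm(target, c(3, 1, 2)) # H x W x D -> D x H x W
  if (!all(dim(target) == dp[-1])) stop_shape("prediction and target shapes differ")
  if (!all(target %in% c(0, 1))) stop_input("target labels must be 0/1")
  n <- prod(dp[-1]); co <- dp[1]
  y <- array(0, dp)
  y[1, , , ] <- 1 - target
  y[2, , , ] <- target
  ce <- -sum(y * log(pmax(probs, 1e-12))) / n
  dice <- numeric(co)
  for (c in seq_len(co)) {
    dice[c] <- (2 * sum(probs[c, , , ] * y[c, , , ]) + eps) /
      (sum(probs[c, , , ]) + sum(y[c, , , ]) + eps)
  }
  structure(ce + (1 - mean(dice)), ce = ce, dice = mean(dice))
}

#' Train the segmentation network
#'
#' Stochastic gradient descent with momentum on the Dice + cross-entropy
#' loss. Deterministic for a fixed seed; zero iterations leave the weights
#' untouched.
#'
#' @param model a `csn_model`.
#' @param items segmentation items from [make_training_items()].
#' @param iterations SGD iterations.
#' @param seed RNG seed for batch sampling.
#' @param lr,batch_size,momentum optional overrides of the config values.
#' @return list `model` (trained) and `history` (loss per iteration).
#' @export
train_segmentation <- function(model, items, iterations, seed = 1L,
                               lr = model$config$learning_rate,
                               batch_size = model$config$batch_size,
                               momentum = model$config$momentum) {
  stopifnot(inherits(model, "csn_model"))
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
        vol <- items[[s]]$volume
        x <- array(aperm(vol, c(3, 1, 2)), c(1, dim(vol)[3], dim(vol)[1], dim(vol)[2]))
        tgt <- aperm(items[[s]]$labels, c(3, 1, 2))
        fw <- seg_forward(model, x, keep_cache = TRUE)
        lo <- dice_ce_from_logits(fw$logits, tgt)
        g <- seg_backward(model, lo$dlogits / length(sel), fw$cache)
        grads <- if (is.null(grads)) g else Map("+", grads, g)
        loss_acc <- loss_acc + lo$loss / length(sel)
      }
      history[it] <- loss_acc
      flat <- unlist_params(model$params)
      st <- sgdm_step(flat, grads, state, lr, momentum)
      state <- st$state
      model$params <- relist_params(st$params, model$params)
    }
  })
  list(model = model, history = history)
}

unlist_params <- function(params) {
  out <- list()
  for (nm in names(params)) {
    out[[paste0(nm, ".W")]] <- params[[nm]]$W
    out[[paste0(nm, ".b")]] <- params[[nm]]$b
  }
  out
}

relist_params <- function(flat, template) {
  for (nm in names(template)) {
    template[[nm]]$W <- flat[[paste0(nm, ".W")]]
    template[[nm]]$b <- flat[[paste0(nm, ".b")]]
  }
  template
}

#' Segment every frame of a video
#'
#' Runs the network on all sliding 3-frame windows (stride 1) and combines
#' the overlapping per-frame predictions by averaging class probabilities
#' before the argmax, so each interior frame aggregates up to three windows.
#'
#' @param model a `csn_model` or plug-in function (see [predict_volume()]).
#' @param video a [video_sequence()] with at least 3 frames.
#' @return a [mask_sequence()] of the same length.
#' @export
segment_video <- function(model, video) {
  n <- n_frames(video)
  if (n < 3) stop_input("segmentation needs at least 3 frames, got %d", n)
  h <- dim(video)[1]; w <- dim(video)[2]
  classes <- if (is.function(model)) 2L else model$config$classes
  acc <- array(0, c(classes, n, h, w))
  cnt <- numeric(n)
  for (t0 in seq_len(n - 2)) {
    pred <- predict_volume(model, unclass(video)[, , t0:(t0 + 2), drop = FALSE])
    for (j in 0:2) {
      acc[, t0 + j, , ] <- acc[, t0 + j, , ] + pred$probabilities[, j + 1, , ]
      cnt[t0 + j] <- cnt[t0 + j] + 1
    }
  }
  masks <- array(0L, c(h, w, n))
  for (t in seq_len(n)) {
    p1 <- acc[2, t, , ] / cnt[t]
    p0 <- acc[1, t, , ] / cnt[t]
    masks[, , t] <- matrix(as.integer(p1 >= p0), h, w)
  }
  mask_sequence(masks, pixel_spacing(video))
}

#' Dice similarity coefficient of two binary masks
#'
#' `2 |A ∩ B| / (|A| + |B|)`; two empty masks score 1 by convention (logged
#' via a message).
#'
#' @param a,b binary matrices or arrays of equal shape.
#' @return DSC in `[0, 1]`.
#' @export
dsc <- function(a, b) {
  if (!all(dim(a) == dim(b))) stop_shape("mask shapes differ")
  sa <- sum(a != 0); sb <- sum(b != 0)
  if (sa + sb == 0) {
    message("dsc: both masks empty; returning 1 by convention")
    return(1)
  }
  2 * sum(a != 0 & b != 0) / (sa + sb)
}

#' Save or load a model checkpoint (config + weights)
#'
#' @param model a `csn_model` or `raft_model`.
#' @param path checkpoint path.
#' @return `load_checkpoint()` returns the model.
#' @export
save_checkpoint <- function(model, path) {
  saveRDS(model, path)
  invisible(path)
}

#' @rdname save_checkpoint
#' @export
load_checkpoint <- function(path) {
  if (!file.exists(path)) stop_format("checkpoint not found: %s", path)
  m <- readRDS(path)
  if (!inherits(m, c("csn_model", "raft_model")))
    stop_format("not an echostrain checkpoint: %s", path)
  m
}
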