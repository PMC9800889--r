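# Minimal neural-network primitives with explicit forward/backward passes.
# No deep-learning framework is available in this R stack, so convolutions
# are implemented as im2col + BLAS matrix multiplication with hand-derived
# gradients. Feature maps are arrays [C, H, W] (2D) or [C, D, H, W] (3D,
# D = frames); weights are arrays [Cout, Cin, k...] flattened column-major to
# [Cout, Cin * prod(k)] so weight-matrix and im2col row orders agree.

nn_he_init <- function(dims, fan_in) {
  array(stats::rnorm(prod(dims), sd = sqrt(2 / fan_in)), dims)
}

new_conv2d <- function(cin, cout, k = 3) {
  list(W = nn_he_init(c(cout, cin, k, k), cin * k * k), b = numeric(cout), k = k)
}

new_conv3d <- function(cin, cout, k = c(3, 3, 3)) {
  list(W = nn_he_init(c(cout, cin, k), cin * prod(k)), b = numeric(cout), k = k)
}

# ---- 2D convolution ---------------------------------------------------------

im2col2d <- function(x, k, stride, pad) {
  cin <- dim(x)[1]; h <- dim(x)[2]; w <- dim(x)[3]
  hp <- h + 2 * pad; wp <- w + 2 * pad
  xp <- array(0, c(cin, hp, wp))
  xp[, pad + seq_len(h), pad + seq_len(w)] <- x
  h2 <- (hp - k) %/% stride + 1L; w2 <- (wp - k) %/% stride + 1L
  cols <- matrix(0, cin * k * k, h2 * w2)
  for (j in seq_len(k)) for (i in seq_len(k)) {
    rows <- (j - 1L) * cin * k + (i - 1L) * cin + seq_len(cin)
    cols[rows, ] <- matrix(xp[, seq(i, by = stride, length.out = h2),
                              seq(j, by = stride, length.out = w2)], cin)
  }
  list(cols = cols, h2 = h2, w2 = w2, hp = hp, wp = wp)
}

col2im2d <- function(dcols, cin, h, w, k, stride, pad, h2, w2) {
  hp <- h + 2 * pad; wp <- w + 2 * pad
  dxp <- array(0, c(cin, hp, wp))
  for (j in seq_len(k)) for (i in seq_len(k)) {
    rows <- (j - 1L) * cin * k + (i - 1L) * cin + seq_len(cin)
    si <- seq(i, by = stride, length.out = h2)
    sj <- seq(j, by = stride, length.out = w2)
    dxp[, si, sj] <- dxp[, si, sj, drop = FALSE] + array(dcols[rows, ], c(cin, h2, w2))
  }
  dxp[, pad + seq_len(h), pad + seq_len(w), drop = FALSE]
}

conv2d_fwd <- function(x, p, stride = 1L, pad = (p$k - 1L) %/% 2L) {
  ic <- im2col2d(x, p$k, stride, pad)
  wm <- matrix(p$W, dim(p$W)[1])
  out <- wm %*% ic$cols + p$b
  list(out = array(out, c(dim(p$W)[1], ic$h2, ic$w2)),
       cache = list(cols = ic$cols, x_dim = dim(x), stride = stride, pad = pad,
                    h2 = ic$h2, w2 = ic$w2, k = p$k))
}

conv2d_bwd <- function(dout, p, cache) {
  co <- dim(p$W)[1]
  dm <- matrix(dout, co)
  wm <- matrix(p$W, co)
  dW <- array(dm %*% t(cache$cols), dim(p$W))
  db <- rowSums(dm)
  dcols <- crossprod(wm, dm)
  dx <- col2im2d(dcols, cache$x_dim[1], cache$x_dim[2], cache$x_dim[3],
                 cache$k, cache$stride, cache$pad, cache$h2, cache$w2)
  list(dx = dx, dW = dW, db = db)
}

# ---- 3D convolution (stride 1, "same" padding) ------------------------------

im2col3d <- function(x, k) {
  cin <- dim(x)[1]; d <- dim(x)[2]; h <- dim(x)[3]; w <- dim(x)[4]
  p <- (k - 1L) %/% 2L
  xp <- array(0, c(cin, d + 2 * p[1], h + 2 * p[2], w + 2 * p[3]))
  xp[, p[1] + seq_len(d), p[2] + seq_len(h), p[3] + seq_len(w)] <- x
  cols <- matrix(0, cin * prod(k), d * h * w)
  for (c3 in seq_len(k[3])) for (c2 in seq_len(k[2])) for (c1 in seq_len(k[1])) {
    rows <- ((c3 - 1L) * k[2] * k[1] + (c2 - 1L) * k[1] + (c1 - 1L)) * cin + seq_len(cin)
    cols[rows, ] <- matrix(xp[, c1 + seq_len(d) - 1L, c2 + seq_len(h) - 1L,
                              c3 + seq_len(w) - 1L], cin)
  }
  cols
}

conv3d_fwd <- function(x, p) {
  cols <- im2col3d(x, p$k)
  wm <- matrix(p$W, dim(p$W)[1])
  out <- wm %*% cols + p$b
  list(out = array(out, c(dim(p$W)[1], dim(x)[2:4])),
       cache = list(cols = cols, x_dim = dim(x), k = p$k))
}

conv3d_bwd <- function(dout, p, cache) {
  co <- dim(p$W)[1]
  dm <- matrix(dout, co)
  dW <- array(dm %*% t(cache$cols), dim(p$W))
  db <- rowSums(dm)
  dcols <- crossprod(matrix(p$W, co), dm)
  cin <- cache$x_dim[1]; d <- cache$x_dim[2]; h <- cache$x_dim[3]; w <- cache$x_dim[4]
  k <- cache$k; p3 <- (k - 1L) %/% 2L
  dxp <- array(0, c(cin, d + 2 * p3[1], h + 2 * p3[2], w + 2 * p3[3]))
  for (c3 in seq_len(k[3])) for (c2 in seq_len(k[2])) for (c1 in seq_len(k[1])) {
    rows <- ((c3 - 1L) * k[2] * k[1] + (c2 - 1L) * k[1] + (c1 - 1L)) * cin + seq_len(cin)
    sl1 <- c1 + seq_len(d) - 1L; sl2 <- c2 + seq_len(h) - 1L; sl3 <- c3 + seq_len(w) - 1L
    dxp[, sl1, sl2, sl3] <- dxp[, sl1, sl2, sl3, drop = FALSE] +
      array(dcols[rows, ], c(cin, d, h, w))
  }
  list(dx = dxp[, p3[1] + seq_len(d), p3[2] + seq_len(h), p3[3] + seq_len(w), drop = FALSE],
       dW = dW, db = db)
}

# ---- activations ------------------------------------------------------------

relu_fwd <- function(x) list(out = pmax(x, 0), cache = x > 0)
relu_bwd <- function(dout, cache) dout * cache
sigmoid <- function(x) 1 / (1 + exp(-x))

# softmax over the first (class) dimension of [C, ...]
softmax_classes <- function(z) {
  co <- dim(z)[1]
  zm <- matrix(z, co)
  zm <- sweep(zm, 2, apply(zm, 2, max))
  e <- exp(zm)
  array(sweep(e, 2, colSums(e), "/"), dim(z))
}

# ---- spatial 2x2 max pooling over (H, W) of [C, D, H, W] --------------------

maxpool_hw_fwd <- function(x) {
  d <- dim(x)
  s <- list(x[, , seq(1, d[3], 2), seq(1, d[4], 2), drop = FALSE],
            x[, , seq(2, d[3], 2), seq(1, d[4], 2), drop = FALSE],
            x[, , seq(1, d[3], 2), seq(2, d[4], 2), drop = FALSE],
            x[, , seq(2, d[3], 2), seq(2, d[4], 2), drop = FALSE])
  mx <- pmax(s[[1]], s[[2]], s[[3]], s[[4]])
  which4 <- (s[[1]] == mx) * 1
  which4[which4 == 0 & s[[2]] == mx] <- 2
  which4[which4 == 0 & s[[3]] == mx] <- 3
  which4[which4 == 0 & s[[4]] == mx] <- 4
  list(out = mx, cache = list(which4 = which4, d = d))
}

maxpool_hw_bwd <- function(dout, cache) {
  d <- cache$d
  dx <- array(0, d)
  sel <- list(list(seq(1, d[3], 2), seq(1, d[4], 2)),
              list(seq(2, d[3], 2), seq(1, d[4], 2)),
              list(seq(1, d[3], 2), seq(2, d[4], 2)),
              list(seq(2, d[3], 2), seq(2, d[4], 2)))
  for (q in 1:4) {
    m <- dout * (cache$which4 == q)
    dx[, , sel[[q]][[1]], sel[[q]][[2]]] <- dx[, , sel[[q]][[1]], sel[[q]][[2]]] + m
  }
  dx
}

# ---- spatial 2x2 transposed convolution (upconvolution) of [C, D, H, W] -----

new_upconv <- function(cin, cout) {
  list(W = nn_he_init(c(cout, cin, 2, 2), cin * 4), b = numeric(cout))
}

upconv_hw_fwd <- function(x, p) {
  d <- dim(x); co <- dim(p$W)[1]
  xm <- matrix(x, d[1])
  out <- array(0, c(co, d[2], 2 * d[3], 2 * d[4]))
  for (dj in 1:2) for (di in 1:2) {
    wq <- matrix(p$W[, , di, dj], co)
    out[, , di + 2 * (seq_len(d[3]) - 1L), dj + 2 * (seq_len(d[4]) - 1L)] <-
      array(wq %*% xm + p$b, c(co, d[2], d[3], d[4]))
  }
  list(out = out, cache = list(x = x, d = d))
}

upconv_hw_bwd <- function(dout, p, cache) {
  d <- cache$d; co <- dim(p$W)[1]
  xm <- matrix(cache$x, d[1])
  dW <- array(0, dim(p$W)); db <- numeric(co)
  dxm <- matrix(0, d[1], ncol(xm))
  for (dj in 1:2) for (di in 1:2) {
    dq <- matrix(dout[, , di + 2 * (seq_len(d[3]) - 1L),
                      dj + 2 * (seq_len(d[4]) - 1L)], co)
    dW[, , di, dj] <- dq %*% t(xm)
    db <- db + rowSums(dq)
    dxm <- dxm + crossprod(matrix(p$W[, , di, dj], co), dq)
  }
  list(dx = array(dxm, d), dW = dW, db = db)
}

# ---- bilinear resize of [C, h, w] (fixed linear map; backward = adjoint) ----

bilinear_matrix <- function(n_out, n_in) {
  # pixel-center convention: output center i maps to (i + 0.5) * n_in/n_out - 0.5
  m <- matrix(0, n_out, n_in)
  src <- (seq_len(n_out) - 0.5) * n_in / n_out - 0.5
  i0 <- floor(src); f <- src - i0
  for (r in seq_len(n_out)) {
    a <- clamp(i0[r], 0, n_in - 1); b <- clamp(i0[r] + 1, 0, n_in - 1)
    m[r, a + 1] <- m[r, a + 1] + (1 - f[r])
    m[r, b + 1] <- m[r, b + 1] + f[r]
  }
  m
}

bilinear_resize_fwd <- function(x, h_out, w_out) {
  d <- dim(x)
  rm <- bilinear_matrix(h_out, d[2]); cm <- bilinear_matrix(w_out, d[3])
  out <- array(0, c(d[1], h_out, w_out))
  for (c in seq_len(d[1])) out[c, , ] <- rm %*% x[c, , ] %*% t(cm)
  list(out = out, cache = list(rm = rm, cm = cm, d = d))
}

bilinear_resize_bwd <- function(dout, cache) {
  d <- cache$d
  dx <- array(0, d)
  for (c in seq_len(d[1])) dx[c, , ] <- t(cache$rm) %*% dout[c, , ] %*% cache$cm
  dx
}

# ---- optimizers (flat named lists of parameter arrays) ----------------------

sgdm_step <- function(params, grads, state, lr, momentum = 0.9) {
  if (is.null(state)) state <- lapply(params, function(p) p * 0)
  for (nm in names(params)) {
    state[[nm]] <- momentum * state[[nm]] + grads[[nm]]
    params[[nm]] <- params[[nm]] - lr * state[[nm]]
  }
  list(params = params, state = state)
}

adamw_step <- function(params, grads, state, lr, betas = c(0.9, 0.999),
                       eps = 1e-8, weight_decay = 1e-5) {
  if (is.null(state))
    state <- list(m = lapply(params, function(p) p * 0),
                  v = lapply(params, function(p) p * 0), t = 0)
  state$t <- state$t + 1
  b1 <- betas[1]; b2 <- betas[2]
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
    state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
    mhat <- state$m[[nm]] / (1 - b1^state$t)
    vhat <- state$v[[nm]] / (1 - b2^state$t)
    params[[nm]] <- params[[nm]] - lr * (mhat / (sqrt(vhat) + eps) +
                                           weight_decay * params[[nm]])
  }
  list(params = params, state = state)
}

# Accumulate a layer's weight gradients into the flat gradient list.
acc_grad <- function(grads, prefix, dW, db) {
  grads[[paste0(prefix, ".W")]] <- grads[[paste0(prefix, ".W")]] + dW
  grads[[paste0(prefix, ".b")]] <- grads[[paste0(prefix, ".b")]] + db
  grads
}

zero_grads <- function(params) lapply(params, function(p) p * 0)
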