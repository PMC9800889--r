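# Internal helpers shared across modules. Coordinate convention throughout the
# package: (x, y) = (column, row), 0-based, pixel centers at integer positions;
# an image array `a` stores the value of pixel (x, y) at a[y + 1, x + 1].

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("echostrain_input_error", "echostrain_error")))
}
stop_shape <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("echostrain_shape_error", "echostrain_error")))
}
stop_geometry <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("echostrain_geometry_error", "echostrain_error")))
}
stop_format <- function(msg, ...) {
  stop(errorCondition(sprintf(msg, ...),
                      class = c("echostrain_format_error", "echostrain_error")))
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG stream.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# 0-based pixel-center coordinate grids for an H x W image.
pixel_grid <- function(h, w) {
  list(x = matrix(rep(0:(w - 1), each = h), h, w),
       y = matrix(rep(0:(h - 1), times = w), h, w))
}

# Bilinear sampling of a matrix at 0-based sub-pixel coordinates.
# Out-of-range taps contribute `fill` (default 0).
bilinear_sample <- function(mat, x, y, fill = 0) {
  h <- nrow(mat); w <- ncol(mat)
  x0 <- floor(x); y0 <- floor(y)
  fx <- x - x0; fy <- y - y0
  tap <- function(xi, yi) {
    ok <- xi >= 0 & xi <= (w - 1) & yi >= 0 & yi <= (h - 1)
    v <- rep(fill, length(xi))
    if (any(ok)) v[ok] <- mat[cbind(yi[ok] + 1, xi[ok] + 1)]
    v
  }
  tap(x0, y0) * (1 - fx) * (1 - fy) +
    tap(x0 + 1, y0) * fx * (1 - fy) +
    tap(x0, y0 + 1) * (1 - fx) * fy +
    tap(x0 + 1, y0 + 1) * fx * fy
}

# Separable Gaussian smoothing with replicate padding.
smooth_gaussian <- function(mat, sigma) {
  if (sigma <= 0) return(mat)
  r <- max(1L, ceiling(3 * sigma))
  k <- exp(-((-r:r)^2) / (2 * sigma^2)); k <- k / sum(k)
  sm_1d <- function(m) { # smooth along rows (dim 1)
    n <- nrow(m)
    idx <- function(i) pmin(pmax(i, 1L), n)
    out <- matrix(0, n, ncol(m))
    for (j in seq_along(k)) out <- out + k[j] * m[idx(seq_len(n) + (j - r - 1L)), , drop = FALSE]
    out
  }
  t(sm_1d(t(sm_1d(mat))))
}

# Exact squared Euclidean distance transform (Felzenszwalb & Huttenlocher),
# distance from each pixel to the nearest TRUE pixel. Returns distances in px.
distance_transform <- function(mask) {
  h <- nrow(mask); w <- ncol(mask)
  inf <- (h + w)^2 + 1
  d <- matrix(ifelse(mask, 0, inf), h, w)
  dt1 <- function(f) {
    n <- length(f)
    v <- integer(n); z <- numeric(n + 1); d1 <- numeric(n)
    kk <- 1L; v[1] <- 1L; z[1] <- -Inf; z[2] <- Inf
    for (q in 2:n) {
      s <- ((f[q] + q^2) - (f[v[kk]] + v[kk]^2)) / (2 * q - 2 * v[kk])
      while (s <= z[kk]) {
        kk <- kk - 1L
        s <- ((f[q] + q^2) - (f[v[kk]] + v[kk]^2)) / (2 * q - 2 * v[kk])
      }
      kk <- kk + 1L; v[kk] <- q; z[kk] <- s; z[kk + 1] <- Inf
    }
    kk <- 1L
    for (q in 1:n) {
      while (z[kk + 1] < q) kk <- kk + 1L
      d1[q] <- (q - v[kk])^2 + f[v[kk]]
    }
    d1
  }
  for (i in seq_len(h)) d[i, ] <- dt1(d[i, ])
  for (j in seq_len(w)) d[, j] <- dt1(d[, j])
  sqrt(d)
}

# Connected-component labelling of a binary matrix (8-connectivity).
# Returns an integer matrix of labels (0 = background), largest first.
label_components <- function(mask, connectivity = 8) {
  mask <- mask != 0
  h <- nrow(mask); w <- ncol(mask)
  lab <- matrix(0L, h, w)
  if (connectivity == 8) {
    off <- cbind(c(-1, -1, -1, 0, 0, 1, 1, 1), c(-1, 0, 1, -1, 1, -1, 0, 1))
  } else {
    off <- cbind(c(-1, 1, 0, 0), c(0, 0, -1, 1))
  }
  cur <- 0L
  todo <- which(mask)
  for (start in todo) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue)) {
      p <- queue
      queue <- integer(0)
      pi <- ((p - 1L) %% h) + 1L
      pj <- ((p - 1L) %/% h) + 1L
      for (o in seq_len(nrow(off))) {
        ni <- pi + off[o, 1]; nj <- pj + off[o, 2]
        ok <- ni >= 1 & ni <= h & nj >= 1 & nj <= w
        if (!any(ok)) next
        np <- (nj[ok] - 1L) * h + ni[ok]
        np <- np[mask[np] & lab[np] == 0L]
        if (length(np)) {
          lab[np] <- cur
          queue <- c(queue, np)
        }
      }
      queue <- unique(queue)
    }
  }
  if (cur > 1L) { # relabel so component 1 is the largest
    sizes <- tabulate(lab[lab > 0L], nbins = cur)
    ord <- order(sizes, decreasing = TRUE)
    remap <- integer(cur); remap[ord] <- seq_len(cur)
    lab[lab > 0L] <- remap[lab[lab > 0L]]
  }
  lab
}
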