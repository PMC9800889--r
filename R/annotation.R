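# Semi-automatic annotation: masks from tracked point sets (concave hull) and
# dense flow supervision from sparse point displacements.

#' Sparse displacement fields
#'
#' Holds per-anchor displacement vectors `V_k = P_k(t+1) - P_k(t)` used to
#' supervise the motion network.
#'
#' @param anchors `n x 2` matrix of `(x, y)` positions at frame `t` (0-based px).
#' @param vectors `n x 2` matrix of `(dx, dy)` px/frame displacements.
#' @return a `sparse_displacement` object.
#' @export
sparse_displacement <- function(anchors, vectors) {
  anchors <- as.matrix(anchors); vectors <- as.matrix(vectors)
  if (nrow(anchors) != nrow(vectors)) stop_input("anchors and vectors must have equal length")
  if (nrow(anchors) < 3) stop_input("need at least 3 anchor points")
  structure(list(anchors = anchors, vectors = vectors), class = "sparse_displacement")
}

tri_circumradius <- function(p1, p2, p3) {
  a <- sqrt(sum((p2 - p3)^2)); b <- sqrt(sum((p1 - p3)^2)); c <- sqrt(sum((p1 - p2)^2))
  area2 <- abs((p2[1] - p1[1]) * (p3[2] - p1[2]) - (p3[1] - p1[1]) * (p2[2] - p1[2]))
  if (area2 < 1e-12) return(Inf)
  a * b * c / (2 * area2)
}

#' Concave-hull myocardial mask from a point set
#'
#' Computes the alpha-shape of the points (Delaunay triangulation filtered by
#' triangle circumradius `<= alpha`) and rasterizes its filled interior:
#' pixels inside or on the hull are labelled 1, all others 0. With
#' `alpha = "auto"` the smallest alpha whose kept triangles form a single
#' edge-connected set covering every point is used; an explicit alpha that is
#' too small falls back to that automatic value with a warning.
#'
#' @param points `n x 2` matrix of `(x, y)` coordinates (0-based px), at least
#'   3 non-collinear points. Duplicated points do not change the result.
#' @param image_size `(H, W)` of the output mask.
#' @param alpha circumradius threshold in px, or `"auto"`.
#' @return binary `H x W` matrix mask.
#' @export
concave_hull_mask <- function(points, image_size, alpha = "auto") {
  pts <- unique(as.matrix(points)[, 1:2, drop = FALSE])
  if (nrow(pts) < 3) stop_geometry("need at least 3 distinct points")
  spread <- abs((pts[, 1] - pts[1, 1]) * (pts[2, 2] - pts[1, 2]) -
                  (pts[2, 1] - pts[1, 1]) * (pts[, 2] - pts[1, 2]))
  if (all(spread < 1e-9)) stop_geometry("points are collinear; no hull exists")
  dd <- deldir::deldir(pts[, 1], pts[, 2], suppressMsge = TRUE)
  tl <- deldir::triang.list(dd)
  if (!length(tl)) stop_geometry("triangulation failed; degenerate point set")
  tris <- t(vapply(tl, function(tr) c(tr$ptNum, tri_circumradius(
    c(tr$x[1], tr$y[1]), c(tr$x[2], tr$y[2]), c(tr$x[3], tr$y[3]))), numeric(4)))
  colnames(tris) <- c("i", "j", "k", "r")

  keep_ok <- function(keep) { # single edge-connected set covering all points
    if (!any(keep)) return(FALSE)
    kt <- tris[keep, 1:3, drop = FALSE]
    if (!all(seq_len(nrow(pts)) %in% kt)) return(FALSE)
    if (sum(keep) == 1) return(TRUE)
    edges <- do.call(rbind, lapply(seq_len(nrow(kt)), function(m) {
      v <- sort(kt[m, ]); cbind(tri = m, e = c(paste(v[1], v[2]), paste(v[1], v[3]), paste(v[2], v[3])))
    }))
    by_edge <- split(as.integer(edges[, "tri"]), edges[, "e"])
    adj <- do.call(rbind, lapply(by_edge, function(v)
      if (length(v) == 2) v else NULL))
    g <- igraph::make_empty_graph(n = nrow(kt), directed = FALSE)
    if (!is.null(adj)) g <- igraph::add_edges(g, as.vector(t(adj)))
    igraph::count_components(g) == 1
  }

  radii <- sort(unique(tris[, "r"]))
  auto_alpha <- radii[which(vapply(radii, function(a) keep_ok(tris[, "r"] <= a), logical(1)))[1]]
  if (is.na(auto_alpha)) auto_alpha <- max(radii)
  if (identical(alpha, "auto")) {
    alpha_use <- auto_alpha
  } else {
    alpha_use <- as.numeric(alpha)
    if (!keep_ok(tris[, "r"] <= alpha_use)) {
      warning(sprintf("alpha = %.3g yields a disconnected hull; falling back to alpha = %.3g",
                      alpha_use, auto_alpha))
      alpha_use <- auto_alpha
    }
  }
  keep <- tris[, "r"] <= alpha_use

  h <- image_size[1]; w <- image_size[2]
  mask <- matrix(0L, h, w)
  eps <- 1e-9
  for (m in which(keep)) {
    v <- tris[m, 1:3]
    tx <- pts[v, 1]; ty <- pts[v, 2]
    xr <- clamp(c(floor(min(tx)), ceiling(max(tx))), 0, w - 1)
    yr <- clamp(c(floor(min(ty)), ceiling(max(ty))), 0, h - 1)
    if (xr[2] < xr[1] || yr[2] < yr[1]) next
    gx <- rep(xr[1]:xr[2], each = yr[2] - yr[1] + 1)
    gy <- rep(yr[1]:yr[2], times = xr[2] - xr[1] + 1)
    d <- (tx[2] - tx[1]) * (ty[3] - ty[1]) - (tx[3] - tx[1]) * (ty[2] - ty[1])
    l1 <- ((gx - tx[1]) * (ty[3] - ty[1]) - (gy - ty[1]) * (tx[3] - tx[1])) / d
    l2 <- ((gy - ty[1]) * (tx[2] - tx[1]) - (gx - tx[1]) * (ty[2] - ty[1])) / d
    inside <- l1 >= -eps & l2 >= -eps & (l1 + l2) <= 1 + eps
    if (any(inside)) mask[cbind(gy[inside] + 1, gx[inside] + 1)] <- 1L
  }
  attr(mask, "alpha") <- alpha_use
  mask
}

# Thin-plate-spline scattered interpolation: exact at anchors and exact for
# constant/affine fields (the affine part is represented analytically).
tps_fit <- function(x, y, v) {
  n <- length(x)
  r2 <- outer(x, x, "-")^2 + outer(y, y, "-")^2
  K <- ifelse(r2 == 0, 0, 0.5 * r2 * log(pmax(r2, 1e-300)))
  P <- cbind(1, x, y)
  A <- rbind(cbind(K, P), cbind(t(P), matrix(0, 3, 3)))
  sol <- tryCatch(solve(A, c(v, 0, 0, 0)),
                  error = function(e) stop_geometry("degenerate anchor layout: %s", conditionMessage(e)))
  list(w = sol[1:n], a = sol[n + 1:3], x = x, y = y)
}

tps_eval <- function(f, xo, yo) {
  r2 <- outer(xo, f$x, "-")^2 + outer(yo, f$y, "-")^2
  K <- ifelse(r2 == 0, 0, 0.5 * r2 * log(pmax(r2, 1e-300)))
  drop(K %*% f$w) + f$a[1] + f$a[2] * xo + f$a[3] * yo
}

# Ray-cast point-in-polygon (vertices vx, vy), inclusive of the boundary.
point_in_polygon <- function(px, py, vx, vy, tol = 1e-9) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  on_edge <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- vx[i]; yi <- vy[i]; xj <- vx[j]; yj <- vy[j]
    cross <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- xor(inside, cross)
    seg2 <- (xj - xi)^2 + (yj - yi)^2
    tproj <- if (seg2 > 0) clamp(((px - xi) * (xj - xi) + (py - yi) * (yj - yi)) / seg2, 0, 1) else 0
    d2 <- (px - (xi + tproj * (xj - xi)))^2 + (py - (yi + tproj * (yj - yi)))^2
    on_edge <- on_edge | d2 <= tol
    j <- i
  }
  inside | on_edge
}

#' Dense flow supervision from sparse point displacements
#'
#' Interpolates each displacement component from the anchors to every mask
#' pixel by thin-plate-spline scattered interpolation (smooth, exact at the
#' anchors, and exact for constant and affine fields). Pixels outside the
#' anchors' convex hull are filled by nearest-anchor extrapolation; their
#' count is reported in a message. Pixels outside the mask are zero.
#'
#' @param sparse a [sparse_displacement()].
#' @param mask binary `H x W` matrix; the myocardial region.
#' @return a [flow_field()] with attribute `n_extrapolated`.
#' @export
sparse_to_dense_flow <- function(sparse, mask) {
  stopifnot(inherits(sparse, "sparse_displacement"))
  an <- sparse$anchors; ve <- sparse$vectors
  dup <- duplicated(an)
  if (any(dup)) { an <- an[!dup, , drop = FALSE]; ve <- ve[!dup, , drop = FALSE] }
  if (nrow(an) < 3) stop_input("need at least 3 distinct anchors")
  h <- nrow(mask); w <- ncol(mask)
  idx <- which(mask == 1)
  px <- (idx - 1L) %/% h; py <- (idx - 1L) %% h # 0-based (x, y)
  fx <- matrix(0, h, w); fy <- matrix(0, h, w)
  if (length(idx)) {
    fit_x <- tps_fit(an[, 1], an[, 2], ve[, 1])
    fit_y <- tps_fit(an[, 1], an[, 2], ve[, 2])
    vx <- tps_eval(fit_x, px, py)
    vy <- tps_eval(fit_y, px, py)
    hull <- grDevices::chull(an[, 1], an[, 2])
    outside <- !point_in_polygon(px, py, an[hull, 1], an[hull, 2])
    if (any(outside)) {
      d2 <- outer(px[outside], an[, 1], "-")^2 + outer(py[outside], an[, 2], "-")^2
      nn <- max.col(-d2)
      vx[outside] <- ve[nn, 1]
      vy[outside] <- ve[nn, 2]
      message(sprintf("sparse_to_dense_flow: %d mask pixels outside the anchor hull filled by nearest anchor",
                      sum(outside)))
    }
    fx[idx] <- vx; fy[idx] <- vy
  }
  out <- flow_field(array(c(fx, fy), c(h, w, 2)))
  attr(out, "n_extrapolated") <- if (length(idx)) sum(outside) else 0L
  out
}

#' Clip a raw video into four cine-loops
#'
#' Every-other-frame sampling at the two phase offsets, each stride-2
#' subsequence split into its first and second half: frames `[0..7]` become
#' loops `[0,2]`, `[4,6]`, `[1,3]`, `[5,7]`. The loops partition the original
#' frames and preserve temporal order; the stride doubles the apparent
#' inter-frame motion, widening the displacement distribution seen in
#' training.
#'
#' @param video a [video_sequence()] with at least 8 frames.
#' @return list of 4 [video_sequence()]s, each with attribute
#'   `source_frames` (0-based original indices).
#' @export
clip_cine_loops <- function(video) {
  n <- n_frames(video)
  if (n < 8) stop_input("need at least 8 frames to clip cine-loops, got %d", n)
  halves <- function(v) {
    k <- floor(length(v) / 2)
    list(v[seq_len(k)], v[(k + 1):length(v)])
  }
  evens <- seq(0, n - 1, by = 2); odds <- seq(1, n - 1, by = 2)
  groups <- c(halves(evens), halves(odds))
  lapply(groups, function(fr) {
    sub <- video_sequence(unclass(video)[, , fr + 1, drop = FALSE], pixel_spacing(video))
    attr(sub, "source_frames") <- fr
    sub
  })
}

#' Assemble network training items from a phantom sequence
#'
#' Segmentation items are sliding windows (stride 1) of three consecutive
#' frames paired with their three mask frames (`n - 2` items); flow items are
#' consecutive frame pairs paired with the dense ground-truth displacement
#' (`n - 1` items).
#'
#' @param sequence a `phantom_sequence` from [make_phantom()], or any list
#'   with elements `video`, `masks` and `flows`.
#' @return list with elements `segmentation` (each item: `volume` `H x W x 3`,
#'   `labels` `H x W x 3`) and `flow` (each item: `frame1`, `frame2`,
#'   `flow` `H x W x 2`).
#' @export
make_training_items <- function(sequence) {
  video <- sequence$video; masks <- sequence$masks; flows <- sequence$flows
  n <- n_frames(video)
  if (n < 3) stop_input("need at least 3 frames, got %d", n)
  seg <- lapply(seq_len(n - 2), function(t) list(
    volume = unclass(video)[, , t:(t + 2), drop = FALSE],
    labels = unclass(masks)[, , t:(t + 2), drop = FALSE]))
  flo <- lapply(seq_len(n - 1), function(t) list(
    frame1 = frame_of(video, t),
    frame2 = frame_of(video, t + 1),
    flow = if (!is.null(flows)) unclass(flows[[t]]) else NULL))
  list(segmentation = seg, flow = flo)
}

#' Generic training-item augmentation
#'
#' Applies a random subset of horizontal flip, gamma jitter and multiplicative
#' speckle noise (generic stand-ins for scanner-specific augmentation): flips
#' mirror images, labels and flow fields and negate the flow x-component.
#'
#' @param item a segmentation or flow item from [make_training_items()].
#' @param seed RNG seed.
#' @param p_flip,gamma_range,noise_sd augmentation parameters.
#' @return an item with the same structure.
#' @export
augment_item <- function(item, seed, p_flip = 0.5, gamma_range = c(0.7, 1.4),
                         noise_sd = 0.05) {
  with_seed(seed, {
    flip <- stats::runif(1) < p_flip
    gam <- stats::runif(1, gamma_range[1], gamma_range[2])
    flip_x <- function(m) m[, rev(seq_len(ncol(m))), drop = FALSE]
    jitter <- function(im) clamp(im^gam * (1 + stats::rnorm(length(im), 0, noise_sd)), 0, 1)
    if (!is.null(item$volume)) {
      for (t in seq_len(dim(item$volume)[3])) {
        fr <- item$volume[, , t]
        if (flip) { fr <- flip_x(fr); item$labels[, , t] <- flip_x(item$labels[, , t]) }
        item$volume[, , t] <- jitter(fr)
      }
    } else {
      if (flip) {
        item$frame1 <- flip_x(item$frame1); item$frame2 <- flip_x(item$frame2)
        if (!is.null(item$flow)) {
          item$flow <- array(c(-flip_x(item$flow[, , 1]), flip_x(item$flow[, , 2])),
                             dim(item$flow))
        }
      }
      item$frame1 <- jitter(item$frame1); item$frame2 <- jitter(item$frame2)
    }
    item
  })
}
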