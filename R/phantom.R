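#' Synthetic deforming-ventricle phantom
#'
#' The phantom emulates the kind of simulated echocardiography data used to
#' train segmentation and motion networks: a horseshoe-shaped myocardial band
#' (an annulus with an angular opening at the base), ~180 material points
#' evenly distributed inside it, per-frame dense displacement ground truth,
#' speckle-textured images, and an analytically known global longitudinal
#' strain curve.
#'
#' Geometry: the band is `r_endo <= |p - center| <= r_epi` excluding directions
#' within `opening_half_angle` of the basal direction (image bottom, +y). The
#' apical focal point sits on the mid-band circle opposite the opening.
#'
#' Motion: in `contraction` mode every material point scales uniformly about
#' the apical focal point by `s(t) = 1 - A * sin^2(pi * t / period_frames)`,
#' so every arc length scales by `s(t)` and the true strain has the closed
#' form `gls_true(t) = s(t) - 1`. `rigid_translation` shifts the band by
#' `translation` px/frame (zero strain); `zero` freezes it.
#'
#' @param center `(x, y)` band center in px (0-based pixel coordinates).
#' @param r_endo,r_epi endocardial/epicardial radii in px, `0 < r_endo < r_epi`.
#' @param opening_half_angle half-angle of the basal gap, radians, in
#'   `(0, pi/2)`.
#' @param image_size `(H, W)` in px.
#' @param pixel_spacing physical pixel size, mm/px.
#' @return `phantom_geometry()` and `phantom_motion()` return validated
#'   parameter lists; `make_phantom()` returns a `phantom_sequence`: a list
#'   with elements `video`, `masks`, `points` (per-frame `K x 2` matrices),
#'   `flows` (list of `n_frames - 1` ground-truth [flow_field()]s),
#'   `gls_true`, `geometry`, `motion`, `focal` and `scales`.
#' @examples
#' geo <- phantom_geometry(image_size = c(64, 64), center = c(32, 32),
#'                         r_endo = 14, r_epi = 24, pixel_spacing = 0.5)
#' mot <- phantom_motion(amplitude = 0.15, n_frames = 8)
#' ph <- make_phantom(geo, mot, speckle_seed = 7, n_points = 40)
#' ph$gls_true
#' @export
phantom_geometry <- function(center = c(128, 128), r_endo = 60, r_epi = 92,
                             opening_half_angle = pi / 4,
                             image_size = c(256, 256), pixel_spacing = 0.3) {
  if (!(r_endo > 0 && r_epi > r_endo)) stop_geometry("need 0 < r_endo < r_epi")
  if (!(opening_half_angle > 0 && opening_half_angle < pi / 2))
    stop_geometry("opening_half_angle must lie in (0, pi/2)")
  if (pixel_spacing <= 0) stop_input("pixel_spacing must be > 0")
  h <- image_size[1]; w <- image_size[2]
  if (center[1] - r_epi < 2 || center[1] + r_epi > w - 3 ||
      center[2] - r_epi < 2 || center[2] + r_epi > h - 3)
    stop_geometry("band does not fit inside the image with a 2 px margin")
  structure(list(center = as.numeric(center), r_endo = r_endo, r_epi = r_epi,
                 opening_half_angle = opening_half_angle,
                 image_size = as.integer(image_size),
                 pixel_spacing = pixel_spacing),
            class = "phantom_geometry")
}

#' @rdname phantom_geometry
#' @param amplitude peak contraction `A` (dimensionless), in `(0, 0.5)` so that
#'   `s(t) > 0.5` always holds.
#' @param n_frames number of frames (>= 2).
#' @param period_frames frames per cardiac cycle (defaults to `n_frames`).
#' @param mode one of `"contraction"`, `"rigid_translation"`, `"zero"`.
#' @param translation `(dx, dy)` px/frame, rigid mode only.
#' @export
phantom_motion <- function(amplitude = 0.15, n_frames = 16,
                           period_frames = n_frames,
                           mode = c("contraction", "rigid_translation", "zero"),
                           translation = c(0, 0)) {
  mode <- match.arg(mode)
  if (mode == "contraction" && !(amplitude > 0 && amplitude < 0.5))
    stop_input("contraction amplitude must lie in (0, 0.5)")
  if (period_frames < 2) stop_input("period_frames must be >= 2")
  structure(list(amplitude = amplitude, n_frames = as.integer(n_frames),
                 period_frames = period_frames, mode = mode,
                 translation = as.numeric(translation)),
            class = "phantom_motion")
}

#' @rdname phantom_geometry
#' @param motion a [phantom_motion()].
#' @param t 0-based frame index.
#' @export
contraction_scale <- function(motion, t) {
  if (motion$mode != "contraction") return(rep(1, length(t)))
  1 - motion$amplitude * sin(pi * t / motion$period_frames)^2
}

# Focal point of the scaling: on the mid-band circle, opposite the opening.
phantom_focal <- function(geometry) {
  r_mid <- (geometry$r_endo + geometry$r_epi) / 2
  c(geometry$center[1], geometry$center[2] - r_mid)
}

ang_dist <- function(theta, theta0) abs(atan2(sin(theta - theta0), cos(theta - theta0)))

# Membership test of 0-based points in the frame-0 band, with optional inward
# margin (px) applied to both the radial and the angular boundary.
band_contains <- function(geometry, px, py, margin = 0) {
  dx <- px - geometry$center[1]; dy <- py - geometry$center[2]
  r <- sqrt(dx^2 + dy^2)
  th <- atan2(dy, dx)
  gap <- ang_dist(th, pi / 2) # basal opening centered on +y (image bottom)
  r >= geometry$r_endo + margin & r <= geometry$r_epi - margin &
    gap >= geometry$opening_half_angle + ifelse(r > 0, margin / pmax(r, 1e-9), 0)
}

# Map pixel positions at frame t back to material (frame-0) coordinates.
material_coords <- function(geometry, motion, t, px, py, scales = NULL) {
  if (motion$mode == "contraction") {
    s <- if (is.null(scales)) contraction_scale(motion, t) else scales[t + 1]
    a <- phantom_focal(geometry)
    list(x = a[1] + (px - a[1]) / s, y = a[2] + (py - a[2]) / s)
  } else if (motion$mode == "rigid_translation") {
    list(x = px - t * motion$translation[1], y = py - t * motion$translation[2])
  } else {
    list(x = px, y = py)
  }
}

phantom_mask_frame <- function(geometry, motion, t) {
  h <- geometry$image_size[1]; w <- geometry$image_size[2]
  g <- pixel_grid(h, w)
  m <- material_coords(geometry, motion, t, g$x, g$y)
  matrix(as.integer(band_contains(geometry, m$x, m$y)), h, w)
}

#' Analytic ground-truth flow of the phantom
#'
#' Dense displacement of the material point at each pixel of frame `t` towards
#' its position in frame `t + 1`; zero outside the frame-`t` mask. In
#' contraction mode the field is `(s(t+1)/s(t) - 1) * (p - focal)`, an affine
#' field whose fixed point is the apical focal point.
#'
#' @inheritParams phantom_geometry
#' @param motion a [phantom_motion()].
#' @param t 0-based frame index with `0 <= t < n_frames - 1`.
#' @param geometry a [phantom_geometry()].
#' @return a [flow_field()] in px/frame.
#' @export
analytic_flow <- function(geometry, motion, t) {
  if (t < 0 || t >= motion$n_frames - 1)
    stop_input("frame index t = %d out of range [0, %d)", t, motion$n_frames - 1)
  h <- geometry$image_size[1]; w <- geometry$image_size[2]
  g <- pixel_grid(h, w)
  msk <- phantom_mask_frame(geometry, motion, t) == 1L
  fx <- matrix(0, h, w); fy <- matrix(0, h, w)
  if (motion$mode == "contraction") {
    s0 <- contraction_scale(motion, t); s1 <- contraction_scale(motion, t + 1)
    a <- phantom_focal(geometry)
    k <- s1 / s0 - 1
    fx[msk] <- k * (g$x[msk] - a[1])
    fy[msk] <- k * (g$y[msk] - a[2])
  } else if (motion$mode == "rigid_translation") {
    fx[msk] <- motion$translation[1]
    fy[msk] <- motion$translation[2]
  }
  flow_field(array(c(fx, fy), c(h, w, 2)))
}

# Exact displacement of material points currently at `pts` (n x 2, frame t).
analytic_flow_at <- function(geometry, motion, t, pts) {
  if (motion$mode == "contraction") {
    s0 <- contraction_scale(motion, t); s1 <- contraction_scale(motion, t + 1)
    a <- phantom_focal(geometry)
    k <- s1 / s0 - 1
    cbind(k * (pts[, 1] - a[1]), k * (pts[, 2] - a[2]))
  } else if (motion$mode == "rigid_translation") {
    matrix(motion$translation, nrow(pts), 2, byrow = TRUE)
  } else {
    matrix(0, nrow(pts), 2)
  }
}

#' Evenly distributed points inside a myocardial mask
#'
#' Draws `k` approximately blue-noise points strictly inside a binary mask by
#' seeded Lloyd clustering (k-means) of the foreground pixel coordinates, with
#' each cluster center snapped to its nearest unused foreground pixel. The
#' result is deterministic for a fixed seed and has near-uniform coverage
#' (nearest-neighbour distance coefficient of variation well below 0.5).
#'
#' @param mask binary matrix (`H x W`).
#' @param k number of points (>= 3).
#' @param seed integer RNG seed; the caller's RNG stream is left untouched.
#' @return a `k x 2` matrix of 0-based `(x, y)` pixel coordinates.
#' @export
sample_myocardial_points <- function(mask, k, seed = 180L) {
  if (k < 3) stop_input("need k >= 3 points")
  idx <- which(mask == 1)
  if (length(idx) == 0) stop_input("mask is empty")
  if (length(idx) < k) stop_input("mask has %d pixels, fewer than k = %d", length(idx), k)
  h <- nrow(mask)
  coords <- cbind(x = ((idx - 1L) %/% h), y = ((idx - 1L) %% h)) # 0-based
  if (length(idx) == k) return(coords[order(coords[, 1], coords[, 2]), , drop = FALSE])
  km <- with_seed(seed, suppressWarnings(
    stats::kmeans(coords, centers = k, iter.max = 100, nstart = 1)))
  centers <- km$centers
  # snap each center to the nearest still-unused foreground pixel
  out <- matrix(0, k, 2)
  used <- rep(FALSE, nrow(coords))
  for (i in seq_len(k)) {
    d2 <- (coords[, 1] - centers[i, 1])^2 + (coords[, 2] - centers[i, 2])^2
    d2[used] <- Inf
    j <- which.min(d2)
    out[i, ] <- coords[j, ]
    used[j] <- TRUE
  }
  colnames(out) <- c("x", "y")
  out[order(out[, 1], out[, 2]), , drop = FALSE]
}

#' @rdname phantom_geometry
#' @param speckle_seed seed for the multiplicative speckle texture; changing it
#'   alters pixel intensities only, never masks, points or flows.
#' @param n_points number of tracked material points `K` (default 180).
#' @param point_seed seed for point placement, deliberately independent of
#'   `speckle_seed`.
#' @param point_margin clearance (px) kept between sampled material points
#'   and the band boundary so advected points stay strictly inside every
#'   rasterized mask; defaults to 3 px, shrunk for narrow bands.
#' @export
make_phantom <- function(geometry, motion, speckle_seed = 1L,
                         n_points = 180L, point_seed = 180L,
                         point_margin = min(3, max(1, (geometry$r_epi - geometry$r_endo) / 4))) {
  stopifnot(inherits(geometry, "phantom_geometry"), inherits(motion, "phantom_motion"))
  n <- motion$n_frames
  if (n < 2) stop_input("n_frames must be >= 2")
  h <- geometry$image_size[1]; w <- geometry$image_size[2]
  ts <- 0:(n - 1)
  scales <- contraction_scale(motion, ts)
  a <- phantom_focal(geometry)

  masks <- array(0L, c(h, w, n))
  for (t in ts) masks[, , t + 1] <- phantom_mask_frame(geometry, motion, t)

  # material points at frame 0, kept clear of the band boundary so that
  # advected points stay strictly inside every rasterized mask
  g <- pixel_grid(h, w)
  margin_mask <- matrix(as.integer(band_contains(geometry, g$x, g$y, margin = point_margin)), h, w)
  p0 <- sample_myocardial_points(margin_mask, n_points, seed = point_seed)
  points <- vector("list", n)
  for (t in ts) {
    points[[t + 1]] <- if (motion$mode == "contraction") {
      s <- scales[t + 1]
      cbind(x = a[1] + s * (p0[, 1] - a[1]), y = a[2] + s * (p0[, 2] - a[2]))
    } else if (motion$mode == "rigid_translation") {
      cbind(x = p0[, 1] + t * motion$translation[1],
            y = p0[, 2] + t * motion$translation[2])
    } else {
      cbind(x = p0[, 1], y = p0[, 2])
    }
  }

  flows <- lapply(0:(n - 2), function(t) analytic_flow(geometry, motion, t))

  gls_true <- if (motion$mode == "contraction") scales - 1 else rep(0, n)

  # speckle texture lives in material coordinates and advects with the tissue
  video <- array(0, c(h, w, n))
  tex <- with_seed(speckle_seed, {
    tx <- smooth_gaussian(matrix(stats::rexp(h * w), h, w), sigma = 1)
    bg <- smooth_gaussian(matrix(stats::rexp(h * w), h, w), sigma = 1)
    list(band = tx / mean(tx), bg = bg / mean(bg))
  })
  for (t in ts) {
    m <- material_coords(geometry, motion, t, g$x, g$y, scales = scales)
    samp <- matrix(bilinear_sample(tex$band, as.vector(m$x), as.vector(m$y), fill = 1), h, w)
    img <- 0.10 * tex$bg
    inside <- masks[, , t + 1] == 1L
    img[inside] <- 0.85 * samp[inside]
    video[, , t + 1] <- clamp(img, 0, 1)
  }

  structure(list(video = video_sequence(video, geometry$pixel_spacing),
                 masks = mask_sequence(masks, geometry$pixel_spacing),
                 points = points, flows = flows, gls_true = gls_true,
                 geometry = geometry, motion = motion,
                 focal = a, scales = scales),
            class = "phantom_sequence")
}

#' @export
print.phantom_sequence <- function(x, ...) {
  cat(sprintf("<phantom_sequence> %d frames, mode '%s', K = %d points, peak true GLS %.3f\n",
              x$motion$n_frames, x$motion$mode, nrow(x$points[[1]]), min(x$gls_true)))
  invisible(x)
}
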