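# Centerline extraction, flow-based tracking and arc-length strain.
# The myocardial centerline (the mid-curve between endocardium and epicardium
# at end-diastole) is tracked through the per-frame displacement fields; its
# arc length tau(t) is the longitudinal length of the myocardium and the
# strain curve is sigma(t) = (tau(t) - tau(0)) / tau(0).

#' Myocardial centerline
#'
#' An ordered sub-pixel polyline from one basal end of the myocardium to the
#' other, with the index of the apical demarcation node.
#'
#' @param points `n x 2` matrix of ordered `(x, y)` coordinates (0-based px),
#'   `n >= 7`, consecutive points distinct.
#' @param apex_index 1-based index of the apex node, strictly interior.
#' @param pixel_spacing mm/px.
#' @return a `centerline` object.
#' @export
centerline <- function(points, apex_index = NULL, pixel_spacing = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 7) stop_geometry("a centerline needs at least 7 points")
  seg <- sqrt(rowSums(diff(points)^2))
  if (any(seg == 0)) stop_geometry("consecutive centerline points must be distinct")
  if (is.null(apex_index)) # degenerate (straight) lines admit any interior apex
    apex_index <- min(max(find_apex(points), 2L), nrow(points) - 1L)
  if (apex_index <= 1 || apex_index >= nrow(points))
    stop_geometry("apex_index must be strictly interior")
  structure(list(points = points, apex_index = as.integer(apex_index),
                 pixel_spacing = pixel_spacing),
            class = "centerline")
}

#' Locate the apical demarcation node of an ordered point list
#'
#' The apex is the point at maximal perpendicular distance from the chord
#' joining the two endpoints; ties are broken towards the smallest index.
#'
#' @param points `n x 2` ordered coordinate matrix, `n >= 3`.
#' @return 1-based index of the apex point.
#' @export
find_apex <- function(points) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3) stop_input("need at least 3 points")
  chord <- points[n, ] - points[1, ]
  len <- sqrt(sum(chord^2))
  if (len < 1e-9) stop_geometry("degenerate chord: coincident endpoints")
  d <- abs((points[, 1] - points[1, 1]) * chord[2] -
             (points[, 2] - points[1, 2]) * chord[1]) / len
  which.max(d)
}

# One Zhang-Suen thinning pass (vectorized); sub = 1 or 2.
zs_pass <- function(m, sub) {
  h <- nrow(m); w <- ncol(m)
  p <- matrix(0L, h + 2, w + 2); p[2:(h + 1), 2:(w + 1)] <- m
  nb <- function(dy, dx) p[(2:(h + 1)) + dy, (2:(w + 1)) + dx]
  p2 <- nb(-1, 0); p3 <- nb(-1, 1); p4 <- nb(0, 1); p5 <- nb(1, 1)
  p6 <- nb(1, 0); p7 <- nb(1, -1); p8 <- nb(0, -1); p9 <- nb(-1, -1)
  b <- p2 + p3 + p4 + p5 + p6 + p7 + p8 + p9
  a <- (p2 == 0 & p3 == 1) + (p3 == 0 & p4 == 1) + (p4 == 0 & p5 == 1) +
    (p5 == 0 & p6 == 1) + (p6 == 0 & p7 == 1) + (p7 == 0 & p8 == 1) +
    (p8 == 0 & p9 == 1) + (p9 == 0 & p2 == 1)
  cond <- m == 1L & b >= 2 & b <= 6 & a == 1
  if (sub == 1) cond <- cond & (p2 * p4 * p6 == 0) & (p4 * p6 * p8 == 0)
  else cond <- cond & (p2 * p4 * p8 == 0) & (p2 * p6 * p8 == 0)
  m[cond] <- 0L
  m
}

skeletonize <- function(mask) {
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  repeat {
    m1 <- zs_pass(m, 1)
    m2 <- zs_pass(m1, 2)
    if (identical(m2, m)) break
    m <- m2
  }
  m
}

# Longest geodesic path through a skeleton (8-connected, Euclidean weights).
skeleton_longest_path <- function(skel) {
  idx <- which(skel == 1L)
  if (length(idx) < 2) return(NULL)
  h <- nrow(skel)
  px <- (idx - 1L) %/% h; py <- (idx - 1L) %% h
  id <- seq_along(idx)
  lut <- new.env()
  key <- function(x, y) paste(x, y)
  for (i in id) assign(key(px[i], py[i]), i, envir = lut)
  edges <- NULL; wts <- NULL
  for (o in list(c(1, 0), c(0, 1), c(1, 1), c(1, -1))) {
    nk <- key(px + o[1], py + o[2])
    hit <- vapply(nk, function(k) if (exists(k, envir = lut)) get(k, envir = lut) else NA_integer_, 1L)
    ok <- !is.na(hit)
    if (any(ok)) {
      edges <- rbind(edges, cbind(id[ok], hit[ok]))
      wts <- c(wts, rep(sqrt(sum(o^2)), sum(ok)))
    }
  }
  if (is.null(edges)) return(NULL)
  g <- igraph::make_empty_graph(n = length(id), directed = FALSE)
  g <- igraph::add_edges(g, as.vector(t(edges)), weight = wts)
  far <- function(v) {
    d <- igraph::distances(g, v = v)[1, ]
    d[!is.finite(d)] <- -1
    which.max(d)
  }
  a <- far(1); b <- far(a)
  path <- igraph::shortest_paths(g, from = a, to = b, output = "vpath")$vpath[[1]]
  cbind(x = px[as.integer(path)], y = py[as.integer(path)])
}

#' Extract the myocardial centerline from a binary mask
#'
#' Morphological (Zhang-Suen) skeletonization pruned to its single longest
#' geodesic path, trimmed of corner spurs (path ends whose clearance from the
#' mask boundary is well below the band half-width), lightly smoothed, and
#' extended along the end tangents to the mask boundary. The apex is located
#' with [find_apex()]. Disconnected masks are reduced to their largest
#' component with a warning.
#'
#' @param mask binary `H x W` matrix, one band-like connected component.
#' @param pixel_spacing mm/px.
#' @return a [centerline()].
#' @export
extract_centerline <- function(mask, pixel_spacing = 1) {
  mask <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  lab <- label_components(mask)
  if (max(lab) > 1) {
    warning("mask has multiple components; using the largest")
    mask <- matrix(as.integer(lab == 1L), nrow(mask), ncol(mask))
  }
  if (sum(mask) < 7) stop_geometry("mask too small for centerline extraction")
  skel <- skeletonize(mask)
  path <- skeleton_longest_path(skel)
  if (is.null(path) || nrow(path) < 7)
    stop_geometry("skeleton contains no path of at least 7 points")

  # clearance from the mask boundary; spur points at the band's cut ends have
  # clearance well below the typical half-width and are trimmed
  dt <- distance_transform(mask == 0L)
  clr <- dt[cbind(path[, 2] + 1, path[, 1] + 1)]
  # corner branches of the medial axis (clearance below the band half-width)
  # are trimmed, capped at 3 half-widths of arc per end so ragged masks are
  # not eaten away
  half_width <- stats::median(clr)
  thr <- 0.9 * half_width
  cap <- 3 * half_width
  s_all <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  first <- 1; last <- nrow(path)
  while (first < last && clr[first] < thr && s_all[first] < cap) first <- first + 1
  while (last > first && clr[last] < thr && s_all[length(s_all)] - s_all[last] < cap) last <- last - 1
  path <- path[first:last, , drop = FALSE]
  # the medial axis also runs parallel to a flat cut face for about one band
  # half-width before joining the mid-line; trim that run off both ends (it is
  # re-grown along the mid-line ridge below)
  s <- c(0, cumsum(sqrt(rowSums(diff(path)^2))))
  keep <- s >= 1.3 * half_width & s <= s[length(s)] - 1.3 * half_width
  if (sum(keep) >= 7) path <- path[keep, , drop = FALSE]
  if (nrow(path) < 7) stop_geometry("skeleton path degenerates after spur trimming")

  smooth_line <- function(v) {
    for (pass in 1:2) {
      n <- length(v)
      idx <- function(i) pmin(pmax(i, 1L), n)
      v <- (v[idx(seq_len(n) - 2)] + 2 * v[idx(seq_len(n) - 1)] + 3 * v +
              2 * v[idx(seq_len(n) + 1)] + v[idx(seq_len(n) + 2)]) / 9
    }
    v
  }
  pts <- cbind(smooth_line(path[, 1]), smooth_line(path[, 2]))

  # Regrow the trimmed ends by extrapolating the path's own smooth geometry:
  # an algebraic (Kasa) circle fit of the points nearest the end, stepped
  # outwards along the fitted arc (straight-line fallback for straight
  # bands), until the clearance from the mask boundary drops below 2 px.
  # The 2 px stop keeps every bilinear flow tap of a tracked end point
  # inside the (possibly contracting) mask during tracking.
  clearance_at <- function(x, y) bilinear_sample(dt, x, y)
  extend_end <- function(pts, head_end) {
    n <- nrow(pts)
    # the fit window scales with the band width: a wider band means a larger
    # vessel radius, and a short chord on a large circle under-constrains the
    # fit (tiny sagitta)
    m <- min(as.integer(max(25, round(3 * half_width))), n)
    sel <- if (head_end) seq_len(m) else (n - m + 1):n
    loc <- pts[sel, , drop = FALSE]
    p_end <- if (head_end) pts[1, ] else pts[n, ]
    p_in <- if (head_end) pts[4, ] else pts[n - 3, ]
    fit <- tryCatch({
      A <- cbind(2 * loc[, 1], 2 * loc[, 2], 1)
      sol <- stats::lm.fit(A, loc[, 1]^2 + loc[, 2]^2)$coefficients
      list(c = sol[1:2], R = sqrt(sol[3] + sol[1]^2 + sol[2]^2))
    }, error = function(e) NULL)
    circular <- !is.null(fit) && is.finite(fit$R) && fit$R < 100 * half_width
    if (circular) {
      th_end <- atan2(p_end[2] - fit$c[2], p_end[1] - fit$c[1])
      th_in <- atan2(p_in[2] - fit$c[2], p_in[1] - fit$c[1])
      dir <- sign(atan2(sin(th_end - th_in), cos(th_end - th_in)))
      if (dir == 0) dir <- 1
      at_step <- function(k) {
        th <- th_end + dir * k / fit$R
        fit$c + fit$R * c(cos(th), sin(th))
      }
    } else {
      tang <- p_end - p_in
      tang <- tang / max(sqrt(sum(tang^2)), 1e-9)
      at_step <- function(k) p_end + k * tang
    }
    added <- NULL
    for (step in seq_len(ceiling(3 * half_width))) {
      cand <- at_step(step)
      if (clearance_at(cand[1], cand[2]) < 2) break
      added <- rbind(added, cand)
    }
    if (is.null(added)) return(pts)
    if (head_end) rbind(added[rev(seq_len(nrow(added))), , drop = FALSE], pts)
    else rbind(pts, added)
  }
  pts <- extend_end(pts, head_end = TRUE)
  pts <- extend_end(pts, head_end = FALSE)
  keep <- c(TRUE, sqrt(rowSums(diff(pts)^2)) > 1e-9)
  pts <- pts[keep, , drop = FALSE]
  dimnames(pts) <- list(NULL, c("x", "y"))
  centerline(pts, pixel_spacing = pixel_spacing)
}

#' Track a centerline through a sequence of displacement fields
#'
#' The update rule is the material one: position(t+1) = position(t) + f_t
#' sampled bilinearly at the current sub-pixel position. Points that would
#' leave the image are clamped to its bounds and counted in the `n_clamped`
#' attribute.
#'
#' @param cl a [centerline()] at frame 0 (end-diastole).
#' @param flows list of [flow_field()]s covering frames `0..T-1`.
#' @return a `centerline_trajectory`: list with `positions`
#'   (`n_points x 2 x T` array), `apex_index`, `pixel_spacing`.
#' @export
track_centerline <- function(cl, flows) {
  stopifnot(inherits(cl, "centerline"))
  if (!length(flows)) stop_input("empty flow list")
  n <- nrow(cl$points)
  tt <- length(flows) + 1L
  pos <- array(0, c(n, 2, tt))
  pos[, , 1] <- cl$points
  h <- dim(flows[[1]])[1]; w <- dim(flows[[1]])[2]
  clamped <- 0L
  cur <- cl$points
  for (t in seq_along(flows)) {
    cur <- cur + sample_flow(flows[[t]], cur)
    out_of_bounds <- cur[, 1] < 0 | cur[, 1] > w - 1 | cur[, 2] < 0 | cur[, 2] > h - 1
    if (any(out_of_bounds)) {
      clamped <- clamped + sum(out_of_bounds)
      cur[, 1] <- clamp(cur[, 1], 0, w - 1)
      cur[, 2] <- clamp(cur[, 2], 0, h - 1)
    }
    pos[, , t + 1] <- cur
  }
  if (clamped > 0)
    warning(sprintf("%d tracked point positions left the image and were clamped", clamped))
  structure(list(positions = pos, apex_index = cl$apex_index,
                 pixel_spacing = cl$pixel_spacing, n_clamped = clamped),
            class = "centerline_trajectory")
}

#' Arc length of an ordered polyline
#'
#' Sum of Euclidean segment lengths scaled by the pixel spacing; a single
#' point has length 0.
#'
#' @param points `n x 2` coordinate matrix.
#' @param pixel_spacing mm/px.
#' @return length in mm.
#' @export
arc_length <- function(points, pixel_spacing = 1) {
  points <- as.matrix(points)
  if (nrow(points) < 2) return(0)
  sum(sqrt(rowSums(diff(points)^2))) * pixel_spacing
}

#' Global longitudinal strain from a tracked centerline
#'
#' tau(t) is the tracked arc length in mm; the strain curve is
#' `sigma(t) = (tau(t) - tau(0)) / tau(0)` (a signed fraction, 0 at
#' end-diastole) and the peak GLS is its minimum over the cycle.
#'
#' @param trajectory a `centerline_trajectory` from [track_centerline()].
#' @param view optional apical view label (`"A2C"`, `"A3C"`, `"A4C"`).
#' @return a `strain_result` with elements `tau`, `gls`, `peak_gls` (and
#'   `rls`, `peak_rls`, `boundaries`, `labels` once [regional_strain()] has
#'   been merged in by [compute_strain()]).
#' @export
strain_curve <- function(trajectory, view = NULL) {
  stopifnot(inherits(trajectory, "centerline_trajectory"))
  tt <- dim(trajectory$positions)[3]
  if (tt < 2) stop_input("trajectory must span at least 2 frames")
  tau <- vapply(seq_len(tt), function(t)
    arc_length(trajectory$positions[, , t], trajectory$pixel_spacing), numeric(1))
  if (tau[1] <= 0) stop_input("degenerate trajectory: tau(0) = 0")
  gls <- (tau - tau[1]) / tau[1]
  structure(list(tau = tau, gls = gls, peak_gls = min(gls),
                 rls = NULL, peak_rls = NULL, view = view,
                 pixel_spacing = trajectory$pixel_spacing),
            class = "strain_result")
}

#' Divide a centerline into the six per-view myocardial segments
#'
#' With the apex of the end-diastolic centerline as the demarcation node, each
#' side is divided into three arcs of equal length (basal, mid, apical on each
#' wall), giving the per-view segments of the 16-segment model. Boundaries are
#' arc-length parameters in px along the polyline.
#'
#' @param cl a [centerline()].
#' @param view apical view (`"A4C"`, `"A2C"`, `"A3C"`) used for segment names.
#' @return a `segment_partition`: list with `boundaries` (7 arc-length cuts),
#'   `labels` (6 names, wall 1 base->apex then wall 2 apex->base), `total`.
#' @export
divide_segments <- function(cl, view = "A4C") {
  stopifnot(inherits(cl, "centerline"))
  s <- c(0, cumsum(sqrt(rowSums(diff(cl$points)^2))))
  sa <- s[cl$apex_index]; total <- s[length(s)]
  if (sa <= 0 || total - sa <= 0) stop_geometry("a side of the apex has zero arc length")
  boundaries <- c(0, sa / 3, 2 * sa / 3, sa,
                  sa + (total - sa) / 3, sa + 2 * (total - sa) / 3, total)
  structure(list(boundaries = boundaries, labels = segment_labels(view),
                 total = total, view = view),
            class = "segment_partition")
}

#' Per-view segment names of the 16-segment model
#'
#' Names run from the basal end of the first imaged wall to the apex, then
#' down the second wall to its base, following the standard apical-view
#' anatomy of the 16-segment left-ventricular model.
#'
#' @param view `"A4C"`, `"A2C"` or `"A3C"`.
#' @return character vector of 6 segment names.
#' @export
segment_labels <- function(view = c("A4C", "A2C", "A3C")) {
  view <- match.arg(view)
  switch(view,
    A4C = c("basal inferoseptal", "mid inferoseptal", "apical septal",
            "apical lateral", "mid anterolateral", "basal anterolateral"),
    A2C = c("basal inferior", "mid inferior", "apical inferior",
            "apical anterior", "mid anterior", "basal anterior"),
    A3C = c("basal inferolateral", "mid inferolateral", "apical lateral",
            "apical anterior", "mid anteroseptal", "basal anteroseptal"))
}

# Edge-to-segment weight matrix (n_edges x 6): the fraction of each ED edge's
# arc-length parameter interval falling inside each segment. Material segment
# membership is fixed at ED; fractional edges split at their ED fraction, so
# segment lengths sum exactly to the total at every frame.
segment_edge_weights <- function(ed_points, partition) {
  s <- c(0, cumsum(sqrt(rowSums(diff(ed_points)^2))))
  b <- partition$boundaries
  ne <- nrow(ed_points) - 1
  wts <- matrix(0, ne, 6)
  for (j in 1:6) {
    lo <- pmax(s[seq_len(ne)], b[j]); hi <- pmin(s[seq_len(ne) + 1], b[j + 1])
    len <- s[seq_len(ne) + 1] - s[seq_len(ne)]
    wts[, j] <- pmax(0, hi - lo) / len
  }
  wts
}

#' Regional longitudinal strain for the six per-view segments
#'
#' Applies the strain formula to each segment's tracked arc length. Segment
#' membership is material: fixed by the end-diastolic partition and carried
#' with the tracked points, so the six segment lengths sum exactly to the
#' total centerline length at every frame.
#'
#' @param trajectory a `centerline_trajectory`.
#' @param partition a `segment_partition` from [divide_segments()] on the
#'   end-diastolic centerline.
#' @return list with `rls` (`T x 6` matrix of strain curves), `peak_rls`
#'   (6 minima), `tau_seg` (`T x 6` arc lengths, mm).
#' @export
regional_strain <- function(trajectory, partition) {
  stopifnot(inherits(trajectory, "centerline_trajectory"),
            inherits(partition, "segment_partition"))
  ed <- trajectory$positions[, , 1]
  wts <- segment_edge_weights(ed, partition)
  if (any(colSums(wts) == 0)) stop_geometry("a segment contains no centerline points")
  tt <- dim(trajectory$positions)[3]
  tau_seg <- matrix(0, tt, 6)
  for (t in seq_len(tt)) {
    el <- sqrt(rowSums(diff(trajectory$positions[, , t])^2)) * trajectory$pixel_spacing
    tau_seg[t, ] <- drop(crossprod(wts, el))
  }
  rls <- sweep(sweep(tau_seg, 2, tau_seg[1, ], "-"), 2, tau_seg[1, ], "/")
  colnames(rls) <- colnames(tau_seg) <- partition$labels
  list(rls = rls, peak_rls = apply(rls, 2, min), tau_seg = tau_seg)
}

#' Full strain result for one view
#'
#' Convenience wrapper running [strain_curve()] and [regional_strain()] and
#' merging the results.
#'
#' @inheritParams regional_strain
#' @param view apical view label.
#' @return a complete `strain_result`.
#' @export
compute_strain <- function(trajectory, partition, view = partition$view) {
  res <- strain_curve(trajectory, view = view)
  reg <- regional_strain(trajectory, partition)
  res$rls <- reg$rls
  res$peak_rls <- reg$peak_rls
  res$tau_seg <- reg$tau_seg
  res$boundaries <- partition$boundaries
  res$labels <- partition$labels
  res
}

#' Study-level GLS from per-view peaks
#'
#' GLS for a study is the arithmetic mean of the available apical-view peak
#' strains (up to A2C, A3C, A4C); fewer than three contributing views are
#' reported via the `n_views` attribute and a message.
#'
#' @param view_peaks numeric vector of 1-3 per-view peak strains (fractions).
#' @return mean peak strain with attribute `n_views`.
#' @export
average_gls <- function(view_peaks) {
  v <- view_peaks[is.finite(view_peaks)]
  if (!length(v)) stop_input("no finite view peaks supplied")
  if (length(v) > 3) stop_input("at most 3 apical views contribute to GLS")
  if (length(v) < 3)
    message(sprintf("average_gls: only %d of 3 apical views available", length(v)))
  structure(mean(v), n_views = length(v))
}

#' @export
print.strain_result <- function(x, ...) {
  cat(sprintf("<strain_result>%s %d frames, peak GLS %.2f%%\n",
              if (is.null(x$view)) "" else paste0(" ", x$view),
              length(x$gls), 100 * x$peak_gls))
  if (!is.null(x$peak_rls)) {
    cat("peak RLS (%):\n")
    print(round(100 * x$peak_rls, 2))
  }
  invisible(x)
}

#' @export
print.centerline <- function(x, ...) {
  cat(sprintf("<centerline> %d points, apex at %d, arc length %.1f mm\n",
              nrow(x$points), x$apex_index,
              arc_length(x$points, x$pixel_spacing)))
  invisible(x)
}
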