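# End-to-end workflow: segment the video (or accept given masks), extract the
# end-diastolic centerline, estimate masked flow fields, track, and compute
# global plus regional strain, writing all artifacts to disk.

#' Pipeline configuration
#'
#' Inputs may be in-memory objects or file paths. The estimator is either a
#' trained `raft_model`, the string `"oracle"` (requires `flows` or a
#' `phantom`), or any plug-in function `(frame_t, frame_t1) -> flow`.
#'
#' @param video a [video_sequence()] or path to a TIFF/PNG-directory video.
#' @param masks optional [mask_sequence()] or TIFF path; if absent,
#'   `model_seg` must be given.
#' @param model_seg optional `csn_model` (or checkpoint path) used when
#'   `masks` is absent.
#' @param estimator `"oracle"`, a `raft_model`, a checkpoint path, or a
#'   function of two frames returning an `H x W x 2` displacement.
#' @param flows optional list of [flow_field()]s used by the oracle
#'   estimator.
#' @param pixel_spacing mm/px.
#' @param view apical view label (`"A2C"`, `"A3C"`, `"A4C"`).
#' @param flow_iterations recurrent iterations for a model estimator.
#' @param seed RNG seed for any stochastic stage.
#' @param out_dir optional output directory for artifacts.
#' @return a `pipeline_config`.
#' @export
pipeline_config <- function(video, masks = NULL, model_seg = NULL,
                            estimator = "oracle", flows = NULL,
                            pixel_spacing = 0.3, view = c("A4C", "A2C", "A3C"),
                            flow_iterations = 12L, seed = 1L, out_dir = NULL) {
  view <- match.arg(view)
  if (pixel_spacing <= 0) stop_input("pixel_spacing must be > 0")
  structure(list(video = video, masks = masks, model_seg = model_seg,
                 estimator = estimator, flows = flows,
                 pixel_spacing = pixel_spacing, view = view,
                 flow_iterations = as.integer(flow_iterations),
                 seed = as.integer(seed), out_dir = out_dir),
            class = "pipeline_config")
}

dilate_mask <- function(mask, r = 2) {
  if (!any(mask == 1)) return(mask)
  matrix(as.integer(distance_transform(mask == 1) <= r), nrow(mask), ncol(mask))
}

stage <- function(name, expr) {
  t0 <- Sys.time()
  out <- tryCatch(expr, error = function(e) {
    stop(errorCondition(sprintf("pipeline stage '%s' failed: %s", name,
                                conditionMessage(e)),
                        class = c("echostrain_stage_error", "echostrain_error")))
  })
  message(sprintf("[echostrain] %-12s %6.2f s", name,
                  as.numeric(difftime(Sys.time(), t0, units = "secs"))))
  out
}

#' Run the full strain analysis pipeline
#'
#' Stages (each timed and logged to stderr): segmentation (or given masks) ->
#' end-diastolic centerline extraction -> flow estimation restricted to the
#' myocardial region (flow outside the 2 px-dilated mask is zeroed, keeping
#' the fixed input size while honouring the region of interest) -> centerline
#' tracking -> global and regional strain. Identical configurations and seeds
#' give identical outputs; tracked points leaving the mask are reported as a
#' tracking-quality warning.
#'
#' @param config a [pipeline_config()].
#' @return a `strain_result` with attribute `artifacts` (paths written, if
#'   `out_dir` was set).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  set.seed(config$seed)
  video <- config$video
  if (is.character(video)) video <- read_video(video, config$pixel_spacing)
  n <- n_frames(video)
  if (n < 3) stop_input("pipeline needs at least 3 frames, got %d", n)

  masks <- stage("segment", {
    if (!is.null(config$masks)) {
      m <- config$masks
      if (is.character(m)) m <- read_masks(m, config$pixel_spacing)
      m
    } else {
      model <- config$model_seg
      if (is.null(model)) stop_input("neither masks nor a segmentation model supplied")
      if (is.character(model)) model <- load_checkpoint(model)
      segment_video(model, video)
    }
  })

  cl <- stage("centerline", extract_centerline(masks[, , 1], config$pixel_spacing))

  flows <- stage("flow", {
    est <- config$estimator
    fl <- if (identical(est, "oracle")) {
      if (is.null(config$flows)) stop_input("oracle estimator requires precomputed flows")
      config$flows
    } else {
      if (is.character(est)) est <- load_checkpoint(est)
      fn <- if (is.function(est)) est else as_estimator(est, config$flow_iterations)
      lapply(seq_len(n - 1), function(t)
        flow_field(unclass(fn(frame_of(video, t), frame_of(video, t + 1)))))
    }
    # restrict motion to the region of interest
    lapply(seq_len(n - 1), function(t) {
      dil <- dilate_mask(masks[, , t], 2)
      f <- unclass(fl[[t]])
      flow_field(array(c(f[, , 1] * dil, f[, , 2] * dil), dim(f)))
    })
  })

  traj <- stage("track", track_centerline(cl, flows))
  result <- stage("strain", {
    part <- divide_segments(cl, config$view)
    compute_strain(traj, part, view = config$view)
  })

  if (!is.null(config$out_dir)) {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    paths <- c(
      masks = file.path(config$out_dir, "masks.tif"),
      strain_csv = file.path(config$out_dir, "strain.csv"),
      strain_json = file.path(config$out_dir, "strain.json"),
      centerline = file.path(config$out_dir, "centerline.csv"))
    write_masks(masks, paths["masks"])
    for (t in seq_along(flows))
      write_flo(flows[[t]], file.path(config$out_dir, sprintf("flow_%04d.flo", t - 1)))
    write_strain_csv(result, paths["strain_csv"])
    write_strain_json(result, paths["strain_json"])
    utils::write.csv(trajectory_tibble(traj), paths["centerline"], row.names = FALSE)
    attr(result, "artifacts") <- paths
  }
  result
}

trajectory_tibble <- function(traj) {
  tt <- dim(traj$positions)[3]
  nn <- dim(traj$positions)[1]
  tibble::tibble(frame = rep(seq_len(tt) - 1L, each = nn),
                 point = rep(seq_len(nn), times = tt),
                 x = as.vector(traj$positions[, 1, ]),
                 y = as.vector(traj$positions[, 2, ]))
}

#' Write a strain result to CSV / JSON
#'
#' The CSV holds one row per frame with the arc length in mm and strain in
#' percent (rounded to 2 decimals); the JSON summary keeps full precision.
#'
#' @param result a `strain_result`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_strain_csv <- function(result, path) {
  df <- data.frame(frame = seq_along(result$tau) - 1L,
                   tau_mm = result$tau,
                   gls_pct = round(100 * result$gls, 2))
  if (!is.null(result$rls)) {
    rls <- round(100 * result$rls, 2)
    colnames(rls) <- paste0("rls_", seq_len(ncol(rls)), "_pct")
    df <- cbind(df, rls)
  }
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_strain_csv
#' @export
write_strain_json <- function(result, path) {
  out <- list(view = result$view, n_frames = length(result$gls),
              pixel_spacing = result$pixel_spacing,
              peak_gls = result$peak_gls, gls = result$gls, tau_mm = result$tau)
  if (!is.null(result$peak_rls)) {
    out$peak_rls <- as.list(result$peak_rls)
    out$segment_labels <- result$labels
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Render segmentation and centerline overlays for visual quality control
#'
#' Burns the mask contour and the tracked centerline points into each frame
#' (intensity 1), leaving all other pixels untouched, so a reader can check
#' whether segmentation and motion estimates look reasonable frame by frame.
#'
#' @param video a [video_sequence()].
#' @param trajectory a `centerline_trajectory` with one position set per
#'   frame.
#' @param masks a [mask_sequence()] of the same length.
#' @return a [video_sequence()] of annotated frames.
#' @export
render_overlay <- function(video, trajectory, masks) {
  n <- n_frames(video)
  if (dim(trajectory$positions)[3] != n || n_frames(masks) != n)
    stop_input("video, trajectory and masks must cover the same frames")
  out <- unclass(video)
  attributes(out) <- list(dim = dim(video))
  h <- dim(out)[1]; w <- dim(out)[2]
  for (t in seq_len(n)) {
    m <- masks[, , t]
    if (!any(m == 1)) {
      warning(sprintf("frame %d has an empty mask; drawing centerline only", t))
    } else {
      inner <- m
      inner[2:(h - 1), 2:(w - 1)] <- m[2:(h - 1), 2:(w - 1)] &
        m[1:(h - 2), 2:(w - 1)] & m[3:h, 2:(w - 1)] &
        m[2:(h - 1), 1:(w - 2)] & m[2:(h - 1), 3:w]
      fr <- out[, , t]
      fr[m == 1 & inner == 0] <- 1
      out[, , t] <- fr
    }
    p <- round(trajectory$positions[, , t])
    ok <- p[, 1] >= 0 & p[, 1] <= (w - 1) & p[, 2] >= 0 & p[, 2] <= (h - 1)
    if (any(ok)) {
      fr <- out[, , t]
      fr[cbind(p[ok, 2] + 1, p[ok, 1] + 1)] <- 1
      out[, , t] <- fr
    }
  }
  video_sequence(out, pixel_spacing(video))
}

#' Map per-view segments onto the 16-segment model
#'
#' Collects the six per-view peak regional strains of up to three apical
#' views and averages segments that appear in more than one view (the
#' apical-ring labels), yielding the standard 16 named segments.
#'
#' @param view_results named list (names among `"A2C"`, `"A3C"`, `"A4C"`) of
#'   `strain_result`s carrying `peak_rls`.
#' @return [tibble::tibble()] with columns `segment`, `peak_rls`, `n_views`.
#' @export
bullseye_16 <- function(view_results) {
  if (!length(view_results)) stop_input("no view results supplied")
  rows <- list()
  for (v in names(view_results)) {
    r <- view_results[[v]]
    if (is.null(r$peak_rls)) stop_input("view %s has no regional strain", v)
    rows[[v]] <- tibble::tibble(segment = names(r$peak_rls) %||% r$labels,
                                peak_rls = as.numeric(r$peak_rls))
  }
  all_rows <- do.call(rbind, rows)
  agg <- stats::aggregate(peak_rls ~ segment, data = all_rows, FUN = mean)
  cnt <- stats::aggregate(peak_rls ~ segment, data = all_rows, FUN = length)
  tibble::tibble(segment = agg$segment, peak_rls = agg$peak_rls,
                 n_views = cnt$peak_rls)
}
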