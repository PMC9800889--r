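test_that("concave hull of a square's corners is the filled square", {
  pts <- rbind(c(5, 5), c(15, 5), c(5, 15), c(15, 15))
  m <- concave_hull_mask(pts, c(24, 24), alpha = 40)
  expect_equal(sum(m), 121) # inclusive rasterization of an 11 x 11 square

  # brute-force oracle: point-in-polygon over every pixel
  gx <- rep(0:23, each = 24); gy <- rep(0:23, times = 24)
  oracle <- echostrain:::point_in_polygon(gy, gx, c(5, 15, 15, 5), c(5, 5, 15, 15))
  expect_true(all((m == 1) == matrix(oracle, 24, 24)))
})

test_that("concave hull handles triangles, duplicates and degeneracy", {
  tri <- concave_hull_mask(rbind(c(2, 2), c(12, 2), c(7, 12)), c(16, 16))
  expect_gt(sum(tri), 40) # a filled triangle, not an outline
  expect_true(all(tri %in% c(0L, 1L)))

  pts <- rbind(c(5, 5), c(15, 5), c(5, 15), c(15, 15))
  m1 <- concave_hull_mask(pts, c(24, 24), alpha = 40)
  m2 <- concave_hull_mask(rbind(pts, pts, pts[2, , drop = FALSE]), c(24, 24), alpha = 40)
  expect_true(all(m1 == m2)) # idempotent under point duplication

  expect_error(concave_hull_mask(rbind(c(1, 1), c(2, 2), c(3, 3)), c(10, 10)),
               class = "echostrain_geometry_error")
  expect_error(concave_hull_mask(rbind(c(1, 1), c(1, 1)), c(10, 10)),
               class = "echostrain_geometry_error")
})

test_that("auto-alpha hull contains all phantom points and keeps the cavity open", {
  ph <- default_phantom()
  p0 <- ph$points[[1]]
  hm <- concave_hull_mask(p0, c(256, 256))
  expect_true(all(hm[cbind(round(p0[, 2]) + 1, round(p0[, 1]) + 1)] == 1))
  expect_equal(hm[129, 129], 0L) # ventricular cavity stays outside the horseshoe
  # a too-small explicit alpha falls back with a warning
  expect_warning(concave_hull_mask(p0, c(256, 256), alpha = 1), "disconnected")
})

test_that("sparse-to-dense interpolation is exact for constant and affine fields", {
  msk <- matrix(0L, 40, 40); msk[6:35, 6:35] <- 1L
  set.seed(2)
  an <- cbind(runif(25, 3, 37), runif(25, 3, 37))

  sp <- sparse_displacement(an, cbind(rep(1.5, 25), rep(-2, 25)))
  fl <- suppressMessages(sparse_to_dense_flow(sp, msk))
  expect_lt(max(abs(fl[, , 1][msk == 1] - 1.5)), 1e-6)
  expect_lt(max(abs(fl[, , 2][msk == 1] + 2)), 1e-6)
  expect_true(all(fl[, , 1][msk == 0] == 0))

  vv <- cbind(0.01 * an[, 1], -0.02 * an[, 2])
  fl2 <- suppressMessages(sparse_to_dense_flow(sparse_displacement(an, vv), msk))
  idx <- which(msk == 1)
  px <- (idx - 1) %/% 40; py <- (idx - 1) %% 40
  hull <- grDevices::chull(an[, 1], an[, 2])
  inh <- echostrain:::point_in_polygon(px, py, an[hull, 1], an[hull, 2])
  expect_lt(max(abs(fl2[, , 1][idx][inh] - 0.01 * px[inh])), 1e-6)
  expect_lt(max(abs(fl2[, , 2][idx][inh] + 0.02 * py[inh])), 1e-6)

  # anchor values reproduced exactly at the anchors
  fit <- echostrain:::tps_fit(an[, 1], an[, 2], vv[, 1])
  expect_lt(max(abs(echostrain:::tps_eval(fit, an[, 1], an[, 2]) - vv[, 1])), 1e-6)

  expect_error(sparse_displacement(an[1:2, ], vv[1:2, ]), class = "echostrain_input_error")
  expect_error(sparse_displacement(an, vv[1:10, ]), class = "echostrain_input_error")
})

test_that("phantom anchors with analytic vectors reconstruct the dense flow", {
  ph <- default_phantom()
  an <- ph$points[[1]]
  v <- ph$points[[2]] - an
  fl <- suppressMessages(sparse_to_dense_flow(sparse_displacement(an, v), ph$masks[, , 1]))
  res <- aepe(fl, ph$flows[[1]], ph$masks[, , 1])
  expect_lt(res$aepe_px, 0.05)
})

test_that("cine-loop clipping partitions the frames by stride and half", {
  v8 <- video_sequence(array(rep(0:7, each = 4) / 7, c(2, 2, 8)))
  loops <- clip_cine_loops(v8)
  expect_length(loops, 4)
  expect_equal(lapply(loops, attr, "source_frames"),
               list(c(0, 2), c(4, 6), c(1, 3), c(5, 7)))
  # conservation: the loops partition the original frames
  all_frames <- sort(unlist(lapply(loops, attr, "source_frames")))
  expect_equal(all_frames, 0:7)
  expect_equal(sum(vapply(loops, n_frames, 1L)), 8L)
  # temporal order preserved within each loop
  for (lp in loops) expect_true(all(diff(attr(lp, "source_frames")) > 0))

  v9 <- video_sequence(array(runif(4 * 9), c(2, 2, 9)))
  loops9 <- clip_cine_loops(v9)
  expect_equal(sort(unlist(lapply(loops9, attr, "source_frames"))), 0:8)

  expect_error(clip_cine_loops(video_sequence(array(0.5, c(2, 2, 7)))),
               class = "echostrain_input_error")
})

test_that("training items are sliding windows with the stated counts and shapes", {
  ph <- tiny_phantom(n_frames = 5)
  it <- make_training_items(ph)
  expect_length(it$segmentation, 3) # n - 2
  expect_length(it$flow, 4)         # n - 1
  expect_equal(dim(it$segmentation[[1]]$volume), c(32, 32, 3))
  expect_equal(dim(it$segmentation[[1]]$labels), c(32, 32, 3))
  expect_equal(dim(it$flow[[1]]$flow), c(32, 32, 2))
  # windows slide with stride 1
  expect_identical(it$segmentation[[2]]$volume[, , 1], unclass(ph$video)[, , 2])

  ph3 <- tiny_phantom(n_frames = 3)
  expect_length(make_training_items(ph3)$segmentation, 1)
  expect_error(make_training_items(list(video = video_sequence(array(0.1, c(8, 8, 2))),
                                        masks = NULL, flows = NULL)),
               class = "echostrain_input_error")
})

test_that("augmentation mirrors images, labels and flow consistently", {
  ph <- tiny_phantom(n_frames = 5)
  it <- make_training_items(ph)
  # find a seed that flips (p_flip = 1 forces it)
  seg_a <- augment_item(it$segmentation[[1]], seed = 3, p_flip = 1, noise_sd = 0)
  expect_identical(seg_a$labels[, , 1], it$segmentation[[1]]$labels[, 32:1, 1])
  flo_a <- augment_item(it$flow[[1]], seed = 3, p_flip = 1, noise_sd = 0)
  expect_equal(flo_a$flow[, , 1], -it$flow[[1]]$flow[, 32:1, 1])
  expect_equal(flo_a$flow[, , 2], it$flow[[1]]$flow[, 32:1, 2])
  # deterministic given the seed
  expect_identical(augment_item(it$flow[[1]], seed = 8),
                   augment_item(it$flow[[1]], seed = 8))
})
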