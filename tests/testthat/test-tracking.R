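test_that("find_apex locates the chord-distance extremum", {
  # symmetric U: apex at the midpoint
  th <- seq(0, pi, length.out = 21)
  u <- cbind(cos(th), sin(th))
  expect_equal(find_apex(u), 11)

  # straight line: all distances zero, smallest index wins
  line <- cbind(1:10, rep(2, 10))
  expect_equal(find_apex(line), 1)

  expect_error(find_apex(rbind(c(0, 0), c(1, 1))), class = "echostrain_input_error")
  expect_error(find_apex(rbind(c(0, 0), c(1, 1), c(0, 0))),
               class = "echostrain_geometry_error")
})

test_that("arc_length matches closed forms", {
  expect_equal(arc_length(rbind(c(0, 0), c(3, 4))), 5)
  expect_equal(arc_length(rbind(c(0, 0), c(3, 4)), pixel_spacing = 0.5), 2.5)
  expect_equal(arc_length(rbind(c(1, 1))), 0)
  th <- seq(0, pi, length.out = 200)
  semi <- cbind(10 * cos(th), 10 * sin(th))
  expect_lt(abs(arc_length(semi) - pi * 10) / (pi * 10), 0.001)
})

test_that("extract_centerline recovers the mid-line of a half-annulus band", {
  mask <- half_annulus_mask()
  cl <- extract_centerline(mask, pixel_spacing = 1)
  rr <- sqrt((cl$points[, 1] - 64)^2 + (cl$points[, 2] - 64)^2)
  expect_lt(max(abs(rr - 50)), 1.5)
  al <- arc_length(cl$points)
  expect_lt(abs(al - pi * 50) / (pi * 50), 0.05)
  # apex near the analytic extremum (64, 14)
  apex <- cl$points[cl$apex_index, ]
  expect_lt(abs(apex[1] - 64), 2.5)
  expect_lt(abs(apex[2] - 14), 2.5)
  # every centerline point lies inside the mask
  expect_true(all(mask[cbind(round(cl$points[, 2]) + 1, round(cl$points[, 1]) + 1)] == 1))
  # arc length scales with the pixel spacing
  cl2 <- extract_centerline(mask, pixel_spacing = 0.3)
  expect_equal(arc_length(cl2$points, cl2$pixel_spacing), 0.3 * al)
})

test_that("extract_centerline handles rectangles, fragments and degenerate masks", {
  m <- matrix(0L, 32, 64); m[14:19, 11:50] <- 1L
  cl <- extract_centerline(m)
  expect_lt(diff(range(cl$points[, 2])), 1.6) # ~horizontal at the vertical midline
  expect_gte(mean(cl$points[, 2]), 14.5); expect_lte(mean(cl$points[, 2]), 16.5)

  frag <- m; frag[25:28, 55:60] <- 1L # small second component
  expect_warning(cl2 <- extract_centerline(frag), "largest")
  expect_equal(nrow(cl2$points), nrow(cl$points))

  expect_error(extract_centerline(matrix(0L, 16, 16)), class = "echostrain_geometry_error")
  tiny <- matrix(0L, 16, 16); tiny[8, 8] <- 1L
  expect_error(extract_centerline(tiny), class = "echostrain_geometry_error")
})

test_that("track_centerline composes displacements by bilinear sampling", {
  mask <- half_annulus_mask()
  cl <- extract_centerline(mask)
  # zero flows: constant trajectory
  z <- flow_field(array(0, c(128, 128, 2)))
  tr0 <- track_centerline(cl, list(z, z))
  expect_identical(tr0$positions[, , 1], tr0$positions[, , 3])
  # constant (2, 0) flows, 3 steps: total shift (6, 0)
  cst <- flow_field(array(c(rep(2, 128 * 128), rep(0, 128 * 128)), c(128, 128, 2)))
  tr1 <- track_centerline(cl, list(cst, cst, cst))
  expect_equal(tr1$positions[, 1, 4], cl$points[, 1] + 6)
  expect_equal(tr1$positions[, 2, 4], cl$points[, 2])

  expect_error(track_centerline(cl, list()), class = "echostrain_input_error")
  # points pushed out of bounds are clamped with a warning
  big <- flow_field(array(c(rep(200, 128 * 128), rep(0, 128 * 128)), c(128, 128, 2)))
  expect_warning(trb <- track_centerline(cl, list(big)), "clamped")
  expect_true(all(trb$positions[, 1, 2] <= 127))
})

test_that("tracked phantom centerline matches analytic advection to < 0.1 px", {
  ph <- default_phantom(amplitude = 0.15, n_frames = 16)
  cl <- extract_centerline(ph$masks[, , 1], ph$geometry$pixel_spacing)
  traj <- track_centerline(cl, oracle_estimator(ph))
  a <- ph$focal
  for (t in 1:16) {
    s <- ph$scales[t]
    adv <- cbind(a[1] + s * (cl$points[, 1] - a[1]), a[2] + s * (cl$points[, 2] - a[2]))
    expect_lt(max(abs(traj$positions[, , t] - adv)), 0.1)
  }
})

test_that("strain_curve applies the relative arc-length formula", {
  # build a trajectory whose arc lengths are exactly (100, 85, 100)
  mk <- function(len) cbind(seq(0, len, length.out = 11), rep(5, 11))
  pos <- array(0, c(11, 2, 3))
  pos[, , 1] <- mk(100); pos[, , 2] <- mk(85); pos[, , 3] <- mk(100)
  traj <- structure(list(positions = pos, apex_index = 6, pixel_spacing = 1),
                    class = "centerline_trajectory")
  res <- strain_curve(traj)
  expect_equal(res$tau, c(100, 85, 100))
  expect_equal(res$gls, c(0, -0.15, 0))
  expect_equal(res$peak_gls, -0.15)

  # constant arc length: zero strain everywhere
  pos2 <- array(rep(mk(50), 3), c(11, 2, 3))
  expect_true(all(strain_curve(structure(list(positions = pos2, apex_index = 6,
                                              pixel_spacing = 1),
                                         class = "centerline_trajectory"))$gls == 0))

  # degenerate tau(0) = 0
  pos3 <- array(1, c(11, 2, 2))
  expect_error(strain_curve(structure(list(positions = pos3, apex_index = 6,
                                           pixel_spacing = 1),
                                      class = "centerline_trajectory")),
               class = "echostrain_input_error")
})

test_that("divide_segments cuts three equal arcs per side of the apex", {
  # symmetric U of total length 60 (30 per side)
  up <- cbind(c(seq(0, 30, 1), rep(30, 30)), c(rep(0, 31), seq(1, 30, 1)))
  cl <- centerline(up, apex_index = 31, pixel_spacing = 1)
  part <- divide_segments(cl, "A4C")
  expect_equal(diff(part$boundaries), rep(10, 6))
  expect_equal(part$labels, segment_labels("A4C"))

  # asymmetric sides 30 and 60: arcs (10,10,10, 20,20,20)
  asym <- cbind(c(seq(0, 30, 1), rep(30, 60)), c(rep(0, 31), seq(1, 60, 1)))
  cl2 <- centerline(asym, apex_index = 31)
  expect_equal(diff(divide_segments(cl2)$boundaries), c(10, 10, 10, 20, 20, 20))
  # boundaries partition [0, total]
  expect_equal(divide_segments(cl2)$boundaries[7], 90)
  expect_equal(length(segment_labels("A2C")), 6)
  expect_equal(length(unique(c(segment_labels("A2C"), segment_labels("A3C"),
                               segment_labels("A4C")))), 16)
})

test_that("regional strain is uniform under scaling, null under rigid motion", {
  res <- oracle_strain(amplitude = 0.15)
  expect_true(all(abs(res$peak_rls - res$peak_gls) < 0.01))

  resr <- oracle_strain(mode = "rigid_translation", translation = c(1.5, 1), n_frames = 8)
  expect_lt(max(abs(resr$rls)), 0.005)
  expect_lt(max(abs(resr$gls)), 0.005)

  # conservation: segment arc lengths sum to the total at every frame
  expect_lt(max(abs(rowSums(res$tau_seg) - res$tau)) / res$tau[1], 1e-9)
  expect_equal(sum(res$tau_seg[1, ]), res$tau[1])
})

test_that("temporal refinement leaves the recovered peak strain stable", {
  r16 <- oracle_strain(amplitude = 0.15, n_frames = 16)
  r32 <- oracle_strain(amplitude = 0.15, n_frames = 32)
  expect_lt(abs(r16$peak_gls - r32$peak_gls), 0.002)
})

test_that("average_gls averages the available apical views", {
  expect_equal(as.numeric(average_gls(c(-0.14, -0.13, -0.13))), -(0.40 / 3))
  expect_message(one <- average_gls(c(-0.12)), "1 of 3")
  expect_equal(as.numeric(one), -0.12)
  expect_equal(attr(one, "n_views"), 1L)
  p <- c(-0.1, -0.15, -0.2)
  expect_equal(as.numeric(average_gls(p)), as.numeric(average_gls(rev(p))))
  expect_error(average_gls(numeric(0)), class = "echostrain_input_error")
  expect_error(average_gls(c(NA, NaN)), class = "echostrain_input_error")
  expect_error(average_gls(rep(-0.1, 4)), class = "echostrain_input_error")
})

test_that("strain results tidy, glance and plot", {
  res <- oracle_strain(amplitude = 0.15)
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_setequal(unique(td$curve), c("GLS", colnames(res$rls)))
  expect_equal(nrow(td), 16 * 7)
  gl <- glance(res)
  expect_equal(gl$peak_gls, res$peak_gls)
  expect_equal(ncol(gl), 4 + 6)
  p <- ggplot2::ggplot_build(autoplot(res))
  expect_gt(length(p$data), 0)
})
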