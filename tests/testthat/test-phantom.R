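test_that("contraction phantom satisfies its analytic contracts", {
  ph <- default_phantom(amplitude = 0.15, n_frames = 16)
  mot <- ph$motion

  # s(t) closed form and its strain: gls_true(t) = s(t) - 1, peak -A at mid-cycle
  expect_equal(ph$gls_true, contraction_scale(mot, 0:15) - 1)
  expect_equal(ph$gls_true[9], -0.15) # t = period/2, sin^2 = 1
  expect_equal(ph$gls_true[1], 0)

  # every tracked point lies strictly inside its frame's rasterized mask
  for (t in 1:16) {
    p <- round(ph$points[[t]])
    expect_true(all(ph$masks[cbind(p[, 2] + 1, p[, 1] + 1, t)] == 1))
  }

  # the rasterized flow, sampled at the material points, reproduces the point
  # displacements (the field is affine, so bilinear sampling is exact)
  for (t in 1:15) {
    d <- cbind(
      echostrain:::bilinear_sample(ph$flows[[t]][, , 1], ph$points[[t]][, 1], ph$points[[t]][, 2]),
      echostrain:::bilinear_sample(ph$flows[[t]][, , 2], ph$points[[t]][, 1], ph$points[[t]][, 2]))
    expect_lt(max(abs(d - (ph$points[[t + 1]] - ph$points[[t]]))), 1e-9)
  }

  # round-trip: advecting frame-0 points through all flows reaches frame 15
  p <- ph$points[[1]]
  for (t in 1:15) {
    p <- p + cbind(
      echostrain:::bilinear_sample(ph$flows[[t]][, , 1], p[, 1], p[, 2]),
      echostrain:::bilinear_sample(ph$flows[[t]][, , 2], p[, 1], p[, 2]))
  }
  expect_lt(max(abs(p - ph$points[[16]])), 1e-6)
})

test_that("analytic mid-band arc length scales exactly by s(t)", {
  ph <- default_phantom(amplitude = 0.15, n_frames = 16)
  geo <- ph$geometry
  # dense analytic sampling of the mid-band curve, scaled about the focal point
  r_mid <- (geo$r_endo + geo$r_epi) / 2
  beta <- geo$opening_half_angle
  th <- seq(pi / 2 + beta, pi / 2 + 2 * pi - beta, length.out = 4000)
  curve0 <- cbind(geo$center[1] + r_mid * cos(th), geo$center[2] + r_mid * sin(th))
  a <- ph$focal
  len <- function(p) sum(sqrt(rowSums(diff(p)^2)))
  l0 <- len(curve0)
  for (t in c(4, 8, 12)) {
    s <- ph$scales[t + 1]
    curve_t <- cbind(a[1] + s * (curve0[, 1] - a[1]), a[2] + s * (curve0[, 2] - a[2]))
    expect_lt(abs(len(curve_t) - s * l0) / (s * l0), 0.001)
  }
})

test_that("rigid and zero modes produce strain-free ground truth", {
  phr <- default_phantom(mode = "rigid_translation", translation = c(2, 0),
                         n_frames = 6, n_points = 60)
  m1 <- phr$masks[, , 1] == 1
  expect_true(all(phr$flows[[1]][, , 1][m1] == 2))
  expect_true(all(phr$flows[[1]][, , 2][m1] == 0))
  expect_true(all(phr$gls_true == 0))

  phz <- default_phantom(mode = "zero", n_frames = 4, n_points = 60)
  expect_identical(phz$video[, , 1], phz$video[, , 4])
  expect_true(all(vapply(phz$flows, function(f) all(f == 0), logical(1))))
  expect_true(all(phz$gls_true == 0))
})

test_that("speckle seed changes pixel intensities only", {
  geo <- phantom_geometry(image_size = c(64, 64), center = c(32, 32),
                          r_endo = 14, r_epi = 24, pixel_spacing = 0.5)
  mot <- phantom_motion(amplitude = 0.1, n_frames = 5)
  a <- make_phantom(geo, mot, speckle_seed = 1, n_points = 30)
  b <- make_phantom(geo, mot, speckle_seed = 99, n_points = 30)
  expect_identical(unclass(a$masks)[, , ], unclass(b$masks)[, , ])
  expect_identical(a$points, b$points)
  expect_identical(a$flows, b$flows)
  expect_false(identical(unclass(a$video)[, , ], unclass(b$video)[, , ]))
})

test_that("myocardial point sampling is even, deterministic and strictly inside", {
  ph <- default_phantom()
  mask <- matrix(as.integer(ph$masks[, , 1]), 256, 256)
  p1 <- sample_myocardial_points(mask, 180, seed = 42)
  p2 <- sample_myocardial_points(mask, 180, seed = 42)
  expect_identical(p1, p2)
  expect_true(all(mask[cbind(p1[, 2] + 1, p1[, 1] + 1)] == 1))

  # brute-force nearest-neighbour distances: near-uniform coverage
  d2 <- as.matrix(stats::dist(p1)); diag(d2) <- Inf
  nn <- apply(d2, 1, min)
  expect_lt(stats::sd(nn) / mean(nn), 0.5)

  # full-image mask, k = 4
  p4 <- sample_myocardial_points(matrix(1L, 10, 10), 4, seed = 1)
  expect_equal(nrow(p4), 4)
  expect_true(all(p4 >= 0 & p4 <= 9))

  expect_error(sample_myocardial_points(matrix(0L, 8, 8), 5), class = "echostrain_input_error")
  small <- matrix(0L, 8, 8); small[3, 3] <- 1L
  expect_error(sample_myocardial_points(small, 5), class = "echostrain_input_error")
  expect_error(sample_myocardial_points(matrix(1L, 8, 8), 2), class = "echostrain_input_error")
})

test_that("analytic_flow validates inputs and has the focal fixed point", {
  ph <- default_phantom()
  geo <- ph$geometry; mot <- ph$motion
  expect_error(analytic_flow(geo, mot, -1), class = "echostrain_input_error")
  expect_error(analytic_flow(geo, mot, 15), class = "echostrain_input_error")
  # the focal point is the fixed point of the scaling
  d <- echostrain:::analytic_flow_at(geo, mot, 3, rbind(ph$focal))
  expect_equal(as.numeric(d), c(0, 0))
})

test_that("geometry and motion constructors enforce their invariants", {
  expect_error(phantom_geometry(r_endo = 50, r_epi = 40), class = "echostrain_geometry_error")
  expect_error(phantom_geometry(opening_half_angle = 2), class = "echostrain_geometry_error")
  expect_error(phantom_geometry(center = c(10, 128)), class = "echostrain_geometry_error")
  expect_error(phantom_motion(amplitude = 0.6), class = "echostrain_input_error")
  expect_error(make_phantom(phantom_geometry(), phantom_motion(n_frames = 1)),
               class = "echostrain_input_error")
  # s(t) stays in (0.5, 1]
  mot <- phantom_motion(amplitude = 0.49, n_frames = 64)
  s <- contraction_scale(mot, 0:63)
  expect_true(all(s > 0.5 & s <= 1))
})
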