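test_that("the correlation volume equals all-pairs dot products", {
  # constant feature vectors: every entry is h * c^2
  fc <- array(2, c(3, 2, 2))
  pc <- correlation_volume(fc, fc)
  expect_true(all(pc$levels[[1]] == 12))

  # orthogonal feature vectors: zero off the matching structure
  f1 <- array(0, c(2, 2, 2)); f2 <- array(0, c(2, 2, 2))
  f1[1, , ] <- 1; f2[2, , ] <- 1
  expect_true(all(correlation_volume(f1, f2)$levels[[1]] == 0))

  # random maps vs the quadruple-loop oracle
  set.seed(10)
  for (trial in 1:3) {
    h <- sample(4:6, 1); w <- sample(4:6, 1); cc <- sample(2:4, 1)
    a <- array(rnorm(cc * h * w), c(cc, h, w))
    b <- array(rnorm(cc * h * w), c(cc, h, w))
    pyr <- correlation_volume(a, b)
    worst <- 0
    for (i in 1:h) for (j in 1:w) for (k in 1:h) for (l in 1:w) {
      s <- i + (j - 1) * h
      worst <- max(worst, abs(pyr$levels[[1]][s, k, l] - sum(a[, i, j] * b[, k, l])))
    }
    expect_lt(worst, 1e-5)
  }
  expect_error(correlation_volume(array(0, c(2, 4, 4)), array(0, c(2, 4, 5))),
               class = "echostrain_shape_error")
})

test_that("pyramid pooling preserves the mean (exact padding-free case)", {
  set.seed(11)
  a <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  b <- array(rnorm(3 * 8 * 8), c(3, 8, 8))
  pyr <- correlation_volume(a, b)
  for (l in 1:3)
    expect_equal(mean(pyr$levels[[l]]), mean(pyr$levels[[l + 1]]), tolerance = 1e-12)
  expect_length(pyr$levels, 4)
})

test_that("correlation lookup indexes and samples the pyramid correctly", {
  set.seed(12)
  pyr <- correlation_volume(array(rnorm(3 * 8 * 8), c(3, 8, 8)),
                            array(rnorm(3 * 8 * 8), c(3, 8, 8)))
  # zero flow, radius 0: the diagonal self-correlation entries
  lk <- corr_lookup(pyr, array(0, c(2, 8, 8)), 0L)
  diag_vals <- vapply(1:64, function(s)
    pyr$levels[[1]][s, (s - 1) %% 8 + 1, (s - 1) %/% 8 + 1], numeric(1))
  expect_equal(as.vector(lk$out[1, , ]), diag_vals)

  # integer flow on level 0 equals direct indexing
  fl <- array(0, c(2, 8, 8)); fl[1, , ] <- 2; fl[2, , ] <- -1
  lk2 <- corr_lookup(pyr, fl, 0L)
  manual <- vapply(1:64, function(s) {
    k <- (s - 1) %% 8; l <- (s - 1) %/% 8
    kk <- k - 1; ll <- l + 2 # (y + dy, x + dx)
    if (kk >= 0 && kk <= 7 && ll >= 0 && ll <= 7) pyr$levels[[1]][s, kk + 1, ll + 1] else 0
  }, numeric(1))
  expect_equal(as.vector(lk2$out[1, , ]), manual)

  # feature dimension is n_levels * (2r + 1)^2
  expect_equal(dim(corr_lookup(pyr, array(0, c(2, 8, 8)), 3L)$out)[1], 4 * 49)
})

test_that("estimate_flow honours the zero initialization and shape contracts", {
  cfg <- tiny_flow_config()
  m <- build_raft(cfg, seed = 2)
  f1 <- matrix(runif(32 * 32), 32, 32); f2 <- matrix(runif(32 * 32), 32, 32)

  e0 <- estimate_flow(m, f1, f2, iterations = 0)
  expect_true(all(e0$final == 0))

  est <- estimate_flow(m, f1, f2, iterations = 3)
  expect_length(est$iterates, 3)
  expect_equal(dim(est$final), c(32, 32, 2))
  # deterministic for fixed weights
  est2 <- estimate_flow(m, f1, f2, iterations = 3)
  expect_identical(unclass(est$final)[, , ], unclass(est2$final)[, , ])

  expect_error(estimate_flow(m, matrix(0, 30, 30), matrix(0, 30, 30)),
               class = "echostrain_shape_error")
  # identical seed -> identical build
  expect_identical(build_raft(cfg, seed = 2)$params, m$params)
})

test_that("sequence_loss matches closed forms, a loop oracle, and monotonicity", {
  set.seed(13)
  gt <- array(rnorm(16 * 16 * 2), c(16, 16, 2))
  expect_equal(sequence_loss(list(gt), gt), 0)

  f_err1 <- gt; f_err1[, , 1] <- f_err1[, , 1] + 1
  expect_identical(sequence_loss(list(f_err1, gt), gt, gamma = 0.8), 0.8)

  fs <- lapply(c(0.5, 0.3, 0.1), function(s) gt + array(rnorm(512, 0, s), dim(gt)))
  manual <- 0
  for (i in 1:3) {
    e <- mean(sqrt((fs[[i]][, , 1] - gt[, , 1])^2 + (fs[[i]][, , 2] - gt[, , 2])^2))
    manual <- manual + 0.8^(3 - i) * e
  }
  expect_equal(sequence_loss(fs, gt, 0.8), manual, tolerance = 1e-12)

  # monotone nondecreasing in each iterate's error
  base <- sequence_loss(fs, gt, 0.8)
  for (i in 1:3) {
    worse <- fs
    worse[[i]] <- worse[[i]] + 0.5
    expect_gt(sequence_loss(worse, gt, 0.8), base)
  }
  expect_error(sequence_loss(list(), gt), class = "echostrain_input_error")
  expect_error(sequence_loss(list(gt[1:8, , ]), gt), class = "echostrain_shape_error")
})

test_that("the oracle estimator returns the analytic flows unchanged", {
  ph <- tiny_phantom(n_frames = 5)
  fl <- oracle_estimator(ph)
  expect_length(fl, 4)
  for (t in 1:4) {
    res <- aepe(fl[[t]], ph$flows[[t]], matrix(1L, 32, 32))
    expect_identical(res$aepe_px, 0)
  }
  phr <- default_phantom(mode = "rigid_translation", translation = c(2, 0),
                         n_frames = 6, n_points = 60)
  f <- oracle_estimator(phr)[[1]]
  msk <- phr$masks[, , 1] == 1
  expect_true(all(f[, , 1][msk] == 2) && all(f[, , 2][msk] == 0))
})

test_that("flow training is seeded-reproducible and a no-op at zero iterations", {
  ph <- tiny_phantom(n_frames = 5)
  items <- make_training_items(ph)$flow
  m <- build_raft(tiny_flow_config(iterations = 2), seed = 4)
  t0 <- train_flow(m, items, iterations = 0)
  expect_identical(t0$model$params, m$params)
  ta <- train_flow(m, items, iterations = 2, seed = 6, batch_size = 1)
  tb <- train_flow(m, items, iterations = 2, seed = 6, batch_size = 1)
  expect_identical(ta$history, tb$history)
  expect_error(train_flow(m, list(), 2), class = "echostrain_input_error")
})
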