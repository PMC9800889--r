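test_that("end-point error matches its formula", {
  expect_equal(epe(c(1, 2), c(1, 2)), 0)
  expect_equal(epe(c(3, 4), c(0, 0)), 5)
  set.seed(1)
  v <- matrix(rnorm(20), 10, 2); w <- matrix(rnorm(20), 10, 2)
  expect_equal(epe(v, w), sqrt((v[, 1] - w[, 1])^2 + (v[, 2] - w[, 2])^2))
  expect_error(epe(c(1, 2, 3), c(1, 2, 3)), class = "echostrain_shape_error")
})

test_that("aepe summarizes per-pixel error over the mask, in px and mm", {
  f <- flow_field(array(rnorm(8 * 8 * 2), c(8, 8, 2)))
  msk <- matrix(1L, 8, 8)
  self <- aepe(f, f, msk, pixel_spacing = 0.3)
  expect_equal(self$aepe_px, 0); expect_equal(self$sd_px, 0)
  expect_equal(self$aepe_mm, 0)

  g <- unclass(f); g[, , 1] <- g[, , 1] + 1
  unif <- aepe(flow_field(g), f, msk, pixel_spacing = 0.5)
  expect_equal(unif$aepe_px, 1); expect_equal(unif$sd_px, 0)
  expect_equal(unif$aepe_mm, 0.5)

  # zero iff the fields agree on every mask pixel
  g2 <- unclass(f); g2[1, 1, 1] <- g2[1, 1, 1] + 5
  msk_hit <- matrix(0L, 8, 8); msk_hit[1, 1] <- 1L
  expect_gt(aepe(flow_field(g2), f, msk_hit)$aepe_px, 0)
  msk_miss <- matrix(0L, 8, 8); msk_miss[2:4, 2:4] <- 1L
  expect_equal(aepe(flow_field(g2), f, msk_miss)$aepe_px, 0)

  expect_error(aepe(f, f, matrix(0L, 8, 8)), class = "echostrain_input_error")
  expect_error(aepe(f, flow_field(array(0, c(4, 4, 2))), msk),
               class = "echostrain_shape_error")
})

test_that("bland_altman matches closed forms and recovers simulated agreement", {
  # constant offset: zero-width limits
  ref <- c(10, 12, 14)
  ba <- bland_altman(cbind(ref - 1.2, ref))
  expect_equal(ba$bias, -1.2)
  expect_equal(ba$loa_low, -1.2); expect_equal(ba$loa_high, -1.2)
  expect_equal(ba$mean_abs_diff, 1.2)

  # d = (+1, -1): bias 0, SD sqrt(2), LOA -+1.96 sqrt(2), MAD 1
  ba2 <- bland_altman(cbind(c(1, -1), c(0, 0)))
  expect_equal(ba2$bias, 0)
  expect_equal(ba2$loa_high, 1.96 * sqrt(2))
  expect_equal(ba2$loa_low, -1.96 * sqrt(2))
  expect_equal(ba2$mean_abs_diff, 1)

  # Monte-Carlo recovery of a Normal(-1.2, 1.5^2) difference distribution
  set.seed(20)
  ref <- rnorm(10000, -14, 3)
  pairs <- cbind(ref + rnorm(10000, -1.2, 1.5), ref)
  ba3 <- bland_altman(pairs)
  expect_lt(abs(ba3$bias + 1.2), 0.05)
  expect_lt(abs((ba3$loa_high - ba3$loa_low) / 2 - 1.96 * 1.5), 0.1)

  # antisymmetry under swapping method/reference; LOA width invariant
  sw <- bland_altman(pairs[, 2:1])
  expect_equal(sw$bias, -ba3$bias)
  expect_equal(sw$loa_high - sw$loa_low, ba3$loa_high - ba3$loa_low)

  expect_error(bland_altman(cbind(1, 2)), class = "echostrain_input_error")
})

test_that("correlations match closed forms and are affine-invariant", {
  x <- 1:8
  expect_equal(correlations(cbind(x, 2 * x + 3))$pearson_r, 1)
  expect_equal(correlations(cbind(x, 2 * x + 3))$spearman_rho, 1)
  expect_equal(correlations(cbind(x, rev(x)))$spearman_rho, -1)

  # small table vs hand-computed product-moment r
  a <- c(1, 2, 4, 5, 8); b <- c(2, 1, 5, 4, 9)
  r_hand <- sum((a - mean(a)) * (b - mean(b))) /
    sqrt(sum((a - mean(a))^2) * sum((b - mean(b))^2))
  expect_equal(correlations(cbind(a, b))$pearson_r, r_hand)

  set.seed(4)
  u <- rnorm(50); v <- u + rnorm(50, 0, 0.5)
  r0 <- correlations(cbind(u, v))$pearson_r
  expect_equal(correlations(cbind(3 * u - 7, v))$pearson_r, r0)
  expect_equal(correlations(cbind(u, 0.1 * v + 2))$pearson_r, r0)

  expect_error(correlations(cbind(c(1, 1, 1), c(1, 2, 3))),
               class = "echostrain_input_error")
  expect_error(correlations(cbind(1:2, 2:3)), class = "echostrain_input_error")
})

test_that("ICC(A,1) matches the two-way ANOVA mean-squares oracle", {
  m <- cbind(c(9, 8, 7, 10, 11, 6), c(8.5, 8.2, 6.1, 9.9, 11.8, 5.4))
  df <- data.frame(y = as.vector(m), subj = factor(rep(1:6, 2)),
                   rater = factor(rep(1:2, each = 6)))
  a <- summary(stats::aov(y ~ subj + rater, data = df))[[1]]
  msr <- a["subj", "Mean Sq"]; msc <- a["rater", "Mean Sq"]
  mse <- a["Residuals", "Mean Sq"]
  oracle <- (msr - mse) / (msr + mse + (2 / 6) * (msc - mse))
  expect_equal(icc(m), oracle, tolerance = 1e-12)

  expect_equal(icc(cbind(1:10, 1:10)), 1)
  expect_warning(v <- icc(matrix(3, 5, 2)), "degenerate")
  expect_equal(v, 1)

  set.seed(6)
  expect_lt(abs(icc(cbind(rnorm(1000), rnorm(1000)))), 0.1)

  # monotone degradation when independent noise is added to one column
  base <- rnorm(1000, -14, 3)
  pair <- cbind(base + rnorm(1000, 0, 0.5), base)
  noisy <- cbind(pair[, 1] + rnorm(1000, 0, 3), pair[, 2])
  expect_gt(icc(pair), icc(noisy))

  expect_error(icc(cbind(1:2, 2:3)), class = "echostrain_input_error")
})

test_that("agreement reports aggregate, tidy and serialize", {
  set.seed(7)
  ref <- rnorm(200, -14, 3)
  rep <- agreement_report(cbind(ref + rnorm(200, -1.2, 1.5), ref))
  expect_s3_class(rep, "agreement_report")
  expect_equal(rep$n_pairs, 200)
  td <- tidy(rep)
  expect_equal(nrow(td), 8)
  gl <- glance(rep)
  expect_equal(gl$bias, rep$bias)
  expect_true(rep$loa_low <= rep$bias && rep$bias <= rep$loa_high)
  expect_gte(rep$mean_abs_diff, abs(rep$bias) - 1e-12)

  path <- withr::local_tempfile(fileext = ".json")
  write_agreement_json(rep, path)
  back <- jsonlite::read_json(path)
  expect_equal(back$bias, rep$bias, tolerance = 1e-12)

  p <- ggplot2::ggplot_build(autoplot(rep))
  expect_gt(length(p$data), 0)

  csv <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(subject = 1:5, view = "A4C",
                              method_value = rnorm(5), reference_value = rnorm(5)),
                   csv, row.names = FALSE)
  df <- read_pairs_csv(csv)
  expect_equal(nrow(df), 5)
  bad <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(data.frame(a = 1), bad, row.names = FALSE)
  expect_error(read_pairs_csv(bad), class = "echostrain_format_error")
})
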