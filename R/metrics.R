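# Flow accuracy metrics (end-point error) and the method-agreement statistics
# used to compare an automatic strain pipeline against a reference method:
# Bland-Altman bias and limits of agreement, Pearson/Spearman correlation,
# and the two-way absolute-agreement intraclass correlation.

#' End-point error between displacement vectors
#'
#' Euclidean distance between predicted and true displacement,
#' `sqrt((Vx - Vx')^2 + (Vy - Vy')^2)`.
#'
#' @param v,v_hat length-2 vectors `(dx, dy)`, or `n x 2` matrices for a
#'   vectorized evaluation.
#' @return numeric EPE (px/frame), one value per row.
#' @export
epe <- function(v, v_hat) {
  v <- rbind(v); v_hat <- rbind(v_hat)
  if (ncol(v) != 2 || ncol(v_hat) != 2) stop_shape("EPE expects 2-component vectors")
  unname(sqrt(rowSums((v - v_hat)^2)))
}

#' Average end-point error of a flow field over a mask
#'
#' Mean and standard deviation (n-1 denominator) of the per-pixel EPE over
#' the mask, in px/frame and, when a pixel spacing is given, in mm/frame.
#'
#' @param flow,gt [flow_field()]s of equal size.
#' @param mask binary `H x W` matrix; evaluation region (nonempty).
#' @param pixel_spacing mm/px, or 0 to skip the mm scale.
#' @return one-row [tibble::tibble()] with `aepe_px`, `sd_px`, `aepe_mm`,
#'   `sd_mm`, `n_pixels`.
#' @export
aepe <- function(flow, gt, mask, pixel_spacing = 0) {
  if (!all(dim(flow) == dim(gt))) stop_shape("flow and ground truth differ in shape")
  if (!all(dim(mask) == dim(flow)[1:2])) stop_shape("mask does not match the flow shape")
  sel <- mask == 1
  if (!any(sel)) stop_input("empty evaluation mask")
  e <- sqrt((flow[, , 1] - gt[, , 1])^2 + (flow[, , 2] - gt[, , 2])^2)[sel]
  s <- if (length(e) > 1) stats::sd(e) else 0
  tibble::tibble(aepe_px = mean(e), sd_px = s,
                 aepe_mm = if (pixel_spacing > 0) mean(e) * pixel_spacing else NA_real_,
                 sd_mm = if (pixel_spacing > 0) s * pixel_spacing else NA_real_,
                 n_pixels = length(e))
}

as_pair_matrix <- function(pairs) {
  m <- as.matrix(pairs)
  if (ncol(m) != 2) stop_shape("pairs must have two columns (method, reference)")
  if (anyNA(m)) stop_input("pairs contain missing values")
  m
}

#' Bland-Altman agreement of paired measurements
#'
#' Differences are `method - reference`. Bias is their mean, the limits of
#' agreement are `bias +/- 1.96 * SD` (sample SD, n-1 denominator), and the
#' mean absolute difference is `mean(|d|)`.
#'
#' @param pairs two-column matrix or data frame `(method, reference)`, at
#'   least 2 rows.
#' @return list with `n_pairs`, `bias`, `sd`, `loa_low`, `loa_high`,
#'   `mean_abs_diff`.
#' @export
bland_altman <- function(pairs) {
  m <- as_pair_matrix(pairs)
  if (nrow(m) < 2) stop_input("need at least 2 measurement pairs")
  d <- m[, 1] - m[, 2]
  s <- stats::sd(d)
  list(n_pairs = nrow(m), bias = mean(d), sd = s,
       loa_low = mean(d) - 1.96 * s, loa_high = mean(d) + 1.96 * s,
       mean_abs_diff = mean(abs(d)))
}

#' Pearson and Spearman correlation of paired measurements
#'
#' @param pairs two-column matrix or data frame, at least 3 rows with nonzero
#'   variance in both columns.
#' @return list with `pearson_r` and `spearman_rho`.
#' @export
correlations <- function(pairs) {
  m <- as_pair_matrix(pairs)
  if (nrow(m) < 3) stop_input("need at least 3 pairs for a correlation")
  if (stats::sd(m[, 1]) == 0 || stats::sd(m[, 2]) == 0)
    stop_input("correlation undefined: a column has zero variance")
  list(pearson_r = stats::cor(m[, 1], m[, 2], method = "pearson"),
       spearman_rho = stats::cor(m[, 1], m[, 2], method = "spearman"))
}

#' Intraclass correlation, two-way absolute agreement, single measurement
#'
#' ICC(A,1) in the McGraw-Wong nomenclature, the variant appropriate for
#' comparing two fixed measurement systems on the same subjects. Computed
#' from the two-way ANOVA mean squares: with `n` subjects and `k` raters,
#' `ICC = (MSR - MSE) / (MSR + (k-1) MSE + k/n (MSC - MSE))`.
#'
#' @param pairs `n x k` matrix or data frame (one column per measurement
#'   system), `n >= 3`, `k >= 2`.
#' @return ICC in `(-1, 1]`; a degenerate table with all values equal returns
#'   1 with a warning.
#' @export
icc <- function(pairs) {
  m <- as.matrix(pairs)
  if (anyNA(m)) stop_input("pairs contain missing values")
  n <- nrow(m); k <- ncol(m)
  if (n < 3 || k < 2) stop_input("ICC needs at least 3 subjects and 2 raters")
  if (stats::sd(as.vector(m)) == 0) {
    warning("all measurements identical; ICC degenerate, returning 1")
    return(1)
  }
  grand <- mean(m)
  row_m <- rowMeans(m); col_m <- colMeans(m)
  msr <- k * sum((row_m - grand)^2) / (n - 1)
  msc <- n * sum((col_m - grand)^2) / (k - 1)
  sse <- sum((m - outer(row_m, rep(1, k)) - outer(rep(1, n), col_m) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
}

#' Full method-agreement report
#'
#' Combines Bland-Altman statistics, Pearson and Spearman correlations and
#' ICC(A,1) for a set of paired measurements (method vs reference).
#'
#' @param pairs two-column matrix or data frame `(method, reference)`.
#' @return an `agreement_report` object; see [tidy.agreement_report()] and
#'   [autoplot.agreement_report()].
#' @export
agreement_report <- function(pairs) {
  m <- as_pair_matrix(pairs)
  ba <- bland_altman(m)
  co <- correlations(m)
  structure(c(ba, co, list(icc = icc(m), pairs = m)),
            class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf(paste0(
    "<agreement_report> n = %d pairs\n",
    "  bias %.4g  LOA [%.4g, %.4g]  mean |diff| %.4g\n",
    "  Pearson r %.3f  Spearman rho %.3f  ICC(A,1) %.3f\n"),
    x$n_pairs, x$bias, x$loa_low, x$loa_high, x$mean_abs_diff,
    x$pearson_r, x$spearman_rho, x$icc))
  invisible(x)
}

#' Tidiers for agreement reports
#'
#' `tidy()` returns one row per statistic; `glance()` a one-row summary.
#'
#' @param x an `agreement_report`.
#' @param ... unused.
#' @return a [tibble::tibble()].
#' @method tidy agreement_report
#' @export
tidy.agreement_report <- function(x, ...) {
  tibble::tibble(
    statistic = c("bias", "sd_diff", "loa_low", "loa_high", "mean_abs_diff",
                  "pearson_r", "spearman_rho", "icc"),
    estimate = c(x$bias, x$sd, x$loa_low, x$loa_high, x$mean_abs_diff,
                 x$pearson_r, x$spearman_rho, x$icc))
}

#' @rdname tidy.agreement_report
#' @method glance agreement_report
#' @export
glance.agreement_report <- function(x, ...) {
  tibble::tibble(n_pairs = x$n_pairs, bias = x$bias, sd_diff = x$sd,
                 loa_low = x$loa_low, loa_high = x$loa_high,
                 mean_abs_diff = x$mean_abs_diff, pearson_r = x$pearson_r,
                 spearman_rho = x$spearman_rho, icc = x$icc)
}

#' Read paired strain measurements from CSV
#'
#' Expected columns: `subject`, `view`, `method_value`, `reference_value` and
#' optionally `group`.
#'
#' @param path CSV path.
#' @return a [tibble::tibble()].
#' @export
read_pairs_csv <- function(path) {
  df <- utils::read.csv(path)
  need <- c("subject", "view", "method_value", "reference_value")
  if (!all(need %in% names(df)))
    stop_format("pairs CSV must have columns %s: %s", paste(need, collapse = ", "), path)
  tibble::as_tibble(df)
}

#' Write an agreement report to JSON
#'
#' @param report an `agreement_report`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_agreement_json <- function(report, path) {
  out <- as.list(glance.agreement_report(report))
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
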