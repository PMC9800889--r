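# Tidiers and ggplot2 autoplot methods for the result objects.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidiers for strain results
#'
#' `tidy()` returns one row per frame and curve (the global curve plus each
#' regional segment); `glance()` a one-row summary with the peak values.
#'
#' @param x a `strain_result`.
#' @param ... unused.
#' @return a [tibble::tibble()].
#' @method tidy strain_result
#' @export
tidy.strain_result <- function(x, ...) {
  frames <- seq_along(x$gls) - 1L
  out <- tibble::tibble(frame = frames, curve = "GLS", tau_mm = x$tau,
                        strain = x$gls)
  if (!is.null(x$rls)) {
    seg <- do.call(rbind, lapply(seq_len(ncol(x$rls)), function(j)
      tibble::tibble(frame = frames, curve = colnames(x$rls)[j],
                     tau_mm = x$tau_seg[, j], strain = x$rls[, j])))
    out <- rbind(out, seg)
  }
  out
}

#' @rdname tidy.strain_result
#' @method glance strain_result
#' @export
glance.strain_result <- function(x, ...) {
  out <- tibble::tibble(view = x$view %||% NA_character_,
                        n_frames = length(x$gls),
                        tau_ed_mm = x$tau[1],
                        peak_gls = x$peak_gls)
  if (!is.null(x$peak_rls)) {
    pk <- tibble::as_tibble(as.list(x$peak_rls))
    names(pk) <- paste0("peak_rls_", seq_along(x$peak_rls))
    out <- cbind(out, pk)
  }
  tibble::as_tibble(out)
}

#' Plot strain curves
#'
#' Draws the global longitudinal strain curve (bold) and, when present, the
#' six regional curves, in percent against frame number.
#'
#' @param object a `strain_result`.
#' @param ... unused.
#' @return a [ggplot2::ggplot()].
#' @method autoplot strain_result
#' @export
autoplot.strain_result <- function(object, ...) {
  df <- tidy.strain_result(object)
  df$pct <- 100 * df$strain
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$pct,
                                   colour = .data$curve)) +
    ggplot2::geom_line(data = df[df$curve != "GLS", ], alpha = 0.7) +
    ggplot2::geom_line(data = df[df$curve == "GLS", ], linewidth = 1.2,
                       colour = "black") +
    ggplot2::labs(x = "frame", y = "longitudinal strain (%)",
                  colour = "segment",
                  title = sprintf("Peak GLS %.1f%%", 100 * object$peak_gls)) +
    ggplot2::theme_minimal()
}

#' Bland-Altman plot of an agreement report
#'
#' Scatter of pair differences against pair means with the bias line (solid)
#' and the 1.96 SD limits of agreement (dashed).
#'
#' @param object an `agreement_report`.
#' @param ... unused.
#' @return a [ggplot2::ggplot()].
#' @method autoplot agreement_report
#' @export
autoplot.agreement_report <- function(object, ...) {
  df <- tibble::tibble(mean = rowMeans(object$pairs),
                       diff = object$pairs[, 1] - object$pairs[, 2])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$mean, y = .data$diff)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::labs(x = "mean of methods", y = "difference (method - reference)",
                  title = sprintf("bias %.2f, LOA [%.2f, %.2f]",
                                  object$bias, object$loa_low, object$loa_high)) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
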