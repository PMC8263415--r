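#' Plot a surface grid as a height map
#'
#' @param object A [surface_grid].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.surface_grid <- function(object, ...) {
  h <- object$heights
  df <- tibble::tibble(
    x_um = rep((seq_len(ncol(h)) - 1) * object$pitch_x, each = nrow(h)),
    y_um = rep((seq_len(nrow(h)) - 1) * object$pitch_y, times = ncol(h)),
    height_um = as.vector(h)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x_um, .data$y_um,
                                   fill = .data$height_um)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey80") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (um)", y = "y (um)", fill = "height (um)",
                  title = object$meta$mark_id)
}

#' Plot the signatures of a set
#'
#' @param object A [signature_set()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_set <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$position_um, .data$height_um,
                               colour = factor(.data$line))) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "position (um)", y = "height (um)", colour = "line",
                  title = paste("signatures of", object$mark_id))
}

#' Plot a cross-correlation curve
#'
#' @param object A `correlation_result` from [normalized_xcorr()] or
#'   [compare_marks()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.correlation_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$lag, .data$xcorr)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = object$best_lag, linetype = 2,
                        colour = "red") +
    ggplot2::annotate("text", x = object$best_lag, y = object$score,
                      label = sprintf("%.3f @ %d", object$score,
                                      object$best_lag),
                      vjust = -0.5, hjust = -0.1, size = 3) +
    ggplot2::labs(x = "lag (samples)", y = "normalized cross-correlation")
}

#' Plot KM/KNM reference distributions with a query score
#'
#' Score samples with their group means and 95% confidence intervals, in the
#' style of a known-match / known-non-match calibration figure; optional
#' query scores are overlaid as horizontal lines.
#'
#' @param object A [build_reference()] object.
#' @param query Optional named numeric vector of query scores to overlay.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ref_distributions <- function(object, query = NULL, ...) {
  pts <- tibble::tibble(
    group = c(rep("KM", object$n_km), rep("KNM", object$n_knm)),
    score = c(object$km_scores, object$knm_scores)
  )
  ci <- tidy(object)
  p <- ggplot2::ggplot(pts, ggplot2::aes(.data$group, .data$score)) +
    ggplot2::geom_jitter(width = 0.08, alpha = 0.6) +
    ggplot2::geom_pointrange(
      data = ci,
      ggplot2::aes(.data$group, .data$mean,
                   ymin = .data$ci_lower, ymax = .data$ci_upper),
      colour = "red", linewidth = 0.8
    ) +
    ggplot2::labs(x = NULL, y = "normalized cross-correlation",
                  title = sprintf("KM/KNM reference (%s, %.0f%% CI)",
                                  object$ci_method, 100 * object$conf))
  if (!is.null(query)) {
    qdf <- tibble::tibble(name = names(query) %||% seq_along(query),
                          score = as.numeric(query))
    p <- p + ggplot2::geom_hline(
      data = qdf, ggplot2::aes(yintercept = .data$score), linetype = 3
    )
  }
  p
}
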