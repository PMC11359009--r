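#' Plot an ROC curve for an evaluation result
#'
#' @param object An `"octa_eval"` from [evaluate()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.octa_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_step(linewidth = 0.8, colour = "#2166ac") +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 3,
                         colour = "grey50") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s | %s | %s", object$task,
                      paste(object$features, collapse = "+"), object$kernel),
      subtitle = sprintf("AUC = %.3f (%s, n = %d)", object$auc,
                         object$scheme, object$n)
    ) +
    ggplot2::theme_minimal()
}

#' QC overlay of FAZ geometry and the sector grid
#'
#' Draws the FAZ boundary, centroid, and the inner/outer sector rings over
#' the en-face image.
#'
#' @param img En-face intensity matrix.
#' @param faz A `"faz_result"`.
#' @param zones Optional `"sector_zones"`; rings are drawn when given.
#' @return A ggplot.
#' @export
plot_faz_overlay <- function(img, faz, zones = NULL) {
  df <- expand.grid(row = seq_len(nrow(img)), col = seq_len(ncol(img)))
  df$value <- as.vector(img)
  bdf <- as.data.frame(faz$boundary_px)
  p <- ggplot2::ggplot() +
    ggplot2::geom_raster(data = df,
                         ggplot2::aes(x = .data$col, y = .data$row,
                                      fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::geom_point(data = bdf,
                        ggplot2::aes(x = .data$col, y = .data$row),
                        colour = "red", size = 0.2) +
    ggplot2::annotate("point", x = faz$centroid[2], y = faz$centroid[1],
                      colour = "red", shape = 3, size = 3) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
  if (!is.null(zones)) {
    th <- seq(0, 2 * pi, length.out = 200)
    for (r in c(zones$inner_radius_px, zones$outer_radius_px)) {
      ring <- data.frame(col = zones$center[2] + r * cos(th),
                         row = zones$center[1] + r * sin(th))
      p <- p + ggplot2::geom_path(data = ring,
                                  ggplot2::aes(x = .data$col, y = .data$row),
                                  colour = "yellow", linewidth = 0.3)
    }
  }
  p
}

#' Plot a range-filter histogram with its FC/FWHM annotation
#'
#' @param hist Tibble from [intensity_histogram()].
#' @param features Optional one-row tibble from [extract_fc_fwhm()]; the
#'   peak and half-maximum crossings are marked when given.
#' @return A ggplot.
#' @export
plot_range_histogram <- function(hist, features = NULL) {
  p <- ggplot2::ggplot(hist, ggplot2::aes(x = .data$intensity,
                                          y = .data$count)) +
    ggplot2::geom_col(width = 1, fill = "#4393c3") +
    ggplot2::labs(x = "Local intensity range", y = "Pixel count") +
    ggplot2::theme_minimal()
  if (!is.null(features)) {
    p <- p +
      ggplot2::geom_vline(xintercept = features$fc, colour = "red") +
      ggplot2::geom_vline(xintercept = c(features$x_half1, features$x_half2),
                          colour = "red", linetype = 2) +
      ggplot2::labs(subtitle = sprintf("FC = %d, FWHM = %d",
                                       features$fc, features$fwhm))
  }
  p
}

#' Scatter plot of a two-feature classification task
#'
#' @param table Feature table with `label`.
#' @param features Character vector of two feature names.
#' @param task One of [octa_tasks()].
#' @return A ggplot.
#' @export
plot_feature_scatter <- function(table, features, task = "normal_vs_ad") {
  stopifnot(length(features) == 2)
  dat <- .task_subset(table, task)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data[[features[1]]],
                                    y = .data[[features[2]]],
                                    colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_colour_manual(values = c(normal = "#b2182b",
                                            disease = "#2166ac")) +
    ggplot2::labs(title = task) +
    ggplot2::theme_minimal()
}
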