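# ggplot2 views of the main result types: PCA score maps and score plots,
# segmentation label maps, pixel classification maps, VIP profiles.

pixel_raster <- function(df, fill) {
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = {{ fill }})) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_minimal()
}

#' Plot a PCA score map
#' @param map A [score_map()] tibble.
#' @return A ggplot.
#' @export
plot_score_map <- function(map) {
  pixel_raster(map, .data$score) +
    ggplot2::scale_fill_viridis_c(name = "score")
}

#' @export
autoplot.msi_pca <- function(object, components = c(1L, 2L), ...) {
  sc <- tibble::as_tibble(as.data.frame(object$scores[, components]))
  names(sc) <- c("a", "b")
  if (!is.null(object$info)) sc$class <- object$info$class_label
  p <- ggplot2::ggplot(sc, ggplot2::aes(x = .data$a, y = .data$b)) +
    ggplot2::labs(
      x = sprintf("PC%d (%.1f%%)", components[1],
                  100 * object$explained[components[1]]),
      y = sprintf("PC%d (%.1f%%)", components[2],
                  100 * object$explained[components[2]])) +
    ggplot2::theme_minimal()
  if (!is.null(object$info)) {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$class), size = 3)
  } else {
    p + ggplot2::geom_point(size = 3)
  }
}

#' @export
autoplot.msi_segmentation <- function(object, ...) {
  df <- object$labels
  df$cluster <- factor(df$cluster)
  pixel_raster(df, .data$cluster) +
    ggplot2::labs(title = sprintf("%s (k = %d)", object$image_id, object$k),
                  fill = "cluster")
}

#' @export
autoplot.pixel_classification <- function(object, ...) {
  pixel_raster(object$map, .data$class) +
    ggplot2::labs(title = sprintf("%s: %.1f%% pixels match '%s'",
                                  object$image_id, object$percent_correct,
                                  object$truth_label),
                  fill = "class")
}

#' @export
autoplot.plsda <- function(object, threshold = 2, ...) {
  df <- tibble::tibble(variable = seq_along(object$vip), vip = object$vip)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$variable, y = .data$vip)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$variable, yend = 0)) +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2,
                        colour = "red") +
    ggplot2::labs(y = "VIP score") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.plsda_cv <- function(object, ...) {
  df <- tidy(object)
  df <- df[df$metric == "accuracy", ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_lv, y = .data$value,
                                   colour = .data$split)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "latent variables", y = "accuracy (%)") +
    ggplot2::theme_minimal()
}
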