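#' Similarity-matrix heatmap
#'
#' Plots the display-normalized cosine similarity matrix of an evaluation as
#' a heatmap, test images on the vertical axis and categories on the
#' horizontal. Because raw similarities crowd toward 1, entries below `floor`
#' are clamped to the floor color to highlight the differences that matter
#' (the real-data figures use a display lower limit of 0.90 on the normalized
#' scale).
#'
#' @param object A `voc_eval` from [evaluate()].
#' @param floor Display lower limit on the normalized similarity (default
#'   0.90); use 0 to show the full range.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot voc_eval
#' @export
autoplot.voc_eval <- function(object, floor = 0.90, ...) {
  S <- object$similarity_norm %||% object$similarity
  df <- tidyr::expand_grid(
    test = factor(rownames(S), levels = rev(rownames(S))),
    category = factor(colnames(S), levels = colnames(S))
  )
  df$similarity <- as.vector(t(S))
  df$shown <- pmax(df$similarity, floor)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$test,
                                   fill = .data$shown)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "normalized\ncosine", limits = c(floor, 1)) +
    ggplot2::labs(x = "category centroid", y = "test image") +
    ggplot2::theme_minimal(base_size = 9) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90, vjust = 0.5))
}

#' @rdname autoplot.voc_eval
#' @param x A `voc_eval`.
#' @param y Unused.
#' @export
plot.voc_eval <- function(x, y, floor = 0.90, ...) print(autoplot(x, floor = floor, ...))

#' Plot a labeled image or its block-averaged reconstruction
#'
#' @param object A [labeled_image()].
#' @param ... Unused.
#' @return A ggplot object rendering the pixels at native aspect ratio.
#' @method autoplot labeled_image
#' @export
autoplot.labeled_image <- function(object, ...) {
  h <- img_height(object); w <- img_width(object)
  rast <- grDevices::as.raster(object$pixels / 255)
  ggplot2::ggplot() +
    ggplot2::annotation_raster(rast, xmin = 0, xmax = w, ymin = 0, ymax = h) +
    ggplot2::coord_fixed(xlim = c(0, w), ylim = c(0, h), expand = FALSE) +
    ggplot2::labs(title = if (is.na(object$label)) object$source_id else object$label) +
    ggplot2::theme_void()
}
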