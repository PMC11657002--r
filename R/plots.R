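# QC figures: slice channels, seed overlays (green positive / magenta
# negative), saliency and tumor heatmaps, superpixel label maps.

raster_df <- function(m, value = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  df
}

theme_image <- function() {
  ggplot2::theme_void() +
    ggplot2::theme(legend.position = "right")
}

#' Plot one channel of a multimodal slice
#' @param pixels an (H, W, 4) slice array
#' @param channel channel to display (default 4, T2-FLAIR)
#' @return a ggplot object
#' @export
plot_slice <- function(pixels, channel = 4L) {
  df <- raster_df(pixels[, , channel])
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white", limits = c(0, 1)) +
    ggplot2::coord_fixed() + theme_image() +
    ggplot2::labs(fill = paste0("ch", channel))
}

#' Overlay localization seeds on a slice
#'
#' Positive seeds are drawn green, negative seeds magenta, unseeded regions
#' keep the underlying image.
#'
#' @param pixels an (H, W, 4) slice array
#' @param seeds a [seed_map()]
#' @param channel background channel (default 4)
#' @return a ggplot object
#' @export
plot_seeds <- function(pixels, seeds, channel = 4L) {
  df <- raster_df(pixels[, , channel])
  df$seed <- c("unseeded", "positive", "negative")[
    1 + as.vector(seeds$positive) + 2 * as.vector(seeds$negative)]
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row)) +
    ggplot2::geom_raster(ggplot2::aes(alpha = .data$value), fill = "white") +
    ggplot2::geom_raster(data = df[df$seed != "unseeded", ],
                         ggplot2::aes(fill = .data$seed), alpha = 0.6) +
    ggplot2::scale_fill_manual(values = c(positive = "green3",
                                          negative = "magenta3")) +
    ggplot2::scale_alpha(range = c(0, 1), guide = "none") +
    ggplot2::coord_fixed() + theme_image()
}

#' Plot a saliency or tumor heatmap
#' @param h an (H, W) matrix
#' @return a ggplot object
#' @export
plot_heatmap <- function(h) {
  ggplot2::ggplot(raster_df(h), ggplot2::aes(.data$col, -.data$row,
                                             fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() + theme_image()
}

#' Plot the hard superpixel label map of an association array
#' @param q an (H, W, N_S) association array
#' @return a ggplot object
#' @export
plot_superpixels <- function(q) {
  lab <- superpixel_labels(q)
  df <- raster_df(lab, "superpixel")
  df$superpixel <- factor(df$superpixel)
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$superpixel)) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::coord_fixed() + theme_image()
}

#' @export
#' @rdname plot_heatmap
#' @param object a `segmentation`
#' @param ... unused
autoplot.segmentation <- function(object, ...) {
  df <- raster_df(object$heatmap)
  df$mask <- as.vector(object$mask)
  p <- plot_heatmap(object$heatmap)
  if (any(df$mask != 0))
    p <- p + ggplot2::geom_tile(data = df[df$mask != 0, ],
                                fill = NA, colour = "red", linewidth = 0.2)
  p
}
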