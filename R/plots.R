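#' @importFrom ggplot2 autoplot ggplot aes geom_raster geom_line geom_path
#'   geom_point geom_errorbar facet_wrap labs scale_fill_viridis_c
#'   scale_fill_manual coord_fixed theme_minimal
#' @export
ggplot2::autoplot

mat_to_df <- function(m, value = "value") {
  df <- expand.grid(row = seq_len(nrow(m)), col = seq_len(ncol(m)))
  df[[value]] <- as.vector(m)
  df
}

ellipse_path_df <- function(e, n = 181) {
  t <- seq(0, 2 * pi, length.out = n)
  u <- e$semi_major * cos(t); v <- e$semi_minor * sin(t)
  data.frame(
    col = e$center[2] + u * cos(e$orientation) - v * sin(e$orientation),
    row = e$center[1] - (u * sin(e$orientation) + v * cos(e$orientation)))
}

#' Plot a trimap with its two ellipses
#'
#' @param object A trimap.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trimap
#' @export
autoplot.trimap <- function(object, ...) {
  df <- mat_to_df(object$labels)
  df$label <- factor(df$value, levels = c(TRIMAP_BG, TRIMAP_FG, TRIMAP_IGNORE),
                     labels = c("background", "foreground", "ignore"))
  ggplot(df, aes(x = .data$col, y = .data$row, fill = .data$label)) +
    geom_raster() +
    geom_path(data = ellipse_path_df(object$small_ellipse),
              aes(x = .data$col, y = .data$row), inherit.aes = FALSE) +
    geom_path(data = ellipse_path_df(object$large_ellipse),
              aes(x = .data$col, y = .data$row), inherit.aes = FALSE,
              linetype = "dashed") +
    scale_fill_manual(values = c(background = "grey20", foreground = "tomato",
                                 ignore = "grey70")) +
    ggplot2::scale_y_reverse() + coord_fixed() + theme_minimal() +
    labs(x = NULL, y = NULL, fill = NULL)
}

#' Plot one multi-modality slice with its truth outline
#'
#' @param slices Slice tibble.
#' @param index Row to plot.
#' @return A ggplot faceted by modality.
#' @export
plot_slice <- function(slices, index = 1) {
  img <- slices$image[[index]]
  dfs <- purrr::map(seq_len(dim(img)[3]), function(m) {
    d <- mat_to_df(img[, , m])
    d$modality <- paste0("modality ", m)
    d
  }) |> dplyr::bind_rows()
  p <- ggplot(dfs, aes(x = .data$col, y = .data$row, fill = .data$value)) +
    geom_raster() + facet_wrap(~modality) +
    scale_fill_viridis_c(option = "magma") +
    ggplot2::scale_y_reverse() + coord_fixed() + theme_minimal() +
    labs(x = NULL, y = NULL, fill = "intensity",
         title = sprintf("%s (slice %d)", slices$patient_id[index],
                         slices$slice_index[index]))
  mask <- slices$mask[[index]]
  if (!is.null(mask) && sum(mask) >= 5) {
    e <- initial_ellipse(largest_component(mask), dilation = 1)
    p <- p + geom_path(data = ellipse_path_df(e),
                       aes(x = .data$col, y = .data$row), inherit.aes = FALSE,
                       colour = "white", linetype = "dotted")
  }
  p
}

largest_component <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  if (max(lab) <= 1) return(mask)
  (lab == which.max(tabulate(lab[lab > 0]))) * 1
}

#' Plot training curves of a trained model
#'
#' @param object A trained `msunet`.
#' @param ... Unused.
#' @return A ggplot of loss and pixel accuracy per epoch, coloured by round.
#' @method autoplot msunet
#' @export
autoplot.msunet <- function(object, ...) {
  h <- tidy(object)
  if (nrow(h) == 0) abort_input("model has no training history")
  long <- tidyr::pivot_longer(h, c("loss", "pixel_accuracy"),
                              names_to = "quantity")
  ggplot(long, aes(x = .data$epoch, y = .data$value, colour = .data$round)) +
    geom_line() + facet_wrap(~quantity, scales = "free_y") +
    theme_minimal() + labs(y = NULL, colour = "round")
}

#' Plot a metrics report as point-ranges
#'
#' @param object A `metrics_report`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot metrics_report
#' @export
autoplot.metrics_report <- function(object, ...) {
  s <- object$summary
  ggplot(s, aes(x = .data$metric, y = .data$mean)) +
    geom_point() +
    geom_errorbar(aes(ymin = .data$mean - .data$sd,
                      ymax = .data$mean + .data$sd), width = 0.2) +
    theme_minimal() +
    labs(x = NULL, y = "mean over runs (+/- population sd)")
}
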