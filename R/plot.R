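#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

raster_df <- function(mat, value = "value") {
  df <- expand.grid(row = seq_len(nrow(mat)), col = seq_len(ncol(mat)))
  df[[value]] <- as.vector(mat)
  df
}

#' Plot a response map
#'
#' @param object A `response_map`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.response_map <- function(object, ...) {
  df <- raster_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c(name = "V") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = if (!is.na(object$threshold)) {
                    sprintf("Negative-Laplacian response (threshold %.3g)",
                            object$threshold)
                  } else "Negative-Laplacian response")
}

#' Plot detected components
#'
#' @param object A `component_set`.
#' @param image Optional background `image_grid` / matrix.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.component_set <- function(object, image = NULL, ...) {
  p <- ggplot2::ggplot()
  if (!is.null(image)) {
    img <- as_image_grid(image)
    p <- p + ggplot2::geom_raster(
      data = raster_df(img$pixels, "intensity"),
      ggplot2::aes(x = .data$col, y = .data$row, fill = .data$intensity)) +
      ggplot2::scale_fill_gradient(low = "black", high = "white",
                                   guide = "none")
  }
  if (length(object$components) > 0) {
    pts <- dplyr::bind_rows(purrr::imap(object$components, function(px, i) {
      tibble::tibble(row = px[, 1], col = px[, 2], component = factor(i))
    }))
    p <- p + ggplot2::geom_point(
      data = pts, ggplot2::aes(x = .data$col, y = .data$row,
                               colour = .data$component),
      size = 0.3, show.legend = FALSE)
  }
  p + ggplot2::scale_y_reverse() + ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%d detected components",
                                  length(object$components)))
}

#' Noise-robustness recall curve
#'
#' @param summary Tibble from [noise_robustness_experiment()].
#' @return A ggplot of recall against noise level, overall and for dim
#'   sources.
#' @export
plot_noise_robustness <- function(summary) {
  long <- tidyr::pivot_longer(
    summary, c("mean_recall", "mean_recall_dim"),
    names_to = "population", values_to = "recall")
  long$population <- ifelse(long$population == "mean_recall",
                            "all sources", "dim sources")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$noise_frac,
                                     y = .data$recall,
                                     colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "noise fraction of 8-bit range", y = "mean recall",
                  colour = NULL)
}

#' Conflict-weight profile of a fused table
#'
#' @param joint Tibble from [combine_labelled_tables()] or
#'   [dempster_combine()].
#' @return A ggplot of the weight of conflict against the joint mass.
#' @export
plot_conflict <- function(joint) {
  ggplot2::ggplot(joint[!joint$contradictory, ],
                  ggplot2::aes(x = .data$joint_mass,
                               y = .data$conflict_weight)) +
    ggplot2::geom_point(alpha = 0.4) +
    ggplot2::labs(x = "joint mass", y = "weight of conflict W")
}
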