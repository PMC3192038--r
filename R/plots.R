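#' Plot score trajectories with their conversion labels
#'
#' Score versus age, one line per MCI subject, colored by trajectory label;
#' the horizontal zero line is the AD-Control decision boundary (negative =
#' AD side).
#'
#' @param object A [score_trajectories()] tibble.
#' @param labels Optional [conversion_labels()] tibble for coloring.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.score_trajectories <- function(object, labels = NULL, ...) {
  df <- as_tibble(object)
  if (!is.null(labels))
    df <- left_join(df, select(labels, "subject_id", "by_trajectory"),
                    by = "subject_id")
  else df$by_trajectory <- "unlabeled"
  ggplot2::ggplot(df, ggplot2::aes(.data$age, .data$score,
                                   group = .data$subject_id,
                                   colour = .data$by_trajectory)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::geom_line(alpha = 0.5) +
    ggplot2::geom_point(size = 0.7, alpha = 0.6) +
    ggplot2::scale_colour_manual(values = c(
      NT = "#1b9e77", CT = "#444444", outlier = "#e6ab02",
      unlabeled = "grey40")) +
    ggplot2::labs(x = "age (years)", y = "signed distance to AD-Control boundary",
                  colour = NULL)
}

#' Plot an elimination trace
#'
#' Margin and (when present) out-of-bootstrap validation error against the
#' number of retained features, right to left as elimination proceeds.
#'
#' @param object An [run_elimination()] trace.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.elimination_trace <- function(object, ...) {
  df <- tidy(object) %>%
    tidyr::pivot_longer(c("margin", "val_error"), names_to = "quantity",
                        values_to = "value") %>%
    filter(!is.na(.data$value))
  ggplot2::ggplot(df, ggplot2::aes(.data$n_retained, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::facet_wrap(~quantity, scales = "free_y", ncol = 1) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "retained features", y = NULL,
                  title = paste0(attr(object, "method"), " elimination"))
}

#' Plot the sorted retained-fraction curve of a region report
#'
#' @param object A [region_retention()] report.
#' @param threshold Threshold drawn as a horizontal line.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.region_report <- function(object, threshold = 0.125, ...) {
  df <- as_tibble(object) %>%
    arrange(dplyr::desc(.data$fraction)) %>%
    mutate(rank = dplyr::row_number())
  ggplot2::ggplot(df, ggplot2::aes(.data$rank, .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = threshold, linetype = 2) +
    ggplot2::labs(x = "region (sorted)", y = "retained voxel fraction")
}

#' Plot per-class biomarker separation as Gaussian curves
#'
#' @param object A [histogram_separation()] result.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.histogram_separation <- function(object, ...) {
  bc <- object$by_class
  lim <- range(bc$mean + 3 * bc$sd, bc$mean - 3 * bc$sd)
  grid <- seq(lim[1], lim[2], length.out = 200)
  df <- purrr::pmap_dfr(bc, function(class, n, mean, sd)
    tibble(class = class, x = grid,
           density = stats::dnorm(grid, mean, sd)))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$density,
                                   colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "biomarker value", y = "density", colour = NULL)
}
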