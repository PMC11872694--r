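#' Assign attributes to better-worse quadrants
#'
#' Places every attribute on the better-worse plane — x = |Worse| (the
#' magnitude of the dissatisfaction coefficient), y = Better — and
#' partitions the plane into four quadrants at the given thresholds.
#' "High" means greater than or equal to the threshold, so the partition is
#' exhaustive and exclusive for any threshold pair. Default thresholds are
#' the cross-attribute means of the two coordinates, the conventional
#' dividing lines when none are prescribed.
#'
#' @param indices Output of [kano_indices()] (or the `indices` element of a
#'   [summarize_survey()] result).
#' @param x_threshold,y_threshold Dividing lines on |Worse| and Better;
#'   `NULL` (default) uses the respective means.
#' @return A tibble: `attribute`, `better`, `worse_magnitude`, `quadrant`
#'   (one of `"high-better/high-worse"`, `"high-better/low-worse"`,
#'   `"low-better/high-worse"`, `"low-better/low-worse"`), plus the
#'   thresholds used (constant columns `x_threshold`, `y_threshold`).
#' @examples
#' q <- quadrant_assign(kano_indices(sports_demand_counts()))
#' table(q$quadrant)
#' @export
quadrant_assign <- function(indices, x_threshold = NULL, y_threshold = NULL) {
  indices <- tibble::as_tibble(indices)
  stopifnot(all(c("attribute", "better", "worse") %in% names(indices)))
  if (nrow(indices) == 0) stop("no attributes to assign", call. = FALSE)
  x <- abs(indices$worse)
  y <- indices$better
  x_threshold <- x_threshold %||% mean(x)
  y_threshold <- y_threshold %||% mean(y)
  stopifnot(is.finite(x_threshold), is.finite(y_threshold))
  tibble::tibble(
    attribute = indices$attribute,
    better = y,
    worse_magnitude = x,
    quadrant = paste0(
      ifelse(y >= y_threshold, "high-better", "low-better"), "/",
      ifelse(x >= x_threshold, "high-worse", "low-worse")
    ),
    x_threshold = x_threshold,
    y_threshold = y_threshold
  )
}

#' Better-worse scatter plot
#'
#' Scatter of attributes on the better-worse plane with labelled points,
#' dashed threshold lines and quadrant shading by assignment. The layout is
#' deterministic for fixed input.
#'
#' @param assignments Output of [quadrant_assign()].
#' @return A ggplot object.
#' @examples
#' q <- quadrant_assign(kano_indices(sports_demand_counts()))
#' plot_better_worse(q)
#' @export
plot_better_worse <- function(assignments) {
  assignments <- tibble::as_tibble(assignments)
  needed <- c("attribute", "better", "worse_magnitude", "quadrant",
              "x_threshold", "y_threshold")
  stopifnot(all(needed %in% names(assignments)))
  if (nrow(assignments) == 0) stop("no attributes to plot", call. = FALSE)
  ggplot2::ggplot(
    assignments,
    ggplot2::aes(x = .data$worse_magnitude, y = .data$better,
                 colour = .data$quadrant)
  ) +
    ggplot2::geom_vline(xintercept = assignments$x_threshold[1],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_hline(yintercept = assignments$y_threshold[1],
                        linetype = "dashed", colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_text(ggplot2::aes(label = .data$attribute),
                       vjust = -0.8, size = 3, show.legend = FALSE) +
    ggplot2::scale_x_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::scale_y_continuous(labels = function(v) sprintf("%.0f%%", 100 * v)) +
    ggplot2::labs(x = "|Worse| (dissatisfaction if absent)",
                  y = "Better (satisfaction if present)",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Write the better-worse plot to a file
#'
#' @inheritParams plot_better_worse
#' @param path Output file; format from the extension (png or svg).
#' @param width,height Plot size in inches.
#' @return `path`, invisibly.
#' @export
write_better_worse_plot <- function(assignments, path, width = 7, height = 5) {
  p <- plot_better_worse(assignments)
  ggplot2::ggsave(path, plot = p, width = width, height = height)
  invisible(path)
}
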