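# ggplot2 displays for cluster patterns, age-trend fits and sector maps.

#' Plot a cluster pattern as a pseudo-coloured 8x8 grid
#'
#' @param object A `cluster_pattern`.
#' @param ... Unused.
#' @return A ggplot. Rows run superior (top) to inferior, columns nasal
#'   (left) to temporal (right), right-eye format; excluded foveal cells are
#'   blank.
#' @method autoplot cluster_pattern
#' @export
autoplot.cluster_pattern <- function(object, ...) {
  td <- tidy(object)
  ggplot2::ggplot(td, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$cluster))) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::scale_y_reverse(breaks = 1:8) +
    ggplot2::scale_x_continuous(breaks = 1:8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (nasal → temporal)",
                  y = "row (superior → inferior)",
                  fill = "cluster",
                  title = sprintf("%s spatial clusters (%s, %s)",
                                  object$layer, object$method, object$grouping)) +
    ggplot2::theme_minimal()
}

#' Plot per-cluster cohort means with fitted age trajectories
#'
#' @param object A `pattern_evaluation` for an age-grouped pattern.
#' @param ... Unused.
#' @return A ggplot of cohort mean thickness against representative age,
#'   one panel-free colour per cluster, with the fitted curve and vertex
#'   marked where it lies within the cohort age range.
#' @method autoplot pattern_evaluation
#' @export
autoplot.pattern_evaluation <- function(object, ...) {
  if (object$grouping != "age") {
    stop("trajectory plot applies to age-grouped evaluations", call. = FALSE)
  }
  models <- object$models
  pts <- tidyr::unnest(dplyr::select(models, "cluster", "points"), "points")
  ages <- seq(min(pts$age), max(pts$age), length.out = 100)
  curves <- purrr::map_dfr(seq_len(nrow(models)), function(i) {
    tibble::tibble(cluster = models$cluster[i], age = ages,
                   thickness_um = predict_fit(models$fit[[i]], ages))
  })
  vertices <- dplyr::filter(models, !.data$beyond_cohort)
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$age, y = .data$thickness_um,
                                         colour = factor(.data$cluster))) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = curves) +
    ggplot2::labs(x = "age (years)", y = "thickness (µm)",
                  colour = "cluster",
                  title = sprintf("%s cluster ageing trajectories",
                                  object$pattern$layer)) +
    ggplot2::theme_minimal()
  if (nrow(vertices)) {
    p <- p + ggplot2::geom_point(
      data = tibble::tibble(cluster = vertices$cluster,
                            age = vertices$vertex_age,
                            thickness_um = vertices$peak_um),
      shape = 4, size = 3, stroke = 1.2)
  }
  p
}

#' Plot the ETDRS sector map over the grid
#'
#' @param object A `sector_map` from [etdrs_sector_map()].
#' @param ... Unused.
#' @return A ggplot of the cellwise sector assignment.
#' @method autoplot sector_map
#' @export
autoplot.sector_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$col, y = .data$row,
                                       fill = .data$sector)) +
    ggplot2::geom_tile(colour = "white", linewidth = 0.4) +
    ggplot2::scale_y_reverse(breaks = 1:8) +
    ggplot2::scale_x_continuous(breaks = 1:8) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "column (nasal → temporal)",
                  y = "row (superior → inferior)",
                  title = "ETDRS sector assignment of grid cells") +
    ggplot2::theme_minimal()
}
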