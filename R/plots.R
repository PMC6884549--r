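# ggplot2 views of the result types. Each returns a plot object the caller
# can restyle.

#' @method autoplot lesion_profile
#' @export
autoplot.lesion_profile <- function(object, ...) {
  object |>
    dplyr::mutate(region = factor(.data$region, levels = region_levels())) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$region, y = .data$rel_to_promoter,
                                 group = .data$gene)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene)) +
    ggplot2::labs(x = NULL, y = "AAG substrates relative to promoter",
                  title = "Region-specific lesion profile")
}

#' @method autoplot occupancy_profile
#' @export
autoplot.occupancy_profile <- function(object, ...) {
  object |>
    dplyr::mutate(region = factor(.data$region, levels = region_levels())) |>
    ggplot2::ggplot(ggplot2::aes(x = .data$region,
                                 y = .data$relative_occupancy,
                                 group = .data$gene)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::facet_wrap(ggplot2::vars(.data$gene)) +
    ggplot2::labs(x = NULL, y = "Occupancy relative to promoter",
                  title = "ChIP-qPCR occupancy profile")
}

#' @method autoplot fmhcr_result
#' @export
autoplot.fmhcr_result <- function(object, ...) {
  ggplot2::ggplot(object$by_condition,
                  ggplot2::aes(x = .data$condition,
                               y = .data$mean_percent_re)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_percent_re - .data$sem,
                   ymax = .data$mean_percent_re + .data$sem),
      width = 0.2, na.rm = TRUE) +
    ggplot2::geom_point(data = object$per_replicate,
                        ggplot2::aes(y = .data$percent_re), alpha = 0.6) +
    ggplot2::labs(x = NULL, y = "% reporter expression",
                  title = "FM-HCR repair capacity (mean ± SEM)")
}

#' @method autoplot coregulation
#' @export
autoplot.coregulation <- function(object, ...) {
  ggplot2::ggplot(object$quadrant_counts,
                  ggplot2::aes(x = .data$quadrant, y = .data$n)) +
    ggplot2::geom_col(fill = "grey35") +
    ggplot2::labs(x = "direction in A _ direction in B", y = "genes",
                  title = sprintf("Direction quadrants of %d co-regulated genes",
                                  object$venn$n_overlap))
}

#' @method autoplot comet_summary
#' @export
autoplot.comet_summary <- function(object, ...) {
  ggplot2::ggplot(object$groups,
                  ggplot2::aes(x = .data$condition,
                               y = .data$mean_percent_tail,
                               fill = .data$enzyme)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(width = 0.8),
                      width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean_percent_tail - .data$sem_cells,
                   ymax = .data$mean_percent_tail + .data$sem_cells),
      position = ggplot2::position_dodge(width = 0.8), width = 0.2,
      na.rm = TRUE) +
    ggplot2::scale_fill_grey(start = 0.6, end = 0.2) +
    ggplot2::labs(x = NULL, y = "% tail DNA",
                  title = "Comet-FLARE group means (± SEM across cells)")
}
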