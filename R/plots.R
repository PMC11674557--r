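#' Plot a processed force-indentation cycle
#'
#' Approach and retract branches in force versus indentation depth after
#' baseline correction and contact-point alignment; the shaded gap between
#' the branches is the dissipated energy.
#'
#' @param object An `fd_processed` curve.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot fd_processed
#' @export
autoplot.fd_processed <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(object$approach, segment = "approach"),
    dplyr::mutate(object$retract, segment = "retract")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$indentation * 1e9,
                                   y = .data$force * 1e12,
                                   colour = .data$segment)) +
    ggplot2::geom_line() +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::labs(x = "indentation (nm)", y = "force (pN)",
                  title = object$metadata$curve_id) +
    ggplot2::theme_minimal()
}

#' Forest plot of marker AUCs
#'
#' AUC with DeLong confidence intervals per marker, against the 0.5 line of
#' a random classifier.
#'
#' @param object A `marker_summary` from [summarize_cohort()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot marker_summary
#' @export
autoplot.marker_summary <- function(object, ...) {
  df <- dplyr::filter(as_tibble(object), !is.na(.data$auc))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$auc,
                                   y = stats::reorder(.data$variable, .data$auc))) +
    ggplot2::geom_vline(xintercept = 0.5, linetype = "dashed") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$auc_ci_low,
                                         xmax = .data$auc_ci_high),
                            height = 0.2) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "AUC (DeLong 95% CI)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Height map of a classified cell
#'
#' Tile map of contact height above the substrate plane with the cell mask
#' outlined.
#'
#' @param pixels Classified pixel tibble from [classify_pixels()].
#' @return A ggplot object.
#' @export
plot_cell_map <- function(pixels) {
  stopifnot(all(c("row", "col", "height_above_plane", "is_cell") %in%
                  names(pixels)))
  ggplot2::ggplot(pixels, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$height_above_plane * 1e6)) +
    ggplot2::geom_point(data = dplyr::filter(pixels, .data$is_cell),
                        shape = 3, size = 1) +
    ggplot2::scale_fill_viridis_c(name = "height (um)") +
    ggplot2::coord_equal() +
    ggplot2::labs(title = "contact-height topography (+ = cell mask)") +
    ggplot2::theme_minimal()
}
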