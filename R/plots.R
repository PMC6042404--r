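#' Plot a length-normalized meta-profile
#'
#' @param object A [scaled_region_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.meta_profile <- function(object, ...) {
  n_fl <- sum(object$segment == "upstream")
  body <- which(object$segment == "body")
  ggplot2::ggplot(object, ggplot2::aes(x = .data$bin, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = c(min(body), max(body)),
                        linetype = "dashed", color = "grey50") +
    ggplot2::scale_x_continuous(
      breaks = c(1, min(body), max(body), nrow(object)),
      labels = c(sprintf("-%g kb", attr(object, "flank") / 1000), "start",
                 "end", sprintf("+%g kb", attr(object, "flank") / 1000))) +
    ggplot2::labs(x = NULL, y = "mean occupancy",
                  title = sprintf("Meta-profile over %d regions",
                                  attr(object, "n_regions"))) +
    ggplot2::theme_minimal()
}

#' Plot CpG-density-stratified binding
#'
#' @param object A [density_profile()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$density,
                                       y = .data$enrichment,
                                       color = .data$track)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "CpG density (per 100 bp)",
                  y = "relative enrichment", color = NULL) +
    ggplot2::theme_minimal()
}

#' Plot cluster mean expression trajectories
#'
#' @param object A [deg_clusters()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.deg_clusters <- function(object, ...) {
  df <- tidy(object) |>
    tidyr::pivot_longer(dplyr::all_of(object$conditions),
                        names_to = "condition", values_to = "z") |>
    dplyr::mutate(condition = factor(.data$condition,
                                     levels = object$conditions))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$condition, y = .data$z,
                                   group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "standardized log2 expression") +
    ggplot2::theme_minimal()
}

#' Plot per-group mean TSS occupancy profiles
#'
#' @param object A [group_summaries()] result containing `profiles`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.group_summary <- function(object, ...) {
  if (is.null(object$profiles)) {
    abort("group_summary has no profiles; supply `tss_matrices`")
  }
  ggplot2::ggplot(object$profiles,
                  ggplot2::aes(x = .data$bin, y = .data$value,
                               color = .data$group)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~track, scales = "free_y") +
    ggplot2::labs(x = "bin (upstream → downstream)",
                  y = "mean occupancy", color = NULL) +
    ggplot2::theme_minimal()
}
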