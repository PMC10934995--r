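#' Plot an elbow curve with the chosen point
#'
#' Works for both selection problems that use the maximum-curvature rule:
#' DEG count versus fold-change threshold, and within-cluster sum of
#' squares versus k.
#'
#' @param x An `elbow_curve` (from [elbow_threshold()]) or
#'   `kmeans_profile` (from [kmeans_elbow()]).
#' @return A ggplot object.
#' @export
plot_elbow <- function(x) {
  if (inherits(x, "elbow_curve")) {
    ggplot2::ggplot(x$curves,
                    ggplot2::aes(x = .data$tau, y = .data$n_deg,
                                 colour = .data$treatment)) +
      ggplot2::geom_line() +
      ggplot2::geom_vline(xintercept = x$threshold, linetype = "dashed") +
      ggplot2::labs(x = "log2 fold-change threshold", y = "DEGs",
                    title = sprintf("median elbow at %.3f", x$threshold)) +
      ggplot2::theme_minimal()
  } else if (inherits(x, "kmeans_profile")) {
    ggplot2::ggplot(x$tss_curve,
                    ggplot2::aes(x = .data$k, y = .data$tot_withinss)) +
      ggplot2::geom_line() +
      ggplot2::geom_point() +
      ggplot2::geom_vline(xintercept = x$k, linetype = "dashed") +
      ggplot2::labs(x = "k", y = "total within-cluster SS",
                    title = sprintf("elbow at k = %d", x$k)) +
      ggplot2::theme_minimal()
  } else {
    stop("plot_elbow() expects an elbow_curve or kmeans_profile",
         call. = FALSE)
  }
}

#' @method autoplot density_fit
#' @export
autoplot.density_fit <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, colour = "red") +
    ggplot2::labs(
      x = if (object$log10_density) "log10 bacterial density" else "density",
      y = "response") +
    ggplot2::theme_minimal()
}

#' @method autoplot enrichment_table
#' @export
autoplot.enrichment_table <- function(object, ...) {
  long <- object |>
    dplyr::select("state", "p_set", "p_genome", "significant") |>
    tidyr::pivot_longer(c("p_set", "p_genome"), names_to = "group",
                        values_to = "proportion") |>
    dplyr::mutate(group = ifelse(.data$group == "p_set", "gene set",
                                 "genome"))
  stars <- object |> dplyr::filter(.data$significant)
  ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$proportion,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(data = stars,
                       ggplot2::aes(x = .data$state,
                                    y = pmax(.data$p_set, .data$p_genome),
                                    label = "*"),
                       inherit.aes = FALSE, vjust = -0.2, size = 6) +
    ggplot2::labs(x = "chromatin state", y = "proportion of genes") +
    ggplot2::theme_minimal()
}

#' Plot per-cluster mean expression profiles
#'
#' @param clusters A `kmeans_profile`.
#' @param profiles The centered profile tibble it was fitted on.
#' @return A ggplot object.
#' @export
plot_cluster_profiles <- function(clusters, profiles) {
  long <- profiles |>
    tidyr::pivot_longer(-"gene_id", names_to = "sample_id",
                        values_to = "value") |>
    dplyr::left_join(clusters$clusters, by = "gene_id") |>
    dplyr::group_by(.data$cluster, .data$sample_id) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$sample_id, y = .data$value,
                                     group = .data$cluster)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "centered moderated log2 cpm") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Simple UpSet-style bar chart of membership signatures
#'
#' @param upset Tibble from [upset_counts()].
#' @return A ggplot object.
#' @export
plot_upset <- function(upset) {
  long <- upset |>
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "count") |>
    dplyr::mutate(direction = ifelse(.data$direction == "n_up", "up", "down"))
  ggplot2::ggplot(long,
                  ggplot2::aes(x = stats::reorder(.data$signature, -.data$count),
                               y = .data$count, fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "set membership", y = "DEGs") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
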