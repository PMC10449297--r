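#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Silhouette profile and cluster embedding plots
#'
#' `autoplot()` on a `cluster_model` draws the 2-D principal-component
#' embedding coloured by cluster; [plot_silhouette()] draws the average
#' silhouette width against the candidate cluster number with the selected
#' `k` marked.
#'
#' @param object A `cluster_model`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.cluster_model <- function(object, ...) {
  ggplot2::ggplot(object$embedding,
                  ggplot2::aes(.data$PC1, .data$PC2,
                               colour = factor(.data$cluster))) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(colour = "cluster",
                  title = sprintf("BMMC clusters (k = %d)", object$k_selected)) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.cluster_model
#' @param model A `cluster_model`.
#' @export
plot_silhouette <- function(model) {
  stopifnot(inherits(model, "cluster_model"))
  ggplot2::ggplot(model$silhouette,
                  ggplot2::aes(.data$k, .data$avg_silhouette)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = model$k_selected, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = model$silhouette$k) +
    ggplot2::labs(x = "number of clusters", y = "average silhouette width") +
    ggplot2::theme_minimal()
}

#' Contribution bars for a metastasis report
#'
#' Shows the fraction of CPCs attributed to the FAM46C-low and -high BMMC
#' groups.
#'
#' @param object A `metastasis_report`.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.metastasis_report <- function(object, ...) {
  ggplot2::ggplot(object$contributions,
                  ggplot2::aes(.data$group, .data$percent, fill = .data$group)) +
    ggplot2::geom_col(width = 0.6) +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       vjust = -0.4) +
    ggplot2::scale_fill_manual(values = c(low = "#D55E00", high = "#0072B2"),
                               guide = "none") +
    ggplot2::labs(x = "FAM46C group",
                  y = "contribution to extramedullary metastasis (%)",
                  title = sprintf("Patient %s (C_p = %d)", object$patient_id,
                                  object$c_p)) +
    ggplot2::theme_minimal()
}
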