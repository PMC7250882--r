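#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Membership-coloured profile plot of a soft clustering
#'
#' One panel per cluster, each gene's standardized profile drawn as a line
#' coloured by its membership in that cluster (high membership = core
#' genes), with the cluster centre overlaid.
#'
#' @param object A `soft_clustering` object.
#' @param x The standardized expression table the fit was computed on.
#' @param min_membership Hide genes below this membership (default 0.3,
#'   keeps panels readable).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot soft_clustering
#' @export
autoplot.soft_clustering <- function(object, x, min_membership = 0.3, ...) {
  vals <- if (is.matrix(x)) x else expression_values(validate_expression(x))
  hard <- assign_clusters(object)
  keep <- hard[hard$membership >= min_membership, ]
  prof <- tibble::as_tibble(vals[keep$gene_id, , drop = FALSE],
                            rownames = "gene_id")
  prof <- tidyr::pivot_longer(prof, -"gene_id",
                              names_to = "condition", values_to = "value")
  prof <- dplyr::left_join(prof, keep, by = "gene_id")
  prof$condition <- factor(prof$condition, levels = colnames(vals))
  centers <- tibble::as_tibble(object$centers, rownames = "cl")
  centers$cluster <- seq_len(nrow(object$centers))
  centers <- tidyr::pivot_longer(centers, c(-"cl", -"cluster"),
                                 names_to = "condition", values_to = "value")
  centers$condition <- factor(centers$condition, levels = colnames(vals))
  ggplot2::ggplot(prof, ggplot2::aes(.data$condition, .data$value)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$gene_id,
                                    colour = .data$membership), alpha = 0.6) +
    ggplot2::geom_line(data = centers,
                       ggplot2::aes(group = .data$cluster),
                       linewidth = 1, colour = "black") +
    ggplot2::scale_colour_gradient(low = "darkgreen", high = "magenta",
                                   limits = c(0, 1)) +
    ggplot2::facet_wrap(~cluster) +
    ggplot2::labs(x = NULL, y = "standardized expression",
                  colour = "membership") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Heatmap of cross-species module overlap significance
#'
#' Tiles coloured by -log10 of the raw upper-tail hypergeometric p-value,
#' annotated with the shared-orthogroup counts.
#'
#' @param object An `overlap_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot overlap_result
#' @export
autoplot.overlap_result <- function(object, ...) {
  d <- tidy(object)
  d$neglog10_p <- -log10(pmax(d$p_raw, 1e-300))
  ggplot2::ggplot(d, ggplot2::aes(factor(.data$module_b),
                                  factor(.data$module_a))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$neglog10_p)) +
    ggplot2::geom_text(ggplot2::aes(label = .data$x), size = 3) +
    ggplot2::scale_fill_gradient(low = "white", high = "firebrick") +
    ggplot2::labs(
      x = paste0(attr(object, "species_b"), " modules"),
      y = paste0(attr(object, "species_a"), " modules"),
      fill = expression(-log[10] ~ p)
    ) +
    ggplot2::theme_minimal()
}

#' Bar chart of second tissues from the shared-tissue filter
#'
#' @param object A `shared_tissue` object.
#' @param ... Unused.
#' @return A ggplot of passing-gene counts per second tissue.
#' @method autoplot shared_tissue
#' @export
autoplot.shared_tissue <- function(object, ...) {
  d <- object$counts
  d$second_condition <- factor(d$second_condition,
                               levels = rev(d$second_condition))
  ggplot2::ggplot(d, ggplot2::aes(.data$n_genes, .data$second_condition)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = paste("genes shared with", object$focal),
      y = "second tissue",
      title = paste0(sum(object$genes$pass), " genes highly expressed in ",
                     object$focal, " plus one other tissue")
    ) +
    ggplot2::theme_minimal()
}

#' Tau distribution plot
#'
#' Histogram of tau over genes, with the specificity threshold marked.
#'
#' @param tau_tbl Result of [tau_table()].
#' @param threshold Threshold line to draw (default 0.8).
#' @return A ggplot.
#' @export
plot_tau <- function(tau_tbl, threshold = 0.8) {
  d <- tau_tbl[!is.na(tau_tbl$tau), ]
  ggplot2::ggplot(d, ggplot2::aes(.data$tau)) +
    ggplot2::geom_histogram(bins = 40, fill = "grey40") +
    ggplot2::geom_vline(xintercept = threshold, colour = "firebrick",
                        linetype = "dashed") +
    ggplot2::labs(x = expression(tau), y = "genes") +
    ggplot2::theme_minimal()
}
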