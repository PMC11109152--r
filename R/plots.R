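#' @import ggplot2
NULL

#' Volcano plot of pseudobulk differential accessibility
#'
#' @param object A `diff_peak_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.diff_peak_result <- function(object, ...) {
  d <- tidy(object)
  d <- d[object$converged & !is.na(d$fdr), ]
  ggplot(d, aes(x = .data$log2fc, y = -log10(pmax(.data$fdr, 1e-300)),
                colour = .data$direction)) +
    geom_point(size = 0.6, alpha = 0.7) +
    scale_colour_manual(values = c(up = "#b2182b", down = "#2166ac",
                                   ns = "grey70")) +
    labs(x = "log2 fold change (KO vs WT)", y = "-log10 FDR",
         colour = NULL) +
    theme_minimal()
}

#' Ranked Functional Perturbation Scores
#'
#' @param object An `fps_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.fps_result <- function(object, ...) {
  d <- tidy(object)
  d$clone <- stats::reorder(d$clone, -d$score)
  p <- ggplot(d, aes(x = .data$clone, y = .data$score)) +
    geom_col(fill = "grey35") +
    geom_hline(yintercept = stats::median(d$score), linetype = "dashed") +
    labs(x = NULL, y = "Functional Perturbation Score") +
    theme_minimal() +
    theme(axis.text.x = element_text(angle = 60, hjust = 1))
  if ("cytokine_group" %in% names(d)) {
    p <- ggplot(d, aes(x = .data$clone, y = .data$score,
                       fill = .data$cytokine_group)) +
      geom_col() +
      geom_hline(yintercept = stats::median(d$score), linetype = "dashed") +
      labs(x = NULL, y = "Functional Perturbation Score", fill = NULL) +
      theme_minimal() +
      theme(axis.text.x = element_text(angle = 60, hjust = 1))
  }
  p
}

#' Sister-sample clone size comparison
#'
#' Scatter of fractional clone abundances in two sister samples with the
#' fitted regression line and the identity diagonal.
#'
#' @param object A `clone_pair_comparison`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.clone_pair_comparison <- function(object, ...) {
  ggplot(object$table, aes(x = .data$frac_a, y = .data$frac_b)) +
    geom_abline(slope = 1, intercept = 0, colour = "grey70",
                linetype = "dotted") +
    geom_abline(slope = object$slope, intercept = object$intercept,
                colour = "#2166ac") +
    geom_point(aes(colour = .data$above_line), size = 1.2) +
    scale_colour_manual(values = c(`TRUE` = "#b2182b", `FALSE` = "grey40")) +
    labs(x = "clone fraction, sample A", y = "clone fraction, sample B",
         colour = "above fit") +
    theme_minimal()
}

#' Neighborhood localization on an embedding
#'
#' @param embedding Cells x dims matrix (first two columns plotted).
#' @param nf Tibble from [neighborhood_fraction()].
#' @return A ggplot.
#' @export
plot_neighborhood <- function(embedding, nf) {
  d <- tibble::tibble(dim1 = embedding[, 1], dim2 = embedding[, 2],
                      fraction = nf$fraction)
  ggplot(d, aes(x = .data$dim1, y = .data$dim2, colour = .data$fraction)) +
    geom_point(size = 0.6) +
    scale_colour_viridis_c(limits = c(0, 1)) +
    labs(colour = "neighborhood\nfraction") +
    theme_minimal()
}
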