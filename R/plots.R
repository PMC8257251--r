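#' @importFrom ggplot2 ggplot aes geom_point geom_col geom_line geom_hline
#'   labs theme_minimal scale_size_area scale_color_gradient2 facet_wrap
#'   autoplot
NULL

#' @export
ggplot2::autoplot

#' Sample PCA plot
#'
#' @param pca a `cafnet_pca` from [pca_project()].
#' @param design optional design tibble to color samples by group.
#' @return a ggplot.
#' @export
plot_pca <- function(pca, design = NULL) {
  stopifnot(inherits(pca, "cafnet_pca"))
  d <- pca$scores
  if (!is.null(design)) d <- left_join(d, design, by = "sample")
  pct <- round(100 * pca$var_frac[1:2], 1)
  p <- ggplot(d, aes(x = .data$PC1, y = .data$PC2))
  p <- if (!is.null(design)) {
    p + geom_point(aes(color = .data$group), size = 3)
  } else {
    p + geom_point(size = 3)
  }
  p + labs(x = paste0("PC1 (", pct[1], "%)"),
           y = paste0("PC2 (", pct[2], "%)")) +
    theme_minimal()
}

#' Bubble heat map of consolidated annotation groups
#'
#' Circle size is the number of member terms; color is the signed mean
#' -log10(q) (negative for groups from downregulated gene lists).
#'
#' @param bubble tibble from [summarize_groups()].
#' @return a ggplot.
#' @export
plot_enrichment_bubbles <- function(bubble) {
  ggplot(bubble, aes(x = .data$comparison, y = .data$group,
                     size = .data$n_terms, color = .data$signed_score)) +
    geom_point() +
    scale_size_area(max_size = 10) +
    scale_color_gradient2(low = "blue", mid = "grey90", high = "red") +
    labs(size = "terms", color = "signed mean -log10(q)") +
    theme_minimal()
}

#' Running-sum plot of a single gene set
#'
#' @param es result of [enrichment_score()].
#' @return a ggplot.
#' @export
plot_running_sum <- function(es) {
  ggplot(es$running, aes(x = .data$rank, y = .data$value)) +
    geom_line() +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = "rank in ordered list", y = "running enrichment score") +
    theme_minimal()
}

#' @describeIn run_gsea NES bar chart of GSEA results.
#' @param object a `gsea_results` tibble.
#' @param ... unused.
#' @export
autoplot.gsea_results <- function(object, ...) {
  d <- as_tibble(object)
  d$term <- factor(d$term, levels = d$term[order(d$nes)])
  ggplot(d, aes(x = .data$nes, y = .data$term, fill = .data$fdr < 0.05)) +
    geom_col() +
    labs(x = "normalized enrichment score", y = NULL, fill = "FDR < 0.05") +
    theme_minimal()
}

#' @describeIn consolidate_ranking Per-parameter Z-score dot plot of the
#'   candidate TFs, faceted by comparison.
#' @param object a `tf_ranking`.
#' @param ... unused.
#' @export
autoplot.tf_ranking <- function(object, ...) {
  ggplot(object$z_scores,
         aes(x = .data$tf, y = .data$z, color = .data$parameter)) +
    geom_point(position = ggplot2::position_jitter(width = 0.1, height = 0,
                                                   seed = 1)) +
    facet_wrap(~comparison) +
    geom_hline(yintercept = 0, linetype = "dashed") +
    labs(x = NULL, y = "parameter Z-score") +
    theme_minimal()
}
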