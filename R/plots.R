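#' Plot a signature graph
#'
#' Force-directed layout of the retained graph; nodes colored by disease,
#' shaped by disease class, edges weighted by Jaccard similarity.
#'
#' @param object A `sig_graph`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sig_graph <- function(object, ...) {
  g <- as_igraph(object)
  lay <- igraph::layout_with_fr(g)
  nd <- object$nodes
  nodes <- tibble::tibble(
    signature_id = igraph::V(g)$name,
    x = lay[, 1], y = lay[, 2]
  )
  nodes <- dplyr::left_join(nodes, nd, by = "signature_id")
  e <- object$edges
  seg <- tibble::tibble(
    x = nodes$x[match(e$node_a, nodes$signature_id)],
    y = nodes$y[match(e$node_a, nodes$signature_id)],
    xend = nodes$x[match(e$node_b, nodes$signature_id)],
    yend = nodes$y[match(e$node_b, nodes$signature_id)],
    jaccard = e$jaccard
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend,
                   yend = .data$yend, linewidth = .data$jaccard),
      color = "grey60"
    ) +
    ggplot2::geom_point(
      data = nodes,
      ggplot2::aes(x = .data$x, y = .data$y, color = .data$disease,
                   shape = .data$disease_class),
      size = 3
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.5)) +
    ggplot2::theme_void() +
    ggplot2::labs(color = "disease", shape = "class", linewidth = "Jaccard")
}

#' Plot edge-category counts
#'
#' Bar chart of retained edges per category, split by tissue relation — the
#' descriptive summary of how often signatures pair within one disease,
#' within a disease class, across classes, or among somatic diseases.
#'
#' @param graph A categorized `sig_graph` (see [categorize_edges()]).
#' @return A ggplot object.
#' @export
plot_edge_categories <- function(graph) {
  stopifnot(inherits(graph, "sig_graph"))
  if (is.null(graph$category_summary)) graph <- categorize_edges(graph)
  ggplot2::ggplot(graph$category_summary,
                  ggplot2::aes(x = .data$n_edges, y = .data$category,
                               fill = .data$tissue_relation)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "signature pairs", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' Exposure scatter plot of ranked genes
#'
#' One point per gene: exposure in the disease-A signature against exposure
#' in the disease-B signature, sized by the geometric mean that ranks them
#' and optionally colored by a category or GWAS label column.
#'
#' @param object A `ranked_genes` tibble from [rank_genes_for_term()],
#'   optionally carrying a `category` or `gwas_label` column to color by.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.ranked_genes <- function(object, ...) {
  color_col <- intersect(c("gwas_label", "category"), names(object))[1]
  p <- ggplot2::ggplot(object,
                       ggplot2::aes(x = .data$exposure_a, y = .data$exposure_b)) +
    ggplot2::geom_point(ggplot2::aes(
      size = .data$geometric_mean,
      color = if (!is.na(color_col)) .data[[color_col]] else NULL)) +
    ggplot2::labs(x = "exposure (disease A signature)",
                  y = "exposure (disease B signature)",
                  size = "geometric mean", color = color_col) +
    ggplot2::theme_minimal()
  p
}

#' Dot plot of an enrichment table
#'
#' @param object An `enrichment_tbl` from [hypergeometric_enrich()].
#' @param max_terms Show at most this many terms (by raw p; default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment_tbl <- function(object, max_terms = 20L, ...) {
  tab <- utils::head(dplyr::arrange(object, .data$raw_p), max_terms)
  tab$term <- factor(tab$term, levels = rev(tab$term))
  ggplot2::ggplot(tab, ggplot2::aes(x = -log10(.data$adjusted_p),
                                    y = .data$term,
                                    size = .data$overlap_size,
                                    color = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = expression(-log[10] ~ "adjusted p"), y = NULL,
                  size = "overlap") +
    ggplot2::theme_minimal()
}

#' Reconstruction-loss curve over ranks
#'
#' @param object A `sig_set` from [mrnmf()].
#' @param ... Unused.
#' @return A ggplot object of Frobenius loss against factorization rank.
#' @export
autoplot.sig_set <- function(object, ...) {
  ggplot2::ggplot(object$losses, ggplot2::aes(x = .data$rank, y = .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "factorization rank k", y = "squared Frobenius loss") +
    ggplot2::theme_minimal()
}
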