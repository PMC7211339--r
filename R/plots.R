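#' @importFrom ggplot2 autoplot ggplot aes geom_col labs theme_minimal
#' @export
ggplot2::autoplot

#' Betweenness-centrality distribution
#'
#' Bar chart of the binned betweenness values (the classic
#' "most nodes sit between 0 and 0.1" view of enrichment networks).
#'
#' @param report A `topology_report`.
#' @return A ggplot object.
#' @export
plot_bc_distribution <- function(report) {
  h <- report$bc_histogram
  h$bin <- sprintf("[%.2g, %.2g%s", h$bin_lo, h$bin_hi,
                   ifelse(seq_len(nrow(h)) == nrow(h), "]", ")"))
  h$bin <- factor(h$bin, levels = h$bin)
  ggplot(h, aes(x = .data$bin, y = .data$count)) +
    geom_col(fill = "steelblue") +
    labs(x = "betweenness centrality", y = "number of nodes") +
    theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Node-degree distribution
#'
#' @param report A `topology_report`.
#' @return A ggplot object.
#' @export
plot_degree_distribution <- function(report) {
  ggplot(report$degree_histogram,
         aes(x = .data$degree, y = .data$count)) +
    geom_col(fill = "grey40") +
    labs(x = "degree", y = "number of nodes") +
    theme_minimal()
}

#' @rdname plot_bc_distribution
#' @param object A `topology_report`.
#' @param which `"betweenness"` or `"degree"`.
#' @param ... Unused.
#' @method autoplot topology_report
#' @export
autoplot.topology_report <- function(object,
                                     which = c("betweenness", "degree"),
                                     ...) {
  which <- match.arg(which)
  if (which == "betweenness") plot_bc_distribution(object)
  else plot_degree_distribution(object)
}

#' Enrichment overview plot
#'
#' Top categories by FDR, shown as -log10(FDR) bars colored by category
#' type; the significance threshold is drawn as a dashed line.
#'
#' @param object An `ora_result`.
#' @param n_top Number of categories to show (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ora_result
#' @export
autoplot.ora_result <- function(object, n_top = 20L, ...) {
  df <- as_tibble(as.data.frame(
    object[c("category_id", "name", "category_type", "fdr")]))
  df <- df[order(df$fdr, df$category_id), ]
  df <- head(df, n_top)
  df$label <- factor(df$name, levels = rev(unique(df$name)))
  thr <- attr(object, "fdr_threshold") %||% 0.05
  ggplot(df, aes(x = -log10(pmax(.data$fdr, 1e-300)), y = .data$label,
                 fill = .data$category_type)) +
    geom_col() +
    ggplot2::geom_vline(xintercept = -log10(thr), linetype = "dashed") +
    labs(x = "-log10(FDR)", y = NULL, fill = "category type") +
    theme_minimal()
}
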