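#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' Tidy enrichment results
#'
#' Flattens the `overlap_genes` list-column to a comma-joined string so
#' the result is a plain rectangular tibble.
#'
#' @param x An `ora_result`.
#' @param ... Unused.
#' @return A tibble, one row per tested category.
#' @method tidy ora_result
#' @export
tidy.ora_result <- function(x, ...) {
  out <- as_tibble(as.data.frame(x[setdiff(names(x), "overlap_genes")]))
  out$overlap_genes <- vapply(x$overlap_genes,
                              function(g) paste(sort(g), collapse = ","), "")
  out
}

#' Summarise an enrichment run in one row
#'
#' @param x An `ora_result`.
#' @param ... Unused.
#' @return A one-row tibble: categories tested, significant count,
#'   threshold, query and background sizes.
#' @method glance ora_result
#' @export
glance.ora_result <- function(x, ...) {
  tibble(
    n_categories = nrow(x),
    n_significant = sum(x$significant),
    fdr_threshold = attr(x, "fdr_threshold") %||% NA_real_,
    n_query = if (nrow(x)) x$n[[1]] else NA_integer_,
    n_background = if (nrow(x)) x$N[[1]] else NA_integer_,
    min_p = if (nrow(x)) min(x$p_value) else NA_real_
  )
}

#' Tidy a heterogeneous network
#'
#' @param x A [hetero_network()].
#' @param ... Unused.
#' @return The node tibble with a `degree` column.
#' @method tidy hetero_network
#' @export
tidy.hetero_network <- function(x, ...) {
  deg <- lengths(network_adjacency(x))
  out <- x$nodes
  out$degree <- as.integer(deg)
  out
}

#' One-row summary of a heterogeneous network
#'
#' @param x A [hetero_network()].
#' @param ... Unused.
#' @return A one-row tibble with node/edge counts overall and per node
#'   type.
#' @method glance hetero_network
#' @export
glance.hetero_network <- function(x, ...) {
  tc <- table(factor(x$nodes$node_type, levels = NODE_TYPES))
  out <- tibble(n_nodes = nrow(x$nodes), n_edges = nrow(x$edges))
  for (tp in NODE_TYPES) out[[paste0("n_", tp)]] <- as.integer(tc[[tp]])
  out
}

#' Tidy a topology report
#'
#' @param x A `topology_report`.
#' @param ... Unused.
#' @return The per-node tibble (id, node_type, degree, betweenness,
#'   closeness).
#' @method tidy topology_report
#' @export
tidy.topology_report <- function(x, ...) x$per_node

#' One-row summary of a topology report
#'
#' @param x A `topology_report`.
#' @param ... Unused.
#' @return A one-row tibble: node, edge, and component counts plus the
#'   maximum betweenness.
#' @method glance topology_report
#' @export
glance.topology_report <- function(x, ...) {
  tibble(
    n_nodes = x$n_nodes, n_edges = x$n_edges,
    n_components = x$n_components,
    max_betweenness = if (nrow(x$per_node)) max(x$per_node$betweenness)
    else NA_real_
  )
}
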