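#' Construct a heterogeneous gene-annotation network
#'
#' Low-level constructor; most users should call [build_network()].
#' Nodes are typed (gene or one of the category types) and edges connect
#' a gene to a category it belongs to (bipartite across the
#' gene/category divide), with no self-loops or parallel edges.
#'
#' @param nodes Tibble with columns `id`, `display_name`, `node_type`,
#'   `fdr` (`NA` for genes).
#' @param edges Tibble with columns `gene` and `category_id`.
#' @return A `hetero_network` object (list of `nodes` and `edges`
#'   tibbles).
#' @export
hetero_network <- function(nodes, edges) {
  nodes <- as_tibble(as.data.frame(nodes))[
    c("id", "display_name", "node_type", "fdr")]
  edges <- as_tibble(as.data.frame(edges))[c("gene", "category_id")]
  nodes$id <- as.character(nodes$id)
  nodes$display_name <- as.character(nodes$display_name)
  nodes$node_type <- as.character(nodes$node_type)
  nodes$fdr <- as.numeric(nodes$fdr)
  edges$gene <- as.character(edges$gene)
  edges$category_id <- as.character(edges$category_id)
  if (anyDuplicated(nodes$id)) {
    abort("node ids must be unique network-wide")
  }
  if (!all(nodes$node_type %in% NODE_TYPES)) {
    abort(paste0("node_type must be one of: ",
                 paste(NODE_TYPES, collapse = ", ")))
  }
  is_gene <- nodes$node_type == "gene"
  if (any(is_gene & !is.na(nodes$fdr)) || any(!is_gene & is.na(nodes$fdr))) {
    abort("`fdr` must be NA exactly for gene nodes")
  }
  gene_ids <- nodes$id[is_gene]
  cat_ids <- nodes$id[!is_gene]
  if (nrow(edges)) {
    if (!all(edges$gene %in% gene_ids)) {
      abort("edge endpoint not a gene node (network must be bipartite)")
    }
    if (!all(edges$category_id %in% cat_ids)) {
      abort("edge endpoint not a category node (network must be bipartite)")
    }
    if (anyDuplicated(edges[c("gene", "category_id")])) {
      abort("parallel edges are not allowed")
    }
  }
  deg0 <- setdiff(cat_ids, edges$category_id)
  if (length(deg0)) {
    abort(sprintf("category node '%s' has degree 0", deg0[[1]]))
  }
  structure(list(nodes = nodes, edges = edges), class = "hetero_network")
}

#' @export
print.hetero_network <- function(x, ...) {
  cat("# Heterogeneous gene-annotation network\n")
  tc <- table(factor(x$nodes$node_type, levels = NODE_TYPES))
  cat(sprintf("#   %d nodes (%s), %d edges\n", nrow(x$nodes),
              paste(sprintf("%s: %d", names(tc), as.integer(tc)),
                    collapse = ", "),
              nrow(x$edges)))
  invisible(x)
}

#' Assemble the enrichment network
#'
#' Builds the undirected heterogeneous network from a query gene list
#' and ORA results: one node per significant category, one node per
#' query gene that overlaps at least one significant category (or every
#' query gene, if `include_isolated_genes`), and an edge `(g, c)` for
#' every gene `g` in the overlap of a significant category `c`. Node
#' order is deterministic: genes sorted by symbol, then categories by
#' type then id.
#'
#' @param query The query [gene_list()] the ORA was run on.
#' @param results An `ora_result` tibble (one or several collections,
#'   e.g. from [run_ora_collections()]).
#' @param include_isolated_genes Keep query genes with no significant
#'   membership as isolated nodes? Default `FALSE`: the network shows
#'   only annotated structure.
#' @return A [hetero_network()].
#' @export
build_network <- function(query, results, include_isolated_genes = FALSE) {
  q <- as_gene_vector(query, "query")
  stopifnot(is.data.frame(results))
  sig <- results[results$significant, , drop = FALSE]
  if (!nrow(sig)) {
    warn("build_network: no significant categories; network has no edges")
  }
  edges <- if (nrow(sig)) {
    tibble(
      gene = unlist(sig$overlap_genes),
      category_id = rep(sig$category_id, lengths(sig$overlap_genes))
    )
  } else {
    tibble(gene = character(0), category_id = character(0))
  }
  gene_ids <- if (include_isolated_genes) {
    sort(unique(c(q, edges$gene)))
  } else {
    sort(unique(edges$gene))
  }
  gene_nodes <- tibble(id = gene_ids, display_name = gene_ids,
                       node_type = "gene", fdr = NA_real_)
  cat_nodes <- tibble(id = sig$category_id, display_name = sig$name,
                      node_type = sig$category_type, fdr = sig$fdr)
  cat_nodes <- cat_nodes[order(match(cat_nodes$node_type, NODE_TYPES),
                               cat_nodes$id), ]
  edges <- edges[order(edges$gene, edges$category_id), ]
  hetero_network(bind_rows(gene_nodes, cat_nodes), edges)
}

#' Convert a heterogeneous network to an igraph graph
#'
#' Vertex attributes `node_type`, `display_name`, and `fdr` are carried
#' over; vertex names are node ids.
#'
#' @param net A [hetero_network()].
#' @return An undirected `igraph` graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  g <- igraph::make_empty_graph(n = nrow(net$nodes), directed = FALSE)
  g <- igraph::set_vertex_attr(g, "name", value = net$nodes$id)
  g <- igraph::set_vertex_attr(g, "display_name",
                               value = net$nodes$display_name)
  g <- igraph::set_vertex_attr(g, "node_type", value = net$nodes$node_type)
  g <- igraph::set_vertex_attr(g, "fdr", value = net$nodes$fdr)
  if (nrow(net$edges)) {
    idx <- rbind(match(net$edges$gene, net$nodes$id),
                 match(net$edges$category_id, net$nodes$id))
    g <- igraph::add_edges(g, as.vector(idx))
  }
  g
}

#' Write a network as SIF (simple interaction format)
#'
#' One line per edge, `gene<TAB>member_of<TAB>category_id`, sorted;
#' Cytoscape-readable. Isolated nodes are not representable in SIF and
#' are omitted.
#'
#' @param net A [hetero_network()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sif <- function(net, path) {
  stopifnot(inherits(net, "hetero_network"))
  e <- net$edges[order(net$edges$gene, net$edges$category_id), ]
  lines <- if (nrow(e)) {
    paste(e$gene, "member_of", e$category_id, sep = "\t")
  } else character(0)
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' Write a network as GraphML
#'
#' Node attributes `node_type`, `display_name`, `fdr`, and (optionally)
#' computed centralities travel with the graph, so the file opens in
#' Cytoscape with everything needed for styling. [read_graphml()]
#' reproduces the network.
#'
#' @param net A [hetero_network()].
#' @param path Output path.
#' @param topology Optional `topology_report` (from
#'   [topology_report()]); its per-node `betweenness`, `closeness`, and
#'   `degree` are attached as node attributes.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(net, path, topology = NULL) {
  g <- as_igraph(net)
  if (!is.null(topology)) {
    pn <- topology$per_node
    i <- match(igraph::V(g)$name, pn$id)
    g <- igraph::set_vertex_attr(g, "betweenness", value = pn$betweenness[i])
    g <- igraph::set_vertex_attr(g, "closeness", value = pn$closeness[i])
    g <- igraph::set_vertex_attr(g, "degree",
                                 value = as.numeric(pn$degree[i]))
  }
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Read a GraphML network back
#'
#' Inverse of [write_graphml()]: reconstructs the `hetero_network`
#' (nodes in the stored order, edges as gene-category pairs). `fdr`
#' values written as missing come back as NaN in GraphML and are mapped
#' back to `NA`.
#'
#' @param path Path to a GraphML file produced by [write_graphml()].
#' @return A [hetero_network()].
#' @export
read_graphml <- function(path) {
  g <- igraph::read_graph(path, format = "graphml")
  fdr <- igraph::vertex_attr(g, "fdr")
  if (is.null(fdr)) fdr <- rep(NA_real_, igraph::vcount(g))
  fdr[!is.finite(fdr)] <- NA_real_
  nodes <- tibble(
    id = igraph::V(g)$name,
    display_name = igraph::vertex_attr(g, "display_name") %||%
      igraph::V(g)$name,
    node_type = igraph::vertex_attr(g, "node_type"),
    fdr = fdr
  )
  el <- igraph::as_edgelist(g, names = TRUE)
  is_gene <- nodes$node_type[match(el[, 1], nodes$id)] == "gene"
  edges <- tibble(
    gene = ifelse(is_gene, el[, 1], el[, 2]),
    category_id = ifelse(is_gene, el[, 2], el[, 1])
  )
  edges <- edges[order(edges$gene, edges$category_id), ]
  hetero_network(nodes, edges)
}

#' Node attribute table in published-table layout
#'
#' One row per node of the requested type(s), ranked by betweenness
#' centrality: `rank`, `display_name`, `id`, `node_type`, `betweenness`,
#' `fdr`. This mirrors how enrichment-network studies tabulate their
#' central genes and categories.
#'
#' @param net A [hetero_network()].
#' @param topology A `topology_report` for `net`.
#' @param node_type Optional filter (e.g. `"gene"`); `NULL` keeps all
#'   nodes.
#' @return A tibble, descending by betweenness (ties by id).
#' @export
node_table <- function(net, topology, node_type = NULL) {
  pn <- topology$per_node
  df <- left_join(net$nodes, pn[c("id", "betweenness", "closeness",
                                  "degree")], by = "id")
  if (!is.null(node_type)) {
    stopifnot(all(node_type %in% NODE_TYPES))
    df <- df[df$node_type %in% node_type, , drop = FALSE]
  }
  df <- df[order(-df$betweenness, df$id), ]
  df$rank <- seq_len(nrow(df))
  as_tibble(df[c("rank", "display_name", "id", "node_type",
                 "betweenness", "closeness", "degree", "fdr")])
}
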