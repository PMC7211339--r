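# Adjacency list (integer indices) for a hetero_network; nodes keep
# their order in net$nodes.
network_adjacency <- function(net) {
  stopifnot(inherits(net, "hetero_network"))
  n <- nrow(net$nodes)
  adj <- vector("list", n)
  for (i in seq_len(n)) adj[[i]] <- integer(0)
  if (nrow(net$edges)) {
    a <- match(net$edges$gene, net$nodes$id)
    b <- match(net$edges$category_id, net$nodes$id)
    for (j in seq_along(a)) {
      adj[[a[j]]] <- c(adj[[a[j]]], b[j])
      adj[[b[j]]] <- c(adj[[b[j]]], a[j])
    }
  }
  adj
}

bfs_distances <- function(adj, s) {
  n <- length(adj)
  dist <- rep(NA_integer_, n)
  dist[s] <- 0L
  queue <- s
  while (length(queue)) {
    v <- queue[[1]]
    queue <- queue[-1]
    for (w in adj[[v]]) {
      if (is.na(dist[w])) {
        dist[w] <- dist[v] + 1L
        queue <- c(queue, w)
      }
    }
  }
  dist
}

#' Betweenness centrality of every node
#'
#' Brandes' accumulation over unweighted shortest paths: for each node
#' `v`, the fraction of all-pairs geodesics passing through `v`
#' (endpoints excluded), normalized by `(n-1)(n-2)/2` over the whole
#' graph so values lie in `[0, 1]`. Node pairs in different components
#' contribute nothing. Networks with fewer than 3 nodes have all-zero
#' betweenness.
#'
#' @param net A [hetero_network()].
#' @return Named numeric vector, one value per node in node order.
#' @export
betweenness_centrality <- function(net) {
  adj <- network_adjacency(net)
  n <- length(adj)
  bc <- numeric(n)
  if (n >= 3L) {
    for (s in seq_len(n)) {
      # single-source shortest-path counts
      sigma <- numeric(n); sigma[s] <- 1
      dist <- rep(-1L, n); dist[s] <- 0L
      preds <- vector("list", n)
      order_visited <- integer(0)
      queue <- s
      while (length(queue)) {
        v <- queue[[1]]
        queue <- queue[-1]
        order_visited <- c(order_visited, v)
        for (w in adj[[v]]) {
          if (dist[w] < 0L) {
            dist[w] <- dist[v] + 1L
            queue <- c(queue, w)
          }
          if (dist[w] == dist[v] + 1L) {
            sigma[w] <- sigma[w] + sigma[v]
            preds[[w]] <- c(preds[[w]], v)
          }
        }
      }
      # dependency accumulation in reverse BFS order
      delta <- numeric(n)
      for (w in rev(order_visited)) {
        for (v in preds[[w]]) {
          delta[v] <- delta[v] + sigma[v] / sigma[w] * (1 + delta[w])
        }
        if (w != s) bc[w] <- bc[w] + delta[w]
      }
    }
    # each unordered (s,t) pair was accumulated from both endpoints
    bc <- bc / ((n - 1) * (n - 2))
  }
  names(bc) <- net$nodes$id
  bc
}

#' Closeness centrality of every node
#'
#' Reachable-set corrected closeness, well-defined on disconnected
#' graphs: with `r` nodes reachable from `v` at total geodesic distance
#' `D`, `closeness(v) = (r / D) * (r / (n - 1))`. Isolated nodes score
#' 0; values lie in `[0, 1]`.
#'
#' @param net A [hetero_network()].
#' @return Named numeric vector, one value per node in node order.
#' @export
closeness_centrality <- function(net) {
  adj <- network_adjacency(net)
  n <- length(adj)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    d <- bfs_distances(adj, v)
    d <- d[-v][!is.na(d[-v])]
    if (length(d) && n > 1L) {
      cc[v] <- (length(d) / sum(d)) * (length(d) / (n - 1))
    }
  }
  names(cc) <- net$nodes$id
  cc
}

#' Connected-component labels
#'
#' BFS labeling; labels are 1-based in order of first appearance.
#'
#' @param net A [hetero_network()].
#' @return Named integer vector of component labels per node.
#' @export
component_labels <- function(net) {
  adj <- network_adjacency(net)
  n <- length(adj)
  lab <- rep(NA_integer_, n)
  comp <- 0L
  for (v in seq_len(n)) {
    if (is.na(lab[v])) {
      comp <- comp + 1L
      reach <- !is.na(bfs_distances(adj, v))
      lab[reach & is.na(lab)] <- comp
    }
  }
  names(lab) <- net$nodes$id
  lab
}

#' Histogram of betweenness values
#'
#' Half-open bins `[a, a + w)` of width `bin_width` on `[0, 1]`, with
#' the final bin closed at 1, so every node falls in exactly one bin.
#'
#' @param bc Numeric vector of betweenness values in `[0, 1]`.
#' @param bin_width Bin width in `(0, 1]` (default 0.1).
#' @return Tibble with `bin_lo`, `bin_hi`, `count`.
#' @export
bc_histogram <- function(bc, bin_width = 0.1) {
  if (!(is.numeric(bin_width) && length(bin_width) == 1L &&
        bin_width > 0 && bin_width <= 1)) {
    abort("`bin_width` must be in (0, 1]")
  }
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  idx <- findInterval(bc, breaks, rightmost.closed = TRUE)
  tibble(
    bin_lo = breaks[-length(breaks)],
    bin_hi = breaks[-1],
    count = as.integer(tabulate(idx, nbins = length(breaks) - 1L))
  )
}

#' Histogram of node degrees
#'
#' Counts for every degree from 0 to the observed maximum.
#'
#' @param degree Integer vector of node degrees.
#' @return Tibble with `degree`, `count`.
#' @export
degree_histogram <- function(degree) {
  if (!length(degree)) return(tibble(degree = integer(0), count = integer(0)))
  counts <- tabulate(degree + 1L, nbins = max(degree) + 1L)
  tibble(degree = 0:max(degree), count = as.integer(counts))
}

#' Topological report of a network
#'
#' The NetworkAnalyzer-style summary: per-node betweenness
#' ([betweenness_centrality()]), closeness ([closeness_centrality()])
#' and degree; global node/edge/component counts; and the betweenness
#' and degree histograms.
#'
#' @param net A [hetero_network()].
#' @param bc_bin_width Bin width for the betweenness histogram (default
#'   0.1).
#' @return A `topology_report`: list with `per_node` (tibble `id`,
#'   `node_type`, `degree`, `betweenness`, `closeness`), `n_nodes`,
#'   `n_edges`, `n_components`, `bc_histogram`, `degree_histogram`.
#' @export
topology_report <- function(net, bc_bin_width = 0.1) {
  adj <- network_adjacency(net)
  deg <- lengths(adj)
  bc <- betweenness_centrality(net)
  cc <- closeness_centrality(net)
  per_node <- tibble(
    id = net$nodes$id,
    node_type = net$nodes$node_type,
    degree = as.integer(deg),
    betweenness = unname(bc),
    closeness = unname(cc)
  )
  structure(list(
    per_node = per_node,
    n_nodes = nrow(net$nodes),
    n_edges = nrow(net$edges),
    n_components = if (nrow(net$nodes)) max(component_labels(net)) else 0L,
    bc_histogram = bc_histogram(per_node$betweenness, bc_bin_width),
    degree_histogram = degree_histogram(per_node$degree)
  ), class = "topology_report")
}

#' @export
print.topology_report <- function(x, ...) {
  cat(sprintf(
    "# Topology report: %d nodes, %d edges, %d connected component(s)\n",
    x$n_nodes, x$n_edges, x$n_components))
  print(x$per_node, ...)
  invisible(x)
}

#' Rank nodes by a topological measure
#'
#' Descending by the chosen measure, ties broken by node id ascending;
#' optionally restricted to one node type.
#'
#' @param report A `topology_report`.
#' @param by `"betweenness"`, `"closeness"`, or `"degree"`.
#' @param node_type Optional node-type filter (e.g. `"gene"`).
#' @return The `per_node` tibble, filtered, ranked, with a `rank`
#'   column.
#' @export
rank_nodes <- function(report, by = c("betweenness", "closeness", "degree"),
                       node_type = NULL) {
  by <- match.arg(by)
  pn <- report$per_node
  if (!is.null(node_type)) {
    stopifnot(all(node_type %in% NODE_TYPES))
    pn <- pn[pn$node_type %in% node_type, , drop = FALSE]
  }
  pn <- pn[order(-pn[[by]], pn$id), ]
  pn$rank <- seq_len(nrow(pn))
  pn[c("rank", setdiff(names(pn), "rank"))]
}

#' Write a topology report
#'
#' `write_topology_tsv()` writes the per-node table;
#' `write_topology_json()` writes the global summary and histograms.
#'
#' @param report A `topology_report`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_topology_tsv <- function(report, path) {
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(as.data.frame(report$per_node), con, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_topology_tsv
#' @export
write_topology_json <- function(report, path) {
  jsonlite::write_json(
    list(
      n_nodes = report$n_nodes,
      n_edges = report$n_edges,
      n_components = report$n_components,
      bc_histogram = as.data.frame(report$bc_histogram),
      degree_histogram = as.data.frame(report$degree_histogram)
    ),
    path, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
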