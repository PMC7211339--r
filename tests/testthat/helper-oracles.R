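# Independent oracles used across the suite. These deliberately avoid
# the package's own code paths: exact integer arithmetic for the
# hypergeometric tail, Floyd-Warshall distances plus explicit geodesic
# enumeration for centralities, and a literal double-loop step-up for
# BH.

# Pascal-triangle binomial table; every entry is an exact integer in a
# double for n <= 40 (max C(40,20) ~ 1.4e11 << 2^53).
pascal_choose <- function(nmax) {
  C <- matrix(0, nmax + 1L, nmax + 1L)
  C[, 1L] <- 1
  for (i in 2:(nmax + 1L)) {
    for (j in 2:i) C[i, j] <- C[i - 1L, j - 1L] + C[i - 1L, j]
  }
  C
}

# exact upper-tail hypergeometric by direct pmf summation; valid while
# C(N, n) stays below 2^53 (all intermediates are bounded by it)
oracle_hyper_exact <- function(k, n, K, N, C = pascal_choose(N)) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  num <- sum(C[K + 1L, i + 1L] * C[N - K + 1L, n - i + 1L])
  num / C[N + 1L, n + 1L]
}

# literal BH step-up: adj_(i) = min_{j>=i} min(1, m p_(j) / j)
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(m * p[o][i:m] / (i:m)))
  }
  out <- numeric(m)
  out[o] <- adj_sorted
  out
}

# dense symmetric distance matrix by Floyd-Warshall
oracle_distances <- function(net) {
  n <- nrow(net$nodes)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  if (nrow(net$edges)) {
    a <- match(net$edges$gene, net$nodes$id)
    b <- match(net$edges$category_id, net$nodes$id)
    for (j in seq_along(a)) D[a[j], b[j]] <- D[b[j], a[j]] <- 1
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      D[i, ] <- pmin(D[i, ], D[i, k] + D[k, ])
    }
  }
  D
}

adjacency_sets <- function(net) {
  n <- nrow(net$nodes)
  adj <- rep(list(integer(0)), n)
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

# enumerate every geodesic between every pair and credit interior
# nodes; normalize by (n-1)(n-2)/2 over the whole graph
oracle_betweenness <- function(net) {
  n <- nrow(net$nodes)
  bc <- numeric(n)
  if (n >= 3L) {
    D <- oracle_distances(net)
    adj <- adjacency_sets(net)
    enumerate_paths <- function(u, t) {
      if (u == t) return(list(t))
      nxt <- adj[[u]][D[adj[[u]], t] == D[u, t] - 1]
      unlist(lapply(nxt, function(w) {
        lapply(enumerate_paths(w, t), function(p) c(u, p))
      }), recursive = FALSE)
    }
    for (s in seq_len(n - 1L)) {
      for (t in (s + 1L):n) {
        if (!is.finite(D[s, t])) next
        paths <- enumerate_paths(s, t)
        sigma <- length(paths)
        interior <- unlist(lapply(paths, function(p) p[-c(1, length(p))]))
        if (length(interior)) {
          tab <- table(interior)
          idx <- as.integer(names(tab))
          bc[idx] <- bc[idx] + as.numeric(tab) / sigma
        }
      }
    }
    bc <- bc / ((n - 1) * (n - 2) / 2)
  }
  stats::setNames(bc, net$nodes$id)
}

oracle_closeness <- function(net) {
  n <- nrow(net$nodes)
  D <- oracle_distances(net)
  cc <- numeric(n)
  for (v in seq_len(n)) {
    d <- D[v, -v]
    d <- d[is.finite(d)]
    if (length(d) && n > 1L) cc[v] <- (length(d) / sum(d)) * (length(d) / (n - 1))
  }
  stats::setNames(cc, net$nodes$id)
}

# seeded random bipartite hetero_network; every category is guaranteed
# at least one member so the constructor's degree invariant holds
random_bipartite_network <- function(n_genes, n_cats, p_edge, seed) {
  set.seed(seed)
  genes <- sprintf("g%02d", seq_len(n_genes))
  cats <- sprintf("c%02d", seq_len(n_cats))
  inc <- matrix(runif(n_genes * n_cats) < p_edge, n_genes, n_cats)
  for (j in which(colSums(inc) == 0L)) inc[sample.int(n_genes, 1L), j] <- TRUE
  idx <- which(inc, arr.ind = TRUE)
  edges <- tibble::tibble(gene = genes[idx[, 1]], category_id = cats[idx[, 2]])
  types <- sample(c("pathway", "molecular_function", "cellular_component",
                    "brain_region"), n_cats, replace = TRUE)
  nodes <- tibble::tibble(
    id = c(genes, cats),
    display_name = c(genes, cats),
    node_type = c(rep("gene", n_genes), types),
    fdr = c(rep(NA_real_, n_genes), runif(n_cats, 0, 0.05))
  )
  hetero_network(nodes, edges)
}

# tiny three-node path network used by several hand examples
path_abc_network <- function() {
  hetero_network(
    tibble::tibble(id = c("A", "C", "B"),
                   display_name = c("A", "C", "B"),
                   node_type = c("gene", "gene", "pathway"),
                   fdr = c(NA, NA, 0.01)),
    tibble::tibble(gene = c("A", "C"), category_id = c("B", "B"))
  )
}

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

default_collection_paths <- function(dir) {
  types <- c("pathway", "molecular_function", "cellular_component",
             "brain_region")
  lapply(types, function(t) list(path = file.path(dir, paste0(t, ".gmt")),
                                 category_type = t))
}
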