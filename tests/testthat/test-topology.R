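test_that("path A-B-C has the textbook betweenness and closeness", {
  net <- path_abc_network()
  bc <- betweenness_centrality(net)
  expect_equal(bc[["B"]], 1)
  expect_equal(bc[["A"]], 0)
  expect_equal(bc[["C"]], 0)
  cc <- closeness_centrality(net)
  expect_equal(cc[["B"]], 1)
  expect_equal(cc[["A"]], 2 / 3)
  expect_equal(cc[["C"]], 2 / 3)
})

test_that("complete bipartite K_{2,2}-with-diagonals analogue: direct edges kill betweenness", {
  # complete bipartite graph on 2 genes x 2 categories: every pair is at
  # distance <= 2 with two geodesics through opposite sides
  nodes <- tibble::tibble(
    id = c("g1", "g2", "c1", "c2"),
    display_name = c("g1", "g2", "c1", "c2"),
    node_type = c("gene", "gene", "pathway", "pathway"),
    fdr = c(NA, NA, 0.01, 0.01))
  edges <- tidyr::expand_grid(gene = c("g1", "g2"),
                              category_id = c("c1", "c2"))
  net <- hetero_network(nodes, edges)
  bc <- betweenness_centrality(net)
  expect_equal(unname(bc), rep(1 / 6, 4), tolerance = 1e-14)
  expect_equal(unname(bc), unname(oracle_betweenness(net)), tolerance = 1e-14)
})

test_that("single edge gives closeness 1 on both ends; isolated nodes score 0", {
  nodes <- tibble::tibble(id = c("g1", "c1"), display_name = c("g1", "c1"),
                          node_type = c("gene", "pathway"), fdr = c(NA, 0.01))
  net <- hetero_network(nodes, tibble::tibble(gene = "g1",
                                              category_id = "c1"))
  expect_equal(unname(closeness_centrality(net)), c(1, 1))

  iso <- hetero_network(
    tibble::tibble(id = c("g1", "g2"), display_name = c("g1", "g2"),
                   node_type = "gene", fdr = NA_real_),
    tibble::tibble(gene = character(0), category_id = character(0)))
  expect_equal(unname(closeness_centrality(iso)), c(0, 0))
  expect_equal(unname(betweenness_centrality(iso)), c(0, 0))
})

test_that("Brandes betweenness and closeness match brute-force enumeration on 50 seeded graphs", {
  for (seed in 1:50) {
    n_genes <- sample(3:8, 1)
    n_cats <- sample(2:6, 1)
    net <- random_bipartite_network(n_genes, n_cats, runif(1, 0.15, 0.5),
                                    seed)
    expect_lte(nrow(net$nodes), 14L)
    expect_equal(betweenness_centrality(net), oracle_betweenness(net),
                 tolerance = 1e-12,
                 label = sprintf("betweenness seed %d", seed))
    expect_equal(closeness_centrality(net), oracle_closeness(net),
                 tolerance = 1e-12,
                 label = sprintf("closeness seed %d", seed))
  }
})

test_that("centralities agree with igraph as an independent library cross-check", {
  for (seed in c(2, 13)) {
    net <- random_bipartite_network(7, 5, 0.3, seed)
    g <- as_igraph(net)
    n <- igraph::vcount(g)
    expect_equal(unname(betweenness_centrality(net)),
                 unname(igraph::betweenness(g)) / ((n - 1) * (n - 2) / 2),
                 tolerance = 1e-12)
    comp <- component_labels(net)
    expect_equal(max(comp), igraph::components(g)$no)
  }
})

test_that("histograms bin correctly and conserve the node count", {
  net <- path_abc_network()
  h <- bc_histogram(betweenness_centrality(net), bin_width = 0.1)
  expect_equal(h$count[[1]], 2L)                  # A and C at 0
  expect_equal(h$count[[nrow(h)]], 1L)            # B at 1, closed last bin
  expect_equal(sum(h$count), 3L)
  expect_error(bc_histogram(c(0.5), bin_width = 0), "bin_width")

  iso <- hetero_network(
    tibble::tibble(id = sprintf("g%d", 1:5),
                   display_name = sprintf("g%d", 1:5),
                   node_type = "gene", fdr = NA_real_),
    tibble::tibble(gene = character(0), category_id = character(0)))
  dh <- degree_histogram(topology_report(iso)$per_node$degree)
  expect_equal(dh, tibble::tibble(degree = 0L, count = 5L))

  for (seed in c(5, 9)) {
    net <- random_bipartite_network(9, 4, 0.3, seed)
    rep <- topology_report(net)
    expect_equal(sum(rep$bc_histogram$count), rep$n_nodes)
    expect_equal(sum(rep$degree_histogram$count), rep$n_nodes)
  }
})

test_that("disjoint doubling rescales closeness by (n-1)/(2n-1) only", {
  net <- random_bipartite_network(6, 4, 0.35, 31)
  n <- nrow(net$nodes)
  copy_nodes <- net$nodes
  copy_nodes$id <- paste0(copy_nodes$id, "_dup")
  copy_nodes$display_name <- copy_nodes$id
  copy_edges <- net$edges
  copy_edges$gene <- paste0(copy_edges$gene, "_dup")
  copy_edges$category_id <- paste0(copy_edges$category_id, "_dup")
  doubled <- hetero_network(dplyr::bind_rows(net$nodes, copy_nodes),
                            dplyr::bind_rows(net$edges, copy_edges))
  cc1 <- closeness_centrality(net)
  cc2 <- closeness_centrality(doubled)[seq_len(n)]
  expect_equal(unname(cc2), unname(cc1) * (n - 1) / (2 * n - 1),
               tolerance = 1e-12)
})

test_that("rank_nodes orders by measure with id tie-break and type filter", {
  net <- path_abc_network()
  rep <- topology_report(net)
  ranked <- rank_nodes(rep, "betweenness")
  expect_equal(ranked$id, c("B", "A", "C"))
  genes <- rank_nodes(rep, "betweenness", node_type = "gene")
  expect_equal(genes$id, c("A", "C"))   # all-zero ties break lexicographically
  expect_error(rank_nodes(rep, "pagerank"))

  # planted hub: one gene in every category dominates gene betweenness
  set.seed(77)
  genes <- sprintf("g%02d", 1:8)
  cats <- sprintf("c%d", 1:5)
  edges <- dplyr::bind_rows(
    tibble::tibble(gene = "g01", category_id = cats),
    tibble::tibble(gene = sample(genes[-1], 5), category_id = cats))
  edges <- dplyr::distinct(edges)
  nodes <- tibble::tibble(
    id = c(genes[unique(c(1, match(unique(edges$gene), genes)))], cats),
    node_type = rep(c("gene", "pathway"),
                    c(length(unique(edges$gene)), length(cats))),
    fdr = rep(c(NA_real_, 0.01),
              c(length(unique(edges$gene)), length(cats))))
  nodes$display_name <- nodes$id
  net <- hetero_network(nodes, edges)
  rep <- topology_report(net)
  gene_rank <- rank_nodes(rep, "betweenness", node_type = "gene")
  expect_equal(gene_rank$id[[1]], "g01")
  expect_equal(rank_nodes(rep, "betweenness", "gene")$betweenness[[1]],
               oracle_betweenness(net)[["g01"]], tolerance = 1e-12)
})

test_that("topology_report counts components across disconnected parts", {
  net <- random_bipartite_network(6, 3, 0.25, 41)
  rep <- topology_report(net)
  expect_equal(rep$n_nodes, nrow(net$nodes))
  expect_equal(rep$n_edges, nrow(net$edges))
  expect_equal(rep$n_components, max(component_labels(net)))
  expect_true(all(rep$per_node$betweenness >= 0 &
                    rep$per_node$betweenness <= 1))
  expect_true(all(rep$per_node$closeness >= 0 &
                    rep$per_node$closeness <= 1))
})
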