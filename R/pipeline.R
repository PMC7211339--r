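#' Pipeline configuration
#'
#' Validates paths and thresholds for an end-to-end run: two disorder
#' gene lists, one or more GMT collections (each tagged with its
#' category type), and optional alias map and background universe.
#'
#' @param list_a,list_b Paths to the two gene-list files.
#' @param collections List of `list(path =, category_type =)` entries.
#' @param out_dir Output directory.
#' @param aliases Optional path to an alias-map TSV.
#' @param background Optional path to a background (universe) gene list;
#'   default is the union of all collection members.
#' @param fdr_threshold Significance threshold (default 0.05).
#' @param min_category_size,max_category_size Category-size filter
#'   (defaults 3, 500).
#' @param include_isolated_genes Keep unannotated query genes as
#'   isolated network nodes? Default `FALSE`.
#' @param label_a,label_b Labels for the two lists (defaults `"A"`,
#'   `"B"`).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(list_a, list_b, collections, out_dir,
                            aliases = NULL, background = NULL,
                            fdr_threshold = 0.05,
                            min_category_size = 3L,
                            max_category_size = 500L,
                            include_isolated_genes = FALSE,
                            label_a = "A", label_b = "B") {
  for (p in c(list_a, list_b, aliases, background)) {
    if (!file.exists(p)) abort(sprintf("config error: '%s' not found", p))
  }
  stopifnot(is.list(collections), length(collections) >= 1L)
  collections <- lapply(collections, function(cl) {
    if (is.null(cl$path) || is.null(cl$category_type)) {
      abort("each collection needs `path` and `category_type`")
    }
    if (!file.exists(cl$path)) {
      abort(sprintf("config error: '%s' not found", cl$path))
    }
    cl$category_type <- match_category_type(cl$category_type)
    cl
  })
  if (!(fdr_threshold > 0 && fdr_threshold <= 1)) {
    abort("`fdr_threshold` must be in (0, 1]")
  }
  structure(list(
    list_a = list_a, list_b = list_b, collections = collections,
    out_dir = out_dir, aliases = aliases, background = background,
    fdr_threshold = fdr_threshold,
    min_category_size = as.integer(min_category_size),
    max_category_size = as.integer(max_category_size),
    include_isolated_genes = isTRUE(include_isolated_genes),
    label_a = label_a, label_b = label_b
  ), class = "pipeline_config")
}

#' Read a pipeline configuration file
#'
#' YAML or JSON (chosen by file extension; anything not `.json` is
#' parsed as YAML). Relative paths are resolved against the config
#' file's directory. Recognized keys match the arguments of
#' [pipeline_config()].
#'
#' @param path Path to the config file.
#' @param ... Overrides passed on to [pipeline_config()] (e.g. from
#'   command-line flags).
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path, ...) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^(/|[A-Za-z]:)", p), p, file.path(base, p))
  }
  for (key in c("list_a", "list_b", "aliases", "background", "out_dir")) {
    raw[[key]] <- resolve(raw[[key]])
  }
  raw$collections <- lapply(raw$collections, function(cl) {
    cl$path <- resolve(cl$path)
    cl
  })
  overrides <- list(...)
  raw[names(overrides)] <- overrides
  do.call(pipeline_config, raw)
}

log_stage <- function(fmt, ...) inform(sprintf(paste0("[comorbinet] ", fmt), ...))

#' Run the full enrichment-network pipeline
#'
#' Reads and canonicalizes the two lists, intersects them, runs ORA of
#' the shared genes against every collection (BH within collection),
#' assembles the heterogeneous network from the significant categories,
#' computes the topology report, and writes all artifacts to
#' `cfg$out_dir`: `shared_genes.txt`, `enrichment_<type>.tsv` per
#' collection, `network.sif` / `network.graphml`, `topology.tsv` /
#' `topology.json`, a ranked `node_table_<type>.tsv` per node type
#' present, and `run_summary.json` with the counts at every stage.
#' Progress is logged to stderr.
#'
#' @param cfg A [pipeline_config()].
#' @return Invisibly, a list with `shared`, `results`, `network`,
#'   `topology`, `node_tables`, and `summary`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "pipeline_config"))
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  aliases <- if (!is.null(cfg$aliases)) read_alias_map(cfg$aliases)

  list_a <- read_gene_list(cfg$list_a, cfg$label_a, aliases)
  list_b <- read_gene_list(cfg$list_b, cfg$label_b, aliases)
  log_stage("read %d '%s' genes (%d collapsed), %d '%s' genes (%d collapsed)",
            nrow(list_a), cfg$label_a, attr(list_a, "n_collapsed"),
            nrow(list_b), cfg$label_b, attr(list_b, "n_collapsed"))
  shared <- intersect_gene_lists(list_a, list_b)
  log_stage("%d shared genes", nrow(shared))
  if (!nrow(shared)) abort("gene_sets stage: empty intersection")
  write_gene_list(shared, file.path(cfg$out_dir, "shared_genes.txt"))

  collections <- lapply(cfg$collections, function(cl) {
    read_gmt(cl$path, cl$category_type)
  })
  background <- if (!is.null(cfg$background)) {
    enrichment_background(read_gene_list(cfg$background, "background")$gene,
                          source = "user_file")
  } else {
    enrichment_background(collection_universe(collections),
                          source = "union_of_collection")
  }

  results <- purrr::map(collections, function(coll) {
    res <- run_ora(shared, coll, background,
                   fdr_threshold = cfg$fdr_threshold,
                   min_category_size = cfg$min_category_size,
                   max_category_size = cfg$max_category_size)
    type <- coll$category_type[[1]]
    log_stage("ORA %s: %d categories tested, %d significant (FDR <= %g)",
              type, nrow(res), sum(res$significant), cfg$fdr_threshold)
    write_ora_tsv(res, file.path(cfg$out_dir,
                                 sprintf("enrichment_%s.tsv", type)))
    res
  })
  all_results <- bind_rows(results)
  class(all_results) <- c("ora_result", class(all_results))

  net <- build_network(shared, all_results,
                       include_isolated_genes = cfg$include_isolated_genes)
  top <- topology_report(net)
  log_stage("network: %d nodes, %d edges, %d component(s)",
            top$n_nodes, top$n_edges, top$n_components)
  write_sif(net, file.path(cfg$out_dir, "network.sif"))
  write_graphml(net, file.path(cfg$out_dir, "network.graphml"),
                topology = top)
  write_topology_tsv(top, file.path(cfg$out_dir, "topology.tsv"))
  write_topology_json(top, file.path(cfg$out_dir, "topology.json"))

  types_present <- intersect(NODE_TYPES, unique(net$nodes$node_type))
  node_tables <- lapply(types_present, function(tp) {
    tab <- node_table(net, top, node_type = tp)
    con <- file(file.path(cfg$out_dir,
                          sprintf("node_table_%s.tsv", tp)), open = "wb")
    on.exit(close(con))
    utils::write.table(as.data.frame(tab), con, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    tab
  })
  names(node_tables) <- types_present

  summary <- list(
    n_list_a = nrow(list_a), n_list_b = nrow(list_b),
    n_collapsed_a = attr(list_a, "n_collapsed"),
    n_collapsed_b = attr(list_b, "n_collapsed"),
    n_shared = nrow(shared),
    background_size = length(background),
    background_source = attr(background, "source"),
    n_categories_tested = nrow(all_results),
    n_significant = sum(all_results$significant),
    n_significant_by_type = as.list(
      table(all_results$category_type[all_results$significant])),
    n_nodes = top$n_nodes, n_edges = top$n_edges,
    n_components = top$n_components
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(shared = shared, results = all_results, network = net,
                 topology = top, node_tables = node_tables,
                 summary = summary))
}
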