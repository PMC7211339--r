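#' The bundled OCD-BD comorbidity case study
#'
#' Node tables of the published OCD-BD shared-gene enrichment network:
#' 34 genes and 28 significant categories (7 pathways, 10 molecular
#' functions, 8 cellular components, 3 brain regions), with the
#' reported FDR per category and the reported betweenness value per
#' node. The published betweenness values are carried for reference
#' only; their normalization convention is not stated, so this package
#' never asserts against them.
#'
#' @return A list with two tibbles: `genes` (rank, symbol,
#'   display_name, betweenness) and `categories` (category_type,
#'   category_id, name, fdr, betweenness).
#' @export
ocd_bd_case_study <- function() {
  read_tsv_file <- function(f) {
    as_tibble(utils::read.delim(
      system.file("extdata", f, package = "comorbinet", mustWork = TRUE),
      sep = "\t", stringsAsFactors = FALSE, check.names = FALSE))
  }
  list(genes = read_tsv_file("ocd_bd_gene_nodes.tsv"),
       categories = read_tsv_file("ocd_bd_category_nodes.tsv"))
}

#' Reconstruct the case-study network
#'
#' Builds a heterogeneous network over the case-study node sets. The
#' original edge list was never published, so gene-category membership
#' is assigned deterministically (gene `i` joins category
#' `((i - 1) mod 28) + 1` in table order): every gene and every
#' category is connected, which is all the node-count bookkeeping
#' needs. Category FDRs come from the published table.
#'
#' @return A [hetero_network()] with 62 nodes.
#' @export
ocd_bd_network <- function() {
  cs <- ocd_bd_case_study()
  ncat <- nrow(cs$categories)
  assignment <- ((seq_len(nrow(cs$genes)) - 1L) %% ncat) + 1L
  results <- tibble(
    category_id = cs$categories$category_id,
    name = cs$categories$name,
    category_type = cs$categories$category_type,
    k = NA_integer_, n = nrow(cs$genes), K = NA_integer_, N = NA_integer_,
    p_value = NA_real_,
    fdr = cs$categories$fdr,
    overlap_genes = lapply(seq_len(ncat), function(j) {
      sort(cs$genes$symbol[assignment == j])
    }),
    significant = TRUE
  )
  results$k <- lengths(results$overlap_genes)
  results$K <- results$k
  build_network(cs$genes$symbol, results)
}
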