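#' Hypergeometric upper-tail probability
#'
#' Probability of observing `k` or more annotated genes in a query of
#' size `n` drawn without replacement from a background of `N` genes of
#' which `K` carry the annotation:
#' \deqn{P(X \ge k) = \sum_{i=k}^{\min(n,K)}
#'   \binom{K}{i}\binom{N-K}{n-i} / \binom{N}{n}.}
#' The sum is accumulated in log space (via `lchoose` and a
#' log-sum-exp), so it is stable for backgrounds far beyond the reach of
#' naive factorials. Vectorized over all four arguments.
#'
#' @param k Overlap count(s), `0 <= k <= min(n, K)`.
#' @param n Query size(s), `n <= N`.
#' @param K Category size(s) within the background, `K <= N`.
#' @param N Background size(s).
#' @return Upper-tail probability in `[0, 1]`.
#' @export
#' @examples
#' hypergeometric_pvalue(3, 5, 10, 100)
hypergeometric_pvalue <- function(k, n, K, N) {
  args <- vctrs_recycle(k = k, n = n, K = K, N = N)
  k <- args$k; n <- args$n; K <- args$K; N <- args$N
  check_hyper_domain(k, n, K, N)
  vapply(seq_along(k), function(j) {
    hyper_upper_tail_one(k[j], n[j], K[j], N[j])
  }, numeric(1))
}

# recycle scalar arguments against the longest, erroring on mismatch
vctrs_recycle <- function(...) {
  args <- list(...)
  len <- max(lengths(args))
  lapply(args, function(a) {
    if (length(a) == len) return(a)
    if (length(a) == 1L) return(rep(a, len))
    abort("arguments must have length 1 or a common length")
  })
}

check_hyper_domain <- function(k, n, K, N) {
  chk <- function(x, nm) {
    if (anyNA(x) || any(x < 0) || any(x != floor(x))) {
      abort(sprintf("`%s` must be a non-negative integer", nm))
    }
  }
  chk(k, "k"); chk(n, "n"); chk(K, "K"); chk(N, "N")
  if (any(n > N)) abort("`n` must not exceed `N`")
  if (any(K > N)) abort("`K` must not exceed `N`")
  if (any(k > pmin(n, K))) abort("`k` must not exceed min(n, K)")
}

hyper_upper_tail_one <- function(k, n, K, N) {
  if (k == 0) return(1)
  i <- k:min(n, K)
  lg <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  m <- max(lg)
  if (!is.finite(m)) return(0)
  min(1, exp(m + log(sum(exp(lg - m)))))
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Classic step-up FDR adjustment: on sorted p-values,
#' `adj_(i) = min_(j >= i) min(1, m * p_(j) / j)`, mapped back to the
#' input order. Adjusted values are monotone in the sorted sense and lie
#' in `[0, 1]`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Adjusted values, in input order.
#' @export
bh_adjust <- function(p_values) {
  p <- as.numeric(p_values)
  if (anyNA(p) || any(p < 0) || any(p > 1)) {
    abort("p-values must lie in [0, 1]")
  }
  m <- length(p)
  if (m <= 1L) return(p)
  o <- order(p, decreasing = TRUE)
  adj <- pmin(1, cummin(m / (m:1) * p[o]))
  adj[order(o)]
}

#' Enrichment background (gene universe)
#'
#' The reference set from which the query is conceptually drawn; it
#' fixes `N` and the effective category sizes `K` in the hypergeometric
#' test. When no user universe is available, the union of all annotated
#' genes across the loaded collections is the reproducible default
#' ([collection_universe()]).
#'
#' @param genes Character vector of canonical symbols (non-empty).
#' @param source `"user_file"` or `"union_of_collection"`.
#' @return A character vector with class `enrichment_background` and a
#'   `source` attribute.
#' @export
enrichment_background <- function(genes,
                                  source = c("user_file",
                                             "union_of_collection")) {
  source <- match.arg(source)
  genes <- unique(toupper(as.character(genes)))
  if (!length(genes)) abort("background must be non-empty")
  structure(genes, class = "enrichment_background", source = source)
}

#' Over-representation analysis of a query list against one collection
#'
#' For every category (restricted to members inside the background and
#' to sizes within `[min_category_size, max_category_size]`), computes
#' the overlap with the query, the hypergeometric upper-tail p-value,
#' and the Benjamini-Hochberg FDR across the tested categories of this
#' collection. A category is flagged significant when
#' `fdr <= fdr_threshold` and it overlaps the query at all.
#'
#' Query genes outside the background are dropped (with a message);
#' `n` is the effective query size after that restriction.
#'
#' @param query A [gene_list()] or character vector of canonical
#'   symbols.
#' @param collection A [gene_set_collection()].
#' @param background Character vector / [enrichment_background()];
#'   `NULL` uses the union of the collection's members.
#' @param fdr_threshold Significance threshold on the FDR (default
#'   0.05).
#' @param min_category_size,max_category_size Effective-size filter for
#'   tested categories (defaults 3 and 500, standard ORA practice).
#' @return An `ora_result` tibble sorted by p-value (ties broken by
#'   `category_id`) with columns `category_id`, `name`, `category_type`,
#'   `k`, `n`, `K`, `N`, `p_value`, `fdr`, `overlap_genes`
#'   (list-column), `significant`.
#' @export
run_ora <- function(query, collection, background = NULL,
                    fdr_threshold = 0.05,
                    min_category_size = 3L, max_category_size = 500L) {
  stopifnot(is.data.frame(collection))
  if (!(is.numeric(fdr_threshold) && length(fdr_threshold) == 1L &&
        fdr_threshold > 0 && fdr_threshold <= 1)) {
    abort("`fdr_threshold` must be in (0, 1]")
  }
  if (min_category_size < 1L || min_category_size > max_category_size) {
    abort("need 1 <= min_category_size <= max_category_size")
  }
  q <- unique(as_gene_vector(query, "query"))
  if (!length(q)) abort("query is empty")
  if (is.null(background)) {
    background <- enrichment_background(collection_universe(collection),
                                        source = "union_of_collection")
  } else if (!inherits(background, "enrichment_background")) {
    background <- enrichment_background(as_gene_vector(background,
                                                       "background"))
  }
  bg <- unclass(background)
  q_in <- q[q %in% bg]
  n_dropped <- length(q) - length(q_in)
  if (!length(q_in)) abort("no query genes in background")
  if (n_dropped > 0L) {
    inform(sprintf("run_ora: dropped %d query gene(s) outside the background",
                   n_dropped))
  }
  n <- length(q_in)
  N <- length(bg)

  members_in <- lapply(collection$genes, function(g) g[g %in% bg])
  K <- lengths(members_in)
  keep <- K >= min_category_size & K <= max_category_size
  res <- tibble(
    category_id = collection$category_id[keep],
    name = collection$name[keep],
    category_type = collection$category_type[keep],
    overlap_genes = lapply(members_in[keep],
                           function(g) sort(g[g %in% q_in])),
    K = as.integer(K[keep])
  )
  res$k <- lengths(res$overlap_genes)
  res$n <- n
  res$N <- N
  res$p_value <- if (nrow(res)) {
    hypergeometric_pvalue(res$k, n, res$K, N)
  } else numeric(0)
  res$fdr <- bh_adjust(res$p_value)
  res$significant <- res$fdr <= fdr_threshold & res$k >= 1L
  res <- res[order(res$p_value, res$category_id), ]
  res <- res[c("category_id", "name", "category_type", "k", "n", "K", "N",
               "p_value", "fdr", "overlap_genes", "significant")]
  class(res) <- c("ora_result", class(res))
  attr(res, "collection_name") <- attr(collection, "collection_name")
  attr(res, "fdr_threshold") <- fdr_threshold
  attr(res, "background_source") <- attr(background, "source")
  attr(res, "n_query_dropped") <- n_dropped
  res
}

#' Run ORA against several collections
#'
#' Applies [run_ora()] to each collection separately, so the BH
#' adjustment stays within each annotation database (matching how
#' enrichment portals report each database on its own), then row-binds
#' the results.
#'
#' @inheritParams run_ora
#' @param collections List of [gene_set_collection()] objects.
#' @return An `ora_result` tibble covering all collections.
#' @export
run_ora_collections <- function(query, collections, background = NULL,
                                fdr_threshold = 0.05,
                                min_category_size = 3L,
                                max_category_size = 500L) {
  if (is.data.frame(collections)) collections <- list(collections)
  if (is.null(background)) {
    background <- enrichment_background(collection_universe(collections),
                                        source = "union_of_collection")
  }
  out <- purrr::map(collections, run_ora, query = query,
                    background = background, fdr_threshold = fdr_threshold,
                    min_category_size = min_category_size,
                    max_category_size = max_category_size)
  res <- bind_rows(out)
  class(res) <- c("ora_result", class(res))
  attr(res, "fdr_threshold") <- fdr_threshold
  res
}

#' Write enrichment results as TSV
#'
#' One row per tested category; `overlap_genes` is comma-joined in
#' sorted order and probabilities are printed in scientific notation
#' with six significant digits.
#'
#' @param results An `ora_result` tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ora_tsv <- function(results, path) {
  df <- as.data.frame(results[c("category_id", "name", "category_type",
                                "k", "n", "K", "N")])
  df$p_value <- sprintf("%.6e", results$p_value)
  df$fdr <- sprintf("%.6e", results$fdr)
  df$overlap_genes <- vapply(results$overlap_genes,
                             function(g) paste(sort(g), collapse = ","), "")
  df$significant <- results$significant
  con <- file(path, open = "wb")
  on.exit(close(con))
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
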