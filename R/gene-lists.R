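#' Construct a labelled gene list
#'
#' A gene list is a one-column tibble (`gene`) of canonical, uppercase,
#' duplicate-free symbols in first-occurrence order, carrying a `label`
#' attribute (e.g. `"BD"`). Most users will obtain one from
#' [read_gene_list()] rather than calling this directly.
#'
#' @param genes Character vector of gene symbols (already canonical).
#' @param label Short label for the list.
#' @param n_collapsed Number of duplicates collapsed during
#'   canonicalization (bookkeeping, stored as an attribute).
#' @return A `gene_list` tibble with one `gene` column.
#' @export
gene_list <- function(genes, label, n_collapsed = 0L) {
  genes <- as.character(genes)
  if (anyNA(genes) || any(!nzchar(trimws(genes)))) {
    abort("gene symbols must be non-empty and non-missing")
  }
  if (anyDuplicated(genes)) {
    abort("gene symbols must be unique; canonicalize first")
  }
  out <- tibble(gene = genes)
  class(out) <- c("gene_list", class(out))
  attr(out, "label") <- as.character(label)
  attr(out, "n_collapsed") <- as.integer(n_collapsed)
  out
}

#' @export
print.gene_list <- function(x, ...) {
  cat("# Gene list '", gene_list_label(x), "': ", nrow(x), " genes\n",
      sep = "")
  NextMethod()
}

#' Label of a gene list
#' @param x A `gene_list`.
#' @return The label string.
#' @export
gene_list_label <- function(x) attr(x, "label") %||% "genes"

as_gene_vector <- function(x, arg = "x") {
  if (is.character(x)) return(x)
  if (is.data.frame(x)) {
    if (!"gene" %in% names(x)) {
      abort(sprintf("`%s` must have a `gene` column", arg))
    }
    return(as.character(x$gene))
  }
  abort(sprintf("`%s` must be a character vector or a gene-list tibble", arg))
}

#' Read a gene-alias map
#'
#' Two-column tab-separated file mapping alias symbols to canonical
#' symbols (many-to-one). A header line is recognized only if it is the
#' literal `alias<TAB>canonical`. Symbols are folded to uppercase, so
#' alias resolution is case-insensitive. This is the hook for
#' identifier-level deduplication (e.g. collapsing legacy symbols onto
#' the Ensembl-backed canonical name) without any network lookup.
#'
#' @param path Path to the TSV file.
#' @return An `alias_map` tibble with columns `alias` and `canonical`.
#' @export
read_alias_map <- function(path) {
  lines <- read_text_lines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) && identical(tolower(lines[[1]]), "alias\tcanonical")) {
    lines <- lines[-1]
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    abort(sprintf("alias map line %d does not have 2 tab-separated fields",
                  bad[[1]]))
  }
  out <- tibble(
    alias = toupper(trimws(vapply(parts, `[[`, "", 1L))),
    canonical = toupper(trimws(vapply(parts, `[[`, "", 2L)))
  )
  out <- distinct(out)
  alias_map(out)
}

#' Construct/validate an alias map
#'
#' @param mapping Data frame with `alias` and `canonical` columns
#'   (uppercase symbols). An alias must map to exactly one canonical
#'   symbol, and a canonical symbol may never itself be an alias of a
#'   different symbol (no chains).
#' @return An `alias_map` tibble.
#' @export
alias_map <- function(mapping) {
  stopifnot(is.data.frame(mapping),
            all(c("alias", "canonical") %in% names(mapping)))
  out <- as_tibble(mapping[c("alias", "canonical")])
  out$alias <- toupper(out$alias)
  out$canonical <- toupper(out$canonical)
  out <- distinct(out)
  dup <- unique(out$alias[duplicated(out$alias)])
  if (length(dup)) {
    abort(sprintf("alias '%s' maps to more than one canonical symbol",
                  dup[[1]]))
  }
  chained <- out$alias[out$alias %in% out$canonical &
                         out$alias != out$canonical]
  chained <- setdiff(
    chained,
    out$alias[match(chained, out$alias)][
      out$canonical[match(chained, out$alias)] == chained]
  )
  if (length(chained)) {
    abort(sprintf(
      "symbol '%s' is both an alias and a canonical target (chain)",
      chained[[1]]))
  }
  class(out) <- c("alias_map", class(out))
  out
}

#' Canonicalize gene symbols
#'
#' Trims whitespace, folds to uppercase, and substitutes aliases by
#' their canonical symbol. Unmapped symbols pass through unchanged, so
#' canonicalization is idempotent.
#'
#' @param genes Character vector of raw symbols.
#' @param aliases Optional `alias_map` (or NULL for no substitution).
#' @return Character vector of canonical uppercase symbols.
#' @export
canonicalize_genes <- function(genes, aliases = NULL) {
  out <- toupper(trimws(as.character(genes)))
  if (!is.null(aliases)) {
    stopifnot(is.data.frame(aliases))
    hit <- match(out, toupper(aliases$alias))
    out[!is.na(hit)] <- toupper(aliases$canonical)[hit[!is.na(hit)]]
  }
  out
}

#' Read a plain-text gene list
#'
#' One symbol per line; blank lines and lines starting with `#` are
#' ignored. Symbols are canonicalized ([canonicalize_genes()]) and
#' duplicates arising after canonicalization are collapsed, keeping the
#' first occurrence; the number collapsed is reported via a message and
#' stored in the `n_collapsed` attribute so curation errors stay
#' visible.
#'
#' @param path Path to the file.
#' @param label Label for the list (e.g. `"BD"`); defaults to the file
#'   base name.
#' @param aliases Optional `alias_map` from [read_alias_map()].
#' @return A [gene_list()] tibble.
#' @export
#' @examples
#' f <- tempfile()
#' writeLines(c("# demo", "drd2", "DRD2", "CACNA1C"), f)
#' read_gene_list(f, label = "demo")
read_gene_list <- function(path, label = NULL, aliases = NULL) {
  label <- label %||% sub("\\.[^.]*$", "", basename(path))
  lines <- read_text_lines(path)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (!length(lines)) abort(sprintf("empty gene list: '%s'", path))
  genes <- canonicalize_genes(lines, aliases)
  keep <- !duplicated(genes)
  n_collapsed <- sum(!keep)
  if (n_collapsed > 0L) {
    inform(sprintf("read_gene_list('%s'): collapsed %d duplicate symbol(s)",
                   label, n_collapsed))
  }
  gene_list(genes[keep], label = label, n_collapsed = n_collapsed)
}

#' Intersect two gene lists
#'
#' Returns the genes present in both lists, ordered by first appearance
#' in `a`. The result's label is `"a\u2229b"`.
#'
#' @param a,b `gene_list` tibbles (or character vectors).
#' @return A [gene_list()] of the shared genes (possibly empty).
#' @export
intersect_gene_lists <- function(a, b) {
  ga <- as_gene_vector(a, "a")
  gb <- as_gene_vector(b, "b")
  if (!length(ga) || !length(gb)) abort("both gene lists must be non-empty")
  shared <- ga[ga %in% gb]
  la <- if (is.data.frame(a)) gene_list_label(a) else "a"
  lb <- if (is.data.frame(b)) gene_list_label(b) else "b"
  out <- tibble(gene = shared)
  class(out) <- c("gene_list", class(out))
  attr(out, "label") <- paste0(la, "\u2229", lb)
  attr(out, "n_collapsed") <- 0L
  out
}

#' Write a gene list to a plain-text file
#'
#' One symbol per line, no comments; inverse of [read_gene_list()].
#'
#' @param x A `gene_list` (or character vector).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gene_list <- function(x, path) {
  writeLines(as_gene_vector(x), path, useBytes = TRUE)
  invisible(path)
}

read_text_lines <- function(path) {
  if (!file.exists(path)) abort(sprintf("cannot read '%s': no such file", path))
  readLines(path, warn = FALSE, encoding = "UTF-8")
}
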