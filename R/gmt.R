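#' Construct a gene-set collection
#'
#' A collection is a tibble with one row per category: `category_id`,
#' `name` (display name), `category_type`, and a `genes` list-column of
#' uppercase member symbols. All categories in one collection share a
#' single type (pathway, molecular function, cellular component, or
#' brain region), mirroring how annotation databases are queried one at
#' a time.
#'
#' @param categories Data frame with columns `category_id`, `name`,
#'   `genes` (list of character vectors).
#' @param category_type One of `"pathway"`, `"molecular_function"`,
#'   `"cellular_component"`, `"brain_region"`.
#' @param collection_name Optional name for the collection; defaults to
#'   the category type.
#' @return A `gene_set_collection` tibble.
#' @export
gene_set_collection <- function(categories, category_type,
                                collection_name = NULL) {
  category_type <- match_category_type(category_type)
  stopifnot(is.data.frame(categories),
            all(c("category_id", "name", "genes") %in% names(categories)))
  out <- as_tibble(categories[c("category_id", "name", "genes")])
  out$category_id <- as.character(out$category_id)
  out$name <- as.character(out$name)
  out$genes <- lapply(out$genes, function(g) unique(toupper(as.character(g))))
  if (anyDuplicated(out$category_id)) {
    abort(sprintf("duplicate category_id '%s' in collection",
                  out$category_id[duplicated(out$category_id)][[1]]))
  }
  if (any(lengths(out$genes) == 0L)) {
    abort("every category must have at least one member gene")
  }
  out$category_type <- category_type
  out <- out[c("category_id", "name", "category_type", "genes")]
  class(out) <- c("gene_set_collection", class(out))
  attr(out, "collection_name") <- collection_name %||% category_type
  out
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat("# Gene-set collection '", attr(x, "collection_name") %||% "?",
      "' (", x$category_type[1] %||% "?", "): ", nrow(x),
      " categories\n", sep = "")
  NextMethod()
}

#' Read a GMT gene-set file
#'
#' Broad-dialect GMT: each line is
#' `categoryID<TAB>description<TAB>member1<TAB>member2...` with at least
#' three fields. Members are uppercased and deduplicated per category;
#' categories left with zero members are dropped with a warning.
#'
#' @param path Path to the GMT file.
#' @param category_type Category type tag for the whole collection.
#' @param collection_name Optional collection name; defaults to the file
#'   base name.
#' @return A [gene_set_collection()] tibble.
#' @export
#' @examples
#' f <- tempfile(fileext = ".gmt")
#' writeLines("hsa04728\tDopaminergic synapse\tDRD1\tDRD2", f)
#' read_gmt(f, "pathway")
read_gmt <- function(path, category_type, collection_name = NULL) {
  category_type <- match_category_type(category_type)
  lines <- read_text_lines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  line_no <- which(keep)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 3L)
  if (length(bad)) {
    abort(sprintf(
      "GMT parse error at line %d of '%s': expected >= 3 tab-separated fields, found %d",
      line_no[bad[[1]]], path, lengths(parts)[bad[[1]]]))
  }
  ids <- vapply(parts, `[[`, "", 1L)
  names_ <- vapply(parts, `[[`, "", 2L)
  members <- lapply(parts, function(p) {
    m <- toupper(trimws(p[-(1:2)]))
    unique(m[nzchar(m)])
  })
  empty <- lengths(members) == 0L
  if (any(empty)) {
    warn(sprintf("read_gmt('%s'): dropped %d categor%s with no members",
                 path, sum(empty), if (sum(empty) == 1L) "y" else "ies"))
  }
  gene_set_collection(
    tibble(category_id = ids[!empty], name = names_[!empty],
           genes = members[!empty]),
    category_type = category_type,
    collection_name = collection_name %||% sub("\\.[^.]*$", "", basename(path))
  )
}

#' Write a gene-set collection as GMT
#'
#' Members are written in sorted order so output is deterministic;
#' `read_gmt(write_gmt(x))` reproduces `x` up to member order.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(is.data.frame(collection))
  lines <- purrr::pmap_chr(
    list(collection$category_id, collection$name, collection$genes),
    function(id, nm, genes) {
      paste(c(id, nm, sort(genes)), collapse = "\t")
    })
  con <- file(path, open = "wb")
  on.exit(close(con))
  writeLines(lines, con, useBytes = TRUE)
  invisible(path)
}

#' All genes annotated in one or more collections
#'
#' The union of member genes, sorted. Used as the default enrichment
#' background when no explicit universe file is supplied.
#'
#' @param collections A `gene_set_collection` or list of them.
#' @return Sorted character vector of gene symbols.
#' @export
collection_universe <- function(collections) {
  if (is.data.frame(collections)) collections <- list(collections)
  sort(unique(unlist(lapply(collections, function(x) unlist(x$genes)))))
}
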