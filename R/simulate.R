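#' Describe one synthetic annotation collection
#'
#' @param category_type Category type of the collection.
#' @param n_categories Number of categories.
#' @param size_range Length-2 integer vector: category sizes are drawn
#'   uniformly from this range.
#' @param n_planted Number of planted (truly enriched) categories.
#' @return A `sim_collection_spec` list.
#' @export
sim_collection_spec <- function(category_type, n_categories = 50L,
                                size_range = c(20L, 40L), n_planted = 5L) {
  category_type <- match_category_type(category_type)
  stopifnot(n_categories >= 1L, length(size_range) == 2L,
            size_range[1] >= 1L, size_range[1] <= size_range[2],
            n_planted >= 0L, n_planted <= n_categories)
  structure(list(category_type = category_type,
                 n_categories = as.integer(n_categories),
                 size_range = as.integer(size_range),
                 n_planted = as.integer(n_planted)),
            class = "sim_collection_spec")
}

default_sim_collections <- function() {
  list(
    sim_collection_spec("pathway", 50L, c(20L, 40L), 5L),
    sim_collection_spec("molecular_function", 50L, c(20L, 40L), 5L),
    sim_collection_spec("cellular_component", 50L, c(20L, 40L), 5L),
    sim_collection_spec("brain_region", 20L, c(20L, 40L), 3L)
  )
}

#' Configuration for a synthetic two-disorder study
#'
#' The defaults emulate the study conditions this package is built
#' around: a curated universe of 2000 genes, disorder lists of 397 and
#' 148 genes sharing exactly 58, and four annotation collections
#' (pathways, molecular functions, cellular components, brain regions)
#' each containing a handful of planted categories genuinely enriched in
#' the shared set. Intersection size is exact by construction (the
#' shared genes are drawn first, then the disjoint remainders), so list
#' counts are assertable, not merely expected.
#'
#' Each planted category contains `ceiling(planted_overlap_fraction *
#' overlap_size)` of the shared genes (its drawn size is raised to that
#' number if needed); remaining members come from the non-shared
#' universe. A designated hub gene (the first shared gene, recorded in
#' the manifest) is a member of every category of every collection, so
#' it has maximal brokerage in the resulting network by construction.
#' Non-planted categories are otherwise uniform draws from the whole
#' universe; with `planted_overlap_fraction = 0` nothing is planted and
#' no hub is placed (pure null draws).
#'
#' @param seed Master seed; one sub-stream per artifact (gene lists,
#'   each collection) is derived from it, so adding a collection does
#'   not perturb the lists.
#' @param universe_size Size of the gene universe (default 2000).
#' @param list_a_size,list_b_size Sizes of the two disorder lists
#'   (defaults 397 and 148).
#' @param overlap_size Exact intersection size (default 58).
#' @param collections List of [sim_collection_spec()]s.
#' @param planted_overlap_fraction Fraction of the shared gene set
#'   contained in each planted category, in `(0, 1]` (default 0.5).
#'   Set to 0 to plant nothing (null calibration studies).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed, universe_size = 2000L,
                       list_a_size = 397L, list_b_size = 148L,
                       overlap_size = 58L,
                       collections = default_sim_collections(),
                       planted_overlap_fraction = 0.5) {
  stopifnot(is.numeric(seed), length(seed) == 1L)
  cfg <- list(
    seed = as.integer(seed),
    universe_size = as.integer(universe_size),
    list_a_size = as.integer(list_a_size),
    list_b_size = as.integer(list_b_size),
    overlap_size = as.integer(overlap_size),
    collections = collections,
    planted_overlap_fraction = as.numeric(planted_overlap_fraction)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  with(cfg, {
    if (overlap_size > min(list_a_size, list_b_size)) {
      abort("infeasible config: overlap_size exceeds a list size")
    }
    if (list_a_size + list_b_size - overlap_size > universe_size) {
      abort("infeasible config: lists do not fit in the universe")
    }
    if (planted_overlap_fraction < 0 || planted_overlap_fraction > 1) {
      abort("`planted_overlap_fraction` must be in [0, 1]")
    }
    for (cl in collections) {
      if (!inherits(cl, "sim_collection_spec")) {
        abort("`collections` must be a list of sim_collection_spec objects")
      }
      if (cl$size_range[2] > universe_size) {
        abort("infeasible config: category size exceeds universe size")
      }
    }
  })
  invisible(cfg)
}

# run expr with a local RNG state seeded by `seed`
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a complete synthetic study
#'
#' Writes, under `out_dir`: the gene universe (`background.txt`), the
#' two disorder lists (`list_a.txt`, `list_b.txt`) whose realized
#' intersection equals `overlap_size` exactly, one GMT file per
#' configured collection (named after its category type), and a
#' `manifest.json` recording the ground truth (shared genes, hub gene,
#' planted category ids, per-category true overlap with the shared
#' set). Gene symbols are synthetic (`G000001`, ...) so no biological
#' identity is implied. The same configuration always produces
#' byte-identical files.
#'
#' @param cfg A [sim_config()].
#' @param out_dir Output directory (created if needed).
#' @return The manifest, invisibly, as a list.
#' @export
generate_study <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "sim_config"))
  validate_sim_config(cfg)
  universe <- sprintf("G%06d", seq_len(cfg$universe_size))
  n_coll <- length(cfg$collections)
  sub_seeds <- with_seed(cfg$seed,
                         sample.int(.Machine$integer.max, 1L + n_coll))

  # gene lists: shared genes first, then disjoint remainders
  lists <- with_seed(sub_seeds[[1]], {
    shared <- sample(universe, cfg$overlap_size)
    rest <- setdiff(universe, shared)
    a_only <- sample(rest, cfg$list_a_size - cfg$overlap_size)
    b_only <- sample(setdiff(rest, a_only),
                     cfg$list_b_size - cfg$overlap_size)
    list(shared = shared,
         a = sample(c(shared, a_only)),
         b = sample(c(shared, b_only)))
  })
  hub <- lists$shared[[1]]
  n_shared_members <- ceiling(cfg$planted_overlap_fraction *
                                cfg$overlap_size)

  prefixes <- c(pathway = "PW", molecular_function = "MF",
                cellular_component = "CC", brain_region = "BR")
  collections <- vector("list", n_coll)
  truth <- vector("list", n_coll)
  for (ci in seq_len(n_coll)) {
    spec <- cfg$collections[[ci]]
    collections[[ci]] <- with_seed(sub_seeds[[1L + ci]], {
      sizes <- sample(spec$size_range[1]:spec$size_range[2],
                      spec$n_categories, replace = TRUE)
      genes <- vector("list", spec$n_categories)
      for (i in seq_len(spec$n_categories)) {
        if (i <= spec$n_planted && n_shared_members > 0L) {
          sizes[i] <- max(sizes[i], n_shared_members)
          from_shared <- c(hub, sample(setdiff(lists$shared, hub),
                                       n_shared_members - 1L))
          filler <- sample(setdiff(universe, lists$shared),
                           sizes[i] - n_shared_members)
          genes[[i]] <- c(from_shared, filler)
        } else if (n_shared_members > 0L) {
          # background category: uniform draw, plus the hub so the
          # planted-hub gene is a member of every category by
          # construction (maximal brokerage)
          genes[[i]] <- c(hub, sample(setdiff(universe, hub), sizes[i] - 1L))
        } else {
          genes[[i]] <- sample(universe, sizes[i])
        }
      }
      pref <- prefixes[[spec$category_type]]
      gene_set_collection(
        tibble(
          category_id = sprintf("%s%03d", pref, seq_len(spec$n_categories)),
          name = sprintf("synthetic %s %d", spec$category_type,
                         seq_len(spec$n_categories)),
          genes = genes
        ),
        category_type = spec$category_type,
        collection_name = spec$category_type
      )
    })
    coll <- collections[[ci]]
    truth[[ci]] <- list(
      category_type = spec$category_type,
      file = paste0(spec$category_type, ".gmt"),
      planted_ids = coll$category_id[seq_len(spec$n_planted)],
      true_overlap = vapply(coll$genes,
                            function(g) sum(g %in% lists$shared),
                            integer(1))
    )
    names(truth[[ci]]$true_overlap) <- coll$category_id
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  write_gene_list(universe, file.path(out_dir, "background.txt"))
  write_gene_list(lists$a, file.path(out_dir, "list_a.txt"))
  write_gene_list(lists$b, file.path(out_dir, "list_b.txt"))
  for (ci in seq_len(n_coll)) {
    write_gmt(collections[[ci]],
              file.path(out_dir, truth[[ci]]$file))
  }
  manifest <- list(
    seed = cfg$seed,
    universe_size = cfg$universe_size,
    list_a_size = cfg$list_a_size,
    list_b_size = cfg$list_b_size,
    overlap_size = cfg$overlap_size,
    planted_overlap_fraction = cfg$planted_overlap_fraction,
    shared_genes = sort(lists$shared),
    hub_gene = hub,
    files = list(background = "background.txt", list_a = "list_a.txt",
                 list_b = "list_b.txt"),
    collections = truth
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
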