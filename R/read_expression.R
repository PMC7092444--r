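#' Validate a tidy expression collection
#'
#' An expression collection is a tibble with one row per (dataset, gene):
#' columns `dataset_id`, `condition`, `gene_id`, `intensity`. Intensities
#' are assumed to be on a within-dataset monotone scale (log or linear —
#' ranking is invariant to any within-dataset monotone transform, so no
#' cross-dataset normalisation is required or applied).
#'
#' @param x A data frame with columns `dataset_id`, `condition`, `gene_id`,
#'   `intensity`.
#' @param universe Optional character vector fixing the gene universe;
#'   defaults to the sorted union of `gene_id`s present.
#' @return The validated collection (tibble) with attributes
#'   `gene_universe` and class `expr_collection`.
#' @export
as_expression_collection <- function(x, universe = NULL) {
  required <- c("dataset_id", "condition", "gene_id", "intensity")
  missing_cols <- setdiff(required, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("expression collection lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "promrank_format_error")
  }
  x <- as_tibble(x)[required]
  if (!is.numeric(x$intensity) || any(!is.finite(x$intensity))) {
    abort("all intensities must be finite numbers",
          class = "promrank_validation_error")
  }
  dup <- x %>% dplyr::count(.data$dataset_id, .data$gene_id) %>%
    filter(.data$n > 1)
  if (nrow(dup) > 0) {
    abort(sprintf("duplicate gene '%s' in dataset '%s'",
                  dup$gene_id[1], dup$dataset_id[1]),
          class = "promrank_format_error")
  }
  if (is.null(universe)) universe <- sort(unique(x$gene_id))
  if (length(universe) == 0) {
    abort("gene universe is empty", class = "promrank_validation_error")
  }
  attr(x, "gene_universe") <- universe
  class(x) <- unique(c("expr_collection", class(x)))
  x
}

#' Gene universe of a collection
#'
#' @param x An expression collection.
#' @return Character vector of gene ids (the `gene_universe` attribute if
#'   present, else the sorted union of observed gene ids).
#' @export
collection_universe <- function(x) {
  attr(x, "gene_universe") %||% sort(unique(x$gene_id))
}

#' Read a multi-dataset expression collection from TSV files
#'
#' Reads one or more gene-by-sample intensity matrices plus a manifest
#' mapping each sample column to a dataset and a condition label, and
#' returns a tidy [as_expression_collection()].
#'
#' The matrix format is TSV with a first column `gene_id` and one column
#' per sample; the manifest is TSV with columns `sample_id`, `dataset_id`,
#' `condition`. Samples present in the matrices but absent from the
#' manifest are ignored with a message.
#'
#' @param matrix_paths Character vector of matrix TSV paths.
#' @param manifest_path Manifest TSV path.
#' @param universe_policy How to reconcile gene sets that differ across
#'   datasets: `"require-identical"` (default; error on any difference),
#'   `"intersect"` (keep the common genes, message the dropped count), or
#'   `"union-worst-rank"` (keep the union; a gene absent from a dataset is
#'   assigned the worst possible rank, the universe size, when ranking).
#' @param replicate_policy `"average"` (default): multiple sample columns
#'   mapped to one `dataset_id` are mean-averaged on the stored scale into
#'   one intensity vector; `"each-sample"`: every sample becomes its own
#'   dataset (dataset id = sample id).
#' @param missing_policy `"strict"` (default): any missing or non-numeric
#'   cell is an error; `"drop-gene"`: genes with any missing value are
#'   dropped from every dataset, with a message.
#' @return An `expr_collection` tibble.
#' @export
read_expression_collection <- function(matrix_paths, manifest_path,
                                       universe_policy = c("require-identical",
                                                           "intersect",
                                                           "union-worst-rank"),
                                       replicate_policy = c("average",
                                                            "each-sample"),
                                       missing_policy = c("strict",
                                                          "drop-gene")) {
  universe_policy <- arg_match(universe_policy)
  replicate_policy <- arg_match(replicate_policy)
  missing_policy <- arg_match(missing_policy)

  manifest <- readr::read_tsv(manifest_path, col_types = readr::cols(
    .default = readr::col_character()))
  need <- c("sample_id", "dataset_id", "condition")
  if (!all(need %in% names(manifest))) {
    abort(paste("manifest must have columns:", paste(need, collapse = ", ")),
          class = "promrank_manifest_error")
  }
  if (anyDuplicated(manifest$sample_id)) {
    abort(sprintf("sample '%s' mapped to more than one dataset in manifest",
                  manifest$sample_id[duplicated(manifest$sample_id)][1]),
          class = "promrank_manifest_error")
  }

  long <- purrr::map(matrix_paths, function(p) {
    m <- readr::read_tsv(p, col_types = readr::cols(
      .default = readr::col_character()))
    if (names(m)[1] != "gene_id") {
      abort(sprintf("matrix '%s' must have first column 'gene_id'", p),
            class = "promrank_format_error")
    }
    if (anyDuplicated(m$gene_id)) {
      abort(sprintf("duplicate gene row '%s' in matrix '%s'",
                    m$gene_id[duplicated(m$gene_id)][1], p),
            class = "promrank_format_error")
    }
    tidyr::pivot_longer(m, -"gene_id", names_to = "sample_id",
                        values_to = "raw")
  }) %>% bind_rows()

  absent <- setdiff(manifest$sample_id, unique(long$sample_id))
  if (length(absent) > 0) {
    abort(sprintf("manifest sample '%s' not found in any matrix", absent[1]),
          class = "promrank_manifest_error")
  }
  unmapped <- setdiff(unique(long$sample_id), manifest$sample_id)
  if (length(unmapped) > 0) {
    inform(sprintf("ignoring %d sample column(s) absent from the manifest",
                   length(unmapped)))
    long <- filter(long, .data$sample_id %in% manifest$sample_id)
  }

  long$intensity <- suppressWarnings(as.numeric(long$raw))
  bad <- !is.finite(long$intensity)
  if (any(bad)) {
    if (missing_policy == "strict") {
      i <- which(bad)[1]
      abort(sprintf("missing/non-numeric intensity for gene '%s', sample '%s'",
                    long$gene_id[i], long$sample_id[i]),
            class = "promrank_validation_error")
    }
    drop_genes <- unique(long$gene_id[bad])
    inform(sprintf("dropping %d gene(s) with missing values", length(drop_genes)))
    long <- filter(long, !.data$gene_id %in% drop_genes)
  }

  long <- left_join(long, manifest, by = "sample_id")
  if (replicate_policy == "each-sample") {
    long$dataset_id <- long$sample_id
  }
  ds_order <- if (replicate_policy == "each-sample") {
    manifest$sample_id
  } else {
    unique(manifest$dataset_id)
  }

  collection <- long %>%
    group_by(.data$dataset_id, .data$condition, .data$gene_id) %>%
    summarise(intensity = mean(.data$intensity), .groups = "drop")

  # reconcile gene sets across datasets
  sets <- split(collection$gene_id, collection$dataset_id)
  universe <- sort(unique(collection$gene_id))
  identical_sets <- all(vapply(sets, function(s) setequal(s, universe),
                               logical(1)))
  if (!identical_sets) {
    if (universe_policy == "require-identical") {
      abort(paste("datasets have differing gene sets;",
                  "use universe_policy = 'intersect' or 'union-worst-rank'"),
            class = "promrank_validation_error")
    }
    if (universe_policy == "intersect") {
      common <- Reduce(intersect, sets)
      dropped <- length(universe) - length(common)
      inform(sprintf("universe policy 'intersect': dropping %d gene(s) not shared by all datasets",
                     dropped))
      collection <- filter(collection, .data$gene_id %in% common)
      universe <- sort(common)
    }
    # union-worst-rank keeps the union; ranking fills absent genes
  }

  collection <- collection %>%
    mutate(dataset_id = factor(.data$dataset_id, levels = ds_order)) %>%
    arrange(.data$dataset_id, .data$gene_id) %>%
    mutate(dataset_id = as.character(.data$dataset_id)) %>%
    select("dataset_id", "condition", "gene_id", "intensity")

  as_expression_collection(collection, universe = universe)
}

#' Write an expression collection back to matrix + manifest TSVs
#'
#' Inverse of [read_expression_collection()] for collections with one
#' intensity per (dataset, gene): each dataset becomes one sample column
#' named `<dataset_id>_s1`. Reading the two files back yields an identical
#' collection.
#'
#' @param collection An `expr_collection`.
#' @param matrix_path,manifest_path Output TSV paths.
#' @return Invisibly, a list with the two paths.
#' @export
write_expression_collection <- function(collection, matrix_path,
                                        manifest_path) {
  ds <- distinct(collection, .data$dataset_id, .data$condition)
  manifest <- tibble(sample_id = paste0(ds$dataset_id, "_s1"),
                     dataset_id = ds$dataset_id,
                     condition = ds$condition)
  wide <- collection %>%
    mutate(sample_id = paste0(.data$dataset_id, "_s1")) %>%
    select("gene_id", "sample_id", "intensity") %>%
    tidyr::pivot_wider(names_from = "sample_id", values_from = "intensity")
  readr::write_tsv(wide, matrix_path)
  readr::write_tsv(manifest, manifest_path)
  invisible(list(matrix = matrix_path, manifest = manifest_path))
}
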