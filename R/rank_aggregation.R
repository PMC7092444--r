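#' Rank genes within one dataset
#'
#' Rank 1 is the highest intensity. Ties are broken deterministically by
#' `gene_id` (lexicographic ascending), which keeps every dataset's ranks
#' an exact permutation of `1..G` — a prerequisite for the order-statistic
#' median used downstream. With a `universe` larger than the genes present
#' (the `"union-worst-rank"` policy), absent genes receive the worst
#' possible rank, the universe size.
#'
#' @param dataset A data frame with columns `gene_id` and `intensity`
#'   (one row per gene).
#' @param universe Optional gene universe; defaults to the dataset's genes.
#' @return A tibble `gene_id`, `rank`, ordered by rank.
#' @examples
#' rank_within_dataset(tibble::tibble(gene_id = c("a", "b", "c"),
#'                                    intensity = c(10, 7.5, 9.9)))
#' @export
rank_within_dataset <- function(dataset, universe = NULL) {
  stopifnot(all(c("gene_id", "intensity") %in% names(dataset)))
  if (is.null(universe)) universe <- dataset$gene_id
  if (length(universe) == 0) {
    abort("gene universe is empty", class = "promrank_validation_error")
  }
  present <- dataset[dataset$gene_id %in% universe, ]
  ord <- order(-present$intensity, present$gene_id)
  out <- tibble(gene_id = present$gene_id[ord],
                rank = seq_along(ord))
  missing_genes <- setdiff(universe, present$gene_id)
  if (length(missing_genes) > 0) {
    out <- bind_rows(out, tibble(gene_id = sort(missing_genes),
                                 rank = length(universe)))
  }
  out
}

#' Order-statistic median of a rank list
#'
#' For an odd number `N` of ranks this is the `((N + 1) / 2)`-th smallest
#' value — e.g. the 42nd of 83 sorted ranks; for even `N`, the mean of the
#' two middle values (which can be a half-integer).
#'
#' @param ranks Numeric vector of ranks (any order).
#' @return A single number.
#' @examples
#' median_rank(1:83)        # 42
#' median_rank(c(4, 2, 10, 6))  # 5
#' @export
median_rank <- function(ranks) {
  if (length(ranks) == 0 || !is.numeric(ranks)) {
    abort("`ranks` must be a non-empty numeric vector",
          class = "promrank_validation_error")
  }
  s <- sort(ranks)
  n <- length(s)
  if (n %% 2 == 1) s[(n + 1) / 2] else (s[n / 2] + s[n / 2 + 1]) / 2
}

#' Per-dataset ranks for a whole collection
#'
#' @param collection An expression collection (see
#'   [as_expression_collection()]).
#' @param dataset_ids Optional subset of datasets to rank; defaults to all.
#' @return A tibble `dataset_id`, `gene_id`, `rank` — one row per
#'   (dataset, universe gene).
#' @export
rank_datasets <- function(collection, dataset_ids = NULL) {
  universe <- collection_universe(collection)
  all_ids <- unique(collection$dataset_id)
  if (is.null(dataset_ids)) dataset_ids <- all_ids
  unknown <- setdiff(dataset_ids, all_ids)
  if (length(unknown) > 0) {
    abort(sprintf("unknown dataset_id '%s'", unknown[1]),
          class = "promrank_reference_error")
  }
  sub <- collection[collection$dataset_id %in% dataset_ids, ]
  parts <- lapply(split(sub, sub$dataset_id), function(d) {
    r <- rank_within_dataset(d, universe = universe)
    r$dataset_id <- d$dataset_id[1]
    r
  })
  bind_rows(parts[as.character(dataset_ids)])[
    , c("dataset_id", "gene_id", "rank")] %>% as_tibble()
}

# min/max/median profile per gene from a long rank table, with the
# deterministic final ordering (median, then max, then min, then gene_id).
# rank_datasets() emits exactly one rank per (universe gene, dataset), so
# the table reshapes to a genes x datasets matrix for speed.
profiles_from_ranks <- function(ranks_long) {
  genes <- sort(unique(ranks_long$gene_id))
  o <- order(match(ranks_long$gene_id, genes))
  n_ds <- nrow(ranks_long) / length(genes)
  stopifnot(n_ds == as.integer(n_ds))
  m <- matrix(ranks_long$rank[o], nrow = length(genes), byrow = TRUE)
  cols <- lapply(seq_len(ncol(m)), function(j) m[, j])
  out <- tibble(
    gene_id = genes,
    n_datasets = as.integer(n_ds),
    min_rank = do.call(pmin, cols),
    max_rank = do.call(pmax, cols),
    median_rank = apply(m, 1, median_rank)
  )
  arrange(out, .data$median_rank, .data$max_rank, .data$min_rank,
          .data$gene_id)
}

#' Aggregate per-dataset ranks into ordered rank profiles
#'
#' The core prioritization step: every gene's per-dataset ranks are
#' summarised by their minimum, maximum and order-statistic median
#' ([median_rank()]), and genes are ordered by ascending median rank
#' (ties: smaller maximum, then smaller minimum, then `gene_id`). Genes at
#' the head of this list are the constitutively highly expressed ones.
#'
#' @inheritParams rank_datasets
#' @return A tibble `gene_id`, `n_datasets`, `min_rank`, `max_rank`,
#'   `median_rank`, ordered; the number of datasets used is recorded in the
#'   `n_datasets` column (identical for every gene).
#' @examples
#' coll <- as_expression_collection(tibble::tibble(
#'   dataset_id = rep(c("d1", "d2"), each = 3),
#'   condition = "c1",
#'   gene_id = rep(c("a", "b", "c"), 2),
#'   intensity = c(3, 2, 1, 1, 3, 2)))
#' aggregate_ranks(coll)
#' @export
aggregate_ranks <- function(collection, dataset_ids = NULL) {
  if (nrow(collection) == 0) {
    abort("collection is empty", class = "promrank_validation_error")
  }
  profiles_from_ranks(rank_datasets(collection, dataset_ids))
}

#' Aggregate ranks over a subset of datasets
#'
#' Identical semantics to [aggregate_ranks()] restricted to
#' `dataset_ids`; the median order statistic is recomputed for the
#' subset's own size. With `dataset_ids` equal to all datasets this
#' reproduces the full aggregation exactly.
#'
#' @inheritParams rank_datasets
#' @return See [aggregate_ranks()].
#' @export
aggregate_on_subset <- function(collection, dataset_ids) {
  if (length(dataset_ids) == 0) {
    abort("`dataset_ids` must be non-empty", class = "promrank_config_error")
  }
  aggregate_ranks(collection, dataset_ids = dataset_ids)
}

#' Write the full rank table to TSV
#'
#' Emits one row per gene with the profile summaries followed by the
#' per-dataset ranks (`rank_<dataset_id>` columns), in the prioritized
#' order.
#'
#' @inheritParams rank_datasets
#' @param path Output TSV path.
#' @return Invisibly, the path.
#' @export
write_rank_table <- function(collection, path, dataset_ids = NULL) {
  ranks_long <- rank_datasets(collection, dataset_ids)
  profiles <- profiles_from_ranks(ranks_long)
  wide <- ranks_long %>%
    mutate(dataset_id = paste0("rank_", .data$dataset_id)) %>%
    tidyr::pivot_wider(names_from = "dataset_id", values_from = "rank")
  out <- left_join(profiles, wide, by = "gene_id")
  readr::write_tsv(out, path)
  invisible(path)
}
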