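#' Top-k overlap between two ordered gene lists
#'
#' Counts the genes shared by the heads (first `k` entries) of two ordered
#' lists and the Jaccard index of the two head sets. When `k` exceeds a
#' list's length the full list is used, with a warning.
#'
#' @param list_a,list_b Ordered character vectors of gene ids, or tibbles
#'   with a `gene_id` column in prioritized order (e.g. from
#'   [aggregate_ranks()]).
#' @param k Head size.
#' @return A list with `overlap` (integer) and `jaccard` (real in
#'   `[0, 1]`).
#' @examples
#' topk_overlap(c("a", "b", "c"), c("a", "c", "d"), k = 2)
#' @export
topk_overlap <- function(list_a, list_b, k) {
  k <- check_count(k, "k")
  ids_a <- if (is.data.frame(list_a)) list_a$gene_id else list_a
  ids_b <- if (is.data.frame(list_b)) list_b$gene_id else list_b
  if (k > length(ids_a) || k > length(ids_b)) {
    warn(sprintf("k = %d exceeds a list length; using full lists", k))
    k <- min(length(ids_a), length(ids_b), k)
  }
  head_a <- head(ids_a, k)
  head_b <- head(ids_b, k)
  ov <- length(intersect(head_a, head_b))
  un <- length(union(head_a, head_b))
  list(overlap = ov, jaccard = if (un == 0) 0 else ov / un)
}

#' Stability of the prioritized list under dataset subsampling
#'
#' Generalizes the question "would fewer datasets have given the same
#' candidates?": for each subset size, `n_replicates` random subsets of
#' datasets are drawn (without replacement within a subset), the
#' aggregation is recomputed on each subset with identical semantics to
#' the full pipeline, and the subset's top-`k` genes are compared with the
#' full-collection top-`k` by overlap and Jaccard index.
#'
#' On collections contaminated by condition-responsive genes the mean
#' overlap grows with subset size — the computational form of the claim
#' that many datasets stabilize the prioritized list.
#'
#' @param collection An expression collection.
#' @param sizes Integer vector of subset sizes to test.
#' @param k Head size compared (default 20).
#' @param n_replicates Random subsets per size (default 50).
#' @param seed Seed for the subset draws.
#' @param stratify_by_condition If `TRUE`, subsets are drawn spread across
#'   condition labels (round-robin over shuffled conditions) so that small
#'   subsets do not drop whole conditions; default unstratified.
#' @return A `stability_curve` object: use [tidy()] for the per-replicate
#'   table (`size`, `rep`, `overlap`, `jaccard`), [glance()] for the
#'   per-size summary with standard errors, [autoplot()] to plot the curve.
#' @export
stability_curve <- function(collection, sizes, k = 20, n_replicates = 50,
                            seed = 1, stratify_by_condition = FALSE) {
  k <- check_count(k, "k")
  n_replicates <- check_count(n_replicates, "n_replicates")
  sizes <- vapply(sizes, check_count, integer(1), field = "sizes")
  ds <- distinct(collection, .data$dataset_id, .data$condition)
  n <- nrow(ds)
  if (any(sizes > n)) {
    abort(sprintf("subset size %d exceeds the %d available datasets",
                  max(sizes), n),
          class = "promrank_config_error")
  }

  # ranks are within-dataset quantities: compute once, reuse per subset
  ranks_long <- rank_datasets(collection)
  full_top <- head(profiles_from_ranks(ranks_long)$gene_id, k)

  draw_subset <- function(size) {
    if (!stratify_by_condition) {
      sample(ds$dataset_id, size)
    } else {
      by_cond <- split(ds$dataset_id, ds$condition)
      by_cond <- lapply(by_cond[sample(names(by_cond))], sample)
      pool <- unlist(lapply(seq_len(max(lengths(by_cond))), function(i) {
        unlist(lapply(by_cond, function(x) if (i <= length(x)) x[i]))
      }), use.names = FALSE)
      pool[seq_len(size)]
    }
  }

  set.seed(substream_seed(seed, 4L))
  reps <- purrr::map(sizes, function(size) {
    purrr::map(seq_len(n_replicates), function(r) {
      ids <- draw_subset(size)
      top <- head(
        profiles_from_ranks(
          ranks_long[ranks_long$dataset_id %in% ids, ])$gene_id, k)
      ov <- topk_overlap(top, full_top, k = k)
      tibble(size = size, rep = r, overlap = ov$overlap,
             jaccard = ov$jaccard)
    }) %>% bind_rows()
  }) %>% bind_rows()

  summary <- reps %>%
    group_by(.data$size) %>%
    summarise(n_replicates = dplyr::n(),
              mean_overlap = mean(.data$overlap),
              se_overlap = stats::sd(.data$overlap) / sqrt(dplyr::n()),
              mean_jaccard = mean(.data$jaccard),
              .groups = "drop")

  structure(list(replicates = reps, summary = summary, k = k,
                 n_datasets = n, seed = seed),
            class = "stability_curve")
}

#' @export
print.stability_curve <- function(x, ...) {
  cat(sprintf("<stability_curve> top-%d overlap with the full %d-dataset list\n",
              x$k, x$n_datasets))
  print(x$summary)
  invisible(x)
}

#' @rdname stability_curve
#' @param x A `stability_curve`.
#' @param ... Unused.
#' @export
tidy.stability_curve <- function(x, ...) x$replicates

#' @rdname stability_curve
#' @export
glance.stability_curve <- function(x, ...) x$summary
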