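#' Apply the constitutive-expression and promoter-space filters
#'
#' Combines rank profiles with upstream-distance records into a candidate
#' table and evaluates the two exclusion filters of the screen:
#'
#' * maximum-rank filter — genes whose worst (largest) rank across the
#'   datasets exceeds `max_rank_threshold` are excluded as not reliably
#'   high (`passes_max_rank`); the boundary value itself passes;
#' * minimum-UTR filter — genes whose upstream intergenic space is shorter
#'   than `min_utr` bp are excluded for lack of regulatory room
#'   (`passes_utr`); the boundary value itself passes.
#'
#' Genes lacking an upstream-distance record are kept in the table,
#' flagged un-annotated (`annotated = FALSE`) and failing the UTR filter,
#' rather than dropped silently.
#'
#' @param profiles Ordered tibble from [aggregate_ranks()].
#' @param utrs Tibble from [compute_upstream_distance()] (or any table
#'   with `gene_id`, `utr_length`).
#' @param max_rank_threshold Worst acceptable maximum rank (default 1000).
#' @param min_utr Minimum upstream intergenic space in bp (default 950).
#' @return A tibble `gene_id`, `min_rank`, `max_rank`, `median_rank`,
#'   `utr_length`, `annotated`, `passes_max_rank`, `passes_utr`, ordered by
#'   ascending median rank (ties: max, min, gene_id).
#' @export
apply_filters <- function(profiles, utrs, max_rank_threshold = 1000,
                          min_utr = 950) {
  if (max_rank_threshold <= 0 || min_utr <= 0) {
    abort("`max_rank_threshold` and `min_utr` must be positive",
          class = "promrank_config_error")
  }
  need <- c("gene_id", "min_rank", "max_rank", "median_rank")
  if (!all(need %in% names(profiles))) {
    abort(paste("`profiles` must have columns:", paste(need, collapse = ", ")),
          class = "promrank_format_error")
  }
  profiles <- profiles[, setdiff(names(profiles), "utr_length")]
  out <- profiles %>%
    left_join(utrs[, c("gene_id", "utr_length")], by = "gene_id") %>%
    mutate(
      annotated = !is.na(.data$utr_length),
      passes_max_rank = .data$max_rank <= max_rank_threshold,
      passes_utr = .data$annotated & .data$utr_length >= min_utr
    ) %>%
    arrange(.data$median_rank, .data$max_rank, .data$min_rank,
            .data$gene_id)
  out
}

#' Select the top candidates passing both filters
#'
#' Marks as selected the first `n` candidates (in the prioritized order)
#' that pass both the maximum-rank and the UTR filter. If fewer than `n`
#' candidates pass, all passing ones are selected with a warning.
#'
#' @param candidates Ordered tibble from [apply_filters()].
#' @param n Number of candidates to select (default 6).
#' @return `candidates` with an added logical column `selected`.
#' @export
select_top <- function(candidates, n = 6) {
  n <- check_count(n, "n")
  passing <- candidates$passes_max_rank & candidates$passes_utr
  sel_idx <- which(passing)
  if (length(sel_idx) < n) {
    warn(sprintf("only %d candidate(s) pass both filters (requested %d)",
                 length(sel_idx), n))
  }
  sel_idx <- head(sel_idx, n)
  mutate(candidates, selected = dplyr::row_number() %in% sel_idx)
}

#' Run the full promoter screen on rank profiles and upstream distances
#'
#' Convenience wrapper producing a `promoter_screen` object:
#' [apply_filters()] then [select_top()], with the parameters recorded for
#' reporting. Use [tidy()] for the per-gene candidate table, [glance()]
#' for the one-row funnel summary (how many genes each filter removed),
#' and [autoplot()] for a filter-space picture.
#'
#' @inheritParams apply_filters
#' @inheritParams select_top
#' @return An object of class `promoter_screen`.
#' @export
screen_promoters <- function(profiles, utrs, max_rank_threshold = 1000,
                             min_utr = 950, n = 6) {
  candidates <- apply_filters(profiles, utrs,
                              max_rank_threshold = max_rank_threshold,
                              min_utr = min_utr)
  candidates <- select_top(candidates, n = n)
  structure(
    list(candidates = candidates,
         params = list(max_rank_threshold = max_rank_threshold,
                       min_utr = min_utr, n = n)),
    class = "promoter_screen"
  )
}

#' @export
print.promoter_screen <- function(x, ...) {
  g <- glance(x)
  cat("<promoter_screen>\n")
  cat(sprintf("  %d genes -> %d pass max-rank <= %g -> %d also pass UTR >= %g bp -> %d selected\n",
              g$n_genes, g$n_pass_max_rank, x$params$max_rank_threshold,
              g$n_pass_both, x$params$min_utr, g$n_selected))
  print(head(filter(x$candidates, .data$selected),
             x$params$n))
  invisible(x)
}

#' @rdname screen_promoters
#' @param x A `promoter_screen`.
#' @param ... Unused.
#' @export
tidy.promoter_screen <- function(x, ...) x$candidates

#' @rdname screen_promoters
#' @export
glance.promoter_screen <- function(x, ...) {
  c <- x$candidates
  tibble(
    n_genes = nrow(c),
    n_pass_max_rank = sum(c$passes_max_rank),
    n_pass_utr = sum(c$passes_utr),
    n_pass_both = sum(c$passes_max_rank & c$passes_utr),
    n_selected = sum(c$selected),
    max_rank_threshold = x$params$max_rank_threshold,
    min_utr = x$params$min_utr
  )
}

#' Write the candidate report and promoter outputs
#'
#' Emits the candidate table as TSV (all columns of [apply_filters()] plus
#' `selected` and, when windows are supplied, `promoter_length`), a BED6
#' and a FASTA of the selected genes' promoter windows, and a JSON run
#' summary with the thresholds and counts. The TSV keeps failing rows up
#' to `depth` times the selection size (counted in passing rows), so the
#' printed head of the list shows the filter pattern around the selected
#' genes; `depth = Inf` keeps every gene.
#'
#' @param screen A `promoter_screen`.
#' @param out_dir Output directory (created if needed).
#' @param windows Optional [promoter_windows()] tibble covering at least
#'   the selected genes.
#' @param seqs Optional [extract_promoter_seqs()] tibble for the selected
#'   genes (required for the FASTA).
#' @param depth Report depth in passing-row multiples of `n` (default 2).
#' @param extra Named list merged into the JSON summary (e.g. seed).
#' @return Invisibly, a named list of written paths.
#' @export
write_report <- function(screen, out_dir, windows = NULL, seqs = NULL,
                         depth = 2, extra = list()) {
  stopifnot(inherits(screen, "promoter_screen"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cand <- screen$candidates

  if (!is.null(windows)) {
    cand <- left_join(cand,
                      tibble(gene_id = windows$gene_id,
                             promoter_length = windows$length),
                      by = "gene_id")
  }
  n_pass_keep <- if (is.finite(depth)) ceiling(depth * screen$params$n) else Inf
  passing_cum <- cumsum(cand$passes_max_rank & cand$passes_utr)
  keep <- passing_cum <= n_pass_keep
  report <- cand[keep | cand$selected, , drop = FALSE]

  tsv_path <- file.path(out_dir, "candidates.tsv")
  readr::write_tsv(report, tsv_path)

  paths <- list(candidates = tsv_path)
  sel <- filter(cand, .data$selected)
  if (!is.null(windows)) {
    w_sel <- windows[windows$gene_id %in% sel$gene_id, , drop = FALSE]
    bed_path <- file.path(out_dir, "promoters.bed")
    score <- sel$median_rank[match(w_sel$gene_id, sel$gene_id)]
    write_promoter_bed(w_sel, bed_path, score = ifelse(is.na(score), 0, score))
    paths$bed <- bed_path
  }
  if (!is.null(seqs)) {
    s_sel <- seqs[seqs$gene_id %in% sel$gene_id, , drop = FALSE]
    fasta_path <- file.path(out_dir, "promoters.fasta")
    write_promoter_fasta(s_sel, fasta_path)
    paths$fasta <- fasta_path
  }

  summary_path <- file.path(out_dir, "run_summary.json")
  summary <- c(list(
    n_genes = nrow(screen$candidates),
    n_datasets = if ("n_datasets" %in% names(cand)) cand$n_datasets[1] else NA,
    n_selected = nrow(sel),
    selected_gene_ids = sel$gene_id,
    max_rank_threshold = screen$params$max_rank_threshold,
    min_utr = screen$params$min_utr,
    top_n = screen$params$n,
    promrank_version = as.character(utils::packageVersion("promrank"))
  ), extra)
  jsonlite::write_json(summary, summary_path, auto_unbox = TRUE, digits = NA)
  paths$summary <- summary_path
  invisible(paths)
}

#' Read a candidate report back from TSV
#'
#' @param path Path written by [write_report()].
#' @return The candidate tibble.
#' @export
read_candidates <- function(path) {
  readr::read_tsv(path, col_types = readr::cols(
    gene_id = readr::col_character(),
    annotated = readr::col_logical(),
    passes_max_rank = readr::col_logical(),
    passes_utr = readr::col_logical(),
    selected = readr::col_logical(),
    .default = readr::col_guess()
  ))
}

#' Curated screen of 13 highly expressed *Aspergillus flavus* genes
#'
#' A small worked-example table: the 13 genes at the head of a published
#' 83-dataset prioritization of *A. flavus*, with their expression-rank
#' summaries (minimum, maximum, median over the datasets), the upstream
#' intergenic space to the next gene, the tested promoter-fragment length
#' for the six genes whose promoters were taken forward (named P1..P6),
#' and the NCBI annotation description.
#'
#' @return A tibble with columns `promoter`, `gene_id`, `min_rank`,
#'   `max_rank`, `median_rank`, `utr_length`, `tested_length`,
#'   `description`.
#' @examples
#' top13 <- aflavus_top13()
#' screen_promoters(top13, top13)
#' @export
aflavus_top13 <- function() {
  path <- system.file("extdata", "aflavus_top13.tsv", package = "promrank")
  readr::read_tsv(path, col_types = readr::cols(
    promoter = readr::col_character(),
    gene_id = readr::col_character(),
    description = readr::col_character(),
    .default = readr::col_double()
  ))
}
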