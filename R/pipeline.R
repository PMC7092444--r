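#' Build or normalise a pipeline configuration
#'
#' A run configuration bundles input paths, thresholds, policies and the
#' seed for [run_pipeline()]. Either `simulate` is a [sim_config()] (the
#' inputs are generated into `out_dir`), or the four input paths are
#' given. Thresholds default to the screen's standard values: maximum
#' rank 1000, minimum upstream space 950 bp, 6 selected genes, 1024 bp
#' promoter target.
#'
#' @param out_dir Output directory.
#' @param matrix_paths,manifest_path,gff3_path,fasta_path Input files
#'   (ignored when `simulate` is given).
#' @param simulate Optional [sim_config()]; when present the synthetic
#'   study is generated under `out_dir/sim` and used as input.
#' @param max_rank_threshold,min_utr,top_n,target_length Screen thresholds.
#' @param universe_policy,replicate_policy,missing_policy Input policies,
#'   see [read_expression_collection()].
#' @param feature_type GFF3 feature type anchoring the promoter (default
#'   `"gene"`).
#' @param stability_sizes Optional integer vector; when set, a
#'   [stability_curve()] over these subset sizes is added to the run.
#' @param stability_k,stability_reps Stability parameters.
#' @param seed Seed for subsampling (and, via `simulate$seed`, generation).
#' @return A `run_config` list.
#' @export
run_config <- function(out_dir,
                       matrix_paths = NULL, manifest_path = NULL,
                       gff3_path = NULL, fasta_path = NULL,
                       simulate = NULL,
                       max_rank_threshold = 1000, min_utr = 950,
                       top_n = 6, target_length = 1024,
                       universe_policy = "require-identical",
                       replicate_policy = "average",
                       missing_policy = "strict",
                       feature_type = "gene",
                       stability_sizes = NULL, stability_k = 20,
                       stability_reps = 50,
                       seed = 1) {
  cfg <- list(
    out_dir = out_dir,
    matrix_paths = matrix_paths, manifest_path = manifest_path,
    gff3_path = gff3_path, fasta_path = fasta_path,
    simulate = simulate,
    max_rank_threshold = check_number(max_rank_threshold, "max_rank_threshold", min = 1),
    min_utr = check_number(min_utr, "min_utr", min = 1),
    top_n = check_count(top_n, "top_n"),
    target_length = check_count(target_length, "target_length"),
    universe_policy = universe_policy,
    replicate_policy = replicate_policy,
    missing_policy = missing_policy,
    feature_type = feature_type,
    stability_sizes = stability_sizes,
    stability_k = check_count(stability_k, "stability_k"),
    stability_reps = check_count(stability_reps, "stability_reps"),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (is.null(simulate) &&
      (is.null(matrix_paths) || is.null(manifest_path) ||
       is.null(gff3_path) || is.null(fasta_path))) {
    abort("either `simulate` or all four input paths must be given",
          class = "promrank_config_error")
  }
  if (!is.null(simulate)) stopifnot(inherits(simulate, "sim_config"))
  structure(cfg, class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML mirrors the arguments of [run_config()]; a `simulate:` block
#' holds [sim_config()] fields.
#'
#' @param path YAML file.
#' @param out_dir Optional override of the configured output directory.
#' @return A `run_config`.
#' @export
read_run_config <- function(path, out_dir = NULL) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$simulate)) y$simulate <- do.call(sim_config, y$simulate)
  if (!is.null(out_dir)) y$out_dir <- out_dir
  do.call(run_config, y)
}

#' Run the full prioritization pipeline
#'
#' simulate (optional) -> read -> rank -> annotate -> filter/select ->
#' promoter extraction -> report, plus an optional stability analysis.
#' Each stage logs one line of counts so the funnel from all genes down to
#' the selected candidates is visible; any stage error is re-raised with
#' the stage name and nothing is written for failed runs (the report is
#' written last).
#'
#' @param config A [run_config()] (or YAML path understood by
#'   [read_run_config()]).
#' @return Invisibly, a list with the `screen`, `profiles`, `utrs`,
#'   `stability` (or `NULL`) objects, the written `paths`, and an
#'   `artifact` tibble of output files with md5 checksums (also written as
#'   `manifest.json`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- read_run_config(config)
  stopifnot(inherits(config, "run_config"))

  truth <- NULL
  if (!is.null(config$simulate)) {
    study <- with_stage("simulate",
                        simulate_study(config$simulate,
                                       file.path(config$out_dir, "sim")))
    config$matrix_paths <- study$matrix
    config$manifest_path <- study$manifest
    config$gff3_path <- study$gff3
    config$fasta_path <- study$fasta
    truth <- study$truth_obj
    inform(sprintf("simulate: %d genes x %d datasets written under %s",
                   config$simulate$n_genes, config$simulate$n_datasets,
                   file.path(config$out_dir, "sim")))
  }

  collection <- with_stage("read", {
    for (p in c(config$matrix_paths, config$manifest_path)) {
      if (!file.exists(p)) abort(sprintf("input file '%s' not found", p))
    }
    read_expression_collection(config$matrix_paths, config$manifest_path,
                               universe_policy = config$universe_policy,
                               replicate_policy = config$replicate_policy,
                               missing_policy = config$missing_policy)
  })
  inform(sprintf("read: %d datasets, %d universe genes",
                 length(unique(collection$dataset_id)),
                 length(collection_universe(collection))))

  profiles <- with_stage("rank", aggregate_ranks(collection))
  inform(sprintf("rank: %d rank profiles aggregated", nrow(profiles)))

  ann <- with_stage("annotate", {
    for (p in c(config$gff3_path, config$fasta_path)) {
      if (!file.exists(p)) abort(sprintf("input file '%s' not found", p))
    }
    features <- read_gene_features(config$gff3_path,
                                   feature_type = config$feature_type)
    lens <- attr(features, "contig_lengths")
    if (is.null(lens) || any(is.na(lens))) {
      lens <- read_contig_lengths(config$fasta_path)
    }
    utrs <- compute_upstream_distance(features, lens)
    list(features = features, utrs = utrs)
  })
  inform(sprintf("annotate: %d gene features, %d at contig edges",
                 nrow(ann$features), sum(ann$utrs$at_contig_edge)))

  screen <- with_stage("prioritize",
                       screen_promoters(profiles, ann$utrs,
                                        max_rank_threshold = config$max_rank_threshold,
                                        min_utr = config$min_utr,
                                        n = config$top_n))
  g <- glance(screen)
  inform(sprintf("prioritize: %d genes -> %d pass max-rank -> %d pass both -> %d selected",
                 g$n_genes, g$n_pass_max_rank, g$n_pass_both, g$n_selected))

  prom <- with_stage("extract", {
    sel <- filter(screen$candidates, .data$selected)
    f_sel <- ann$features[ann$features$gene_id %in% sel$gene_id, ]
    u_sel <- ann$utrs[ann$utrs$gene_id %in% sel$gene_id, ]
    windows <- promoter_windows(f_sel, u_sel,
                                target_length = config$target_length)
    seqs <- extract_promoter_seqs(windows, config$fasta_path)
    list(windows = windows, seqs = seqs)
  })

  stability <- NULL
  if (!is.null(config$stability_sizes)) {
    stability <- with_stage("stability",
                            stability_curve(collection,
                                            sizes = config$stability_sizes,
                                            k = config$stability_k,
                                            n_replicates = config$stability_reps,
                                            seed = config$seed))
    inform(sprintf("stability: sizes %s, k=%d, %d replicates",
                   paste(config$stability_sizes, collapse = "/"),
                   config$stability_k, config$stability_reps))
  }

  paths <- with_stage("report", {
    dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
    ranks_path <- file.path(config$out_dir, "ranks.tsv")
    write_rank_table(collection, ranks_path)
    p <- write_report(screen, config$out_dir,
                      windows = prom$windows, seqs = prom$seqs,
                      extra = list(seed = config$seed))
    p$ranks <- ranks_path
    if (!is.null(stability)) {
      rep_path <- file.path(config$out_dir, "stability_replicates.tsv")
      sum_path <- file.path(config$out_dir, "stability_summary.tsv")
      readr::write_tsv(tidy(stability), rep_path)
      readr::write_tsv(glance(stability), sum_path)
      p$stability_replicates <- rep_path
      p$stability_summary <- sum_path
    }
    p
  })

  files <- unlist(paths, use.names = FALSE)
  artifact <- tibble(file = basename(files),
                     md5 = unname(tools::md5sum(files)))
  jsonlite::write_json(artifact, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(screen = screen, profiles = profiles, utrs = ann$utrs,
                 stability = stability, truth = truth, paths = paths,
                 artifact = artifact))
}
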