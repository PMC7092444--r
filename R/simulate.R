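#' Simulate a multi-dataset expression collection with planted constitutive genes
#'
#' Draws log-intensities under the generative model described in
#' [sim_config()]: planted genes sit at a constant high mean with no
#' condition effect, all other genes combine a baseline mean (truncated
#' below the planted level), a per-condition effect shared by datasets of
#' the same condition, and independent per-sample noise. Every dataset
#' contains every gene.
#'
#' @param config A [sim_config()].
#' @return A list with
#'   * `collection`: a tidy expression collection — one row per
#'     (dataset, gene) with columns `dataset_id`, `condition`, `gene_id`,
#'     `intensity` (see [as_expression_collection()]);
#'   * `truth`: a `sim_truth` list carrying `constitutive_gene_ids`, the
#'     per-gene baseline means and the dataset-to-condition assignment.
#' @examples
#' sim <- simulate_expression(sim_config(n_genes = 50, n_datasets = 4,
#'                                       n_conditions = 2, n_constitutive = 3,
#'                                       seed = 1))
#' dplyr::count(sim$collection, dataset_id)
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  dataset_ids <- sprintf("ds%03d", seq_len(config$n_datasets))
  condition_ids <- sprintf("cond%02d", seq_len(config$n_conditions))
  cond_of <- condition_ids[((seq_len(config$n_datasets) - 1L) %%
                              config$n_conditions) + 1L]

  set.seed(substream_seed(config$seed, 1L))
  planted <- sort(sample(gene_ids, config$n_constitutive))
  is_planted <- gene_ids %in% planted

  # baseline means, rejection-sampled to stay strictly below mu_high so the
  # planted genes separate exactly in the zero-noise limit
  mu <- numeric(config$n_genes)
  mu[is_planted] <- config$mu_high
  n_base <- config$n_genes - config$n_constitutive
  base <- rnorm(n_base, config$mu_base_mean, config$mu_base_sd)
  while (any(bad <- base >= config$mu_high)) {
    base[bad] <- rnorm(sum(bad), config$mu_base_mean, config$mu_base_sd)
  }
  mu[!is_planted] <- base

  beta <- matrix(rnorm(config$n_genes * config$n_conditions,
                       0, config$tau_condition),
                 nrow = config$n_genes)
  beta[is_planted, ] <- 0

  cond_idx <- match(cond_of, condition_ids)
  x <- vapply(seq_len(config$n_datasets), function(d) {
    mu + beta[, cond_idx[d]] +
      rnorm(config$n_genes, 0, config$sigma_noise)
  }, numeric(config$n_genes))

  collection <- tibble(
    dataset_id = rep(dataset_ids, each = config$n_genes),
    condition = rep(cond_of, each = config$n_genes),
    gene_id = rep(gene_ids, times = config$n_datasets),
    intensity = as.vector(x)
  )
  collection <- as_expression_collection(collection)

  truth <- structure(
    list(
      constitutive_gene_ids = planted,
      baseline_mu = tibble(gene_id = gene_ids, mu = mu),
      dataset_conditions = tibble(dataset_id = dataset_ids,
                                  condition = cond_of),
      config = config
    ),
    class = "sim_truth"
  )
  list(collection = collection, truth = truth)
}

#' Simulate genome geometry: gene placements and true upstream distances
#'
#' Places genes sequentially along contigs (an equal share of genes per
#' contig) with intergenic gaps drawn from the configured short/long
#' mixture, random strands, and a 500 bp tail after the last gene of each
#' contig. The true upstream intergenic distance of every gene is recorded
#' as placed, using the same strand-aware convention as
#' [compute_upstream_distance()]: for a `+` gene the gap back to the
#' previous gene body, for a `-` gene the gap forward to the next one;
#' genes with no upstream neighbor get the distance to the contig edge and
#' an edge flag.
#'
#' @param config A [sim_config()].
#' @return A list with `features` (tibble: `gene_id`, `contig`, `start`,
#'   `end`, `strand`; 1-based inclusive), `utrs` (tibble: `gene_id`,
#'   `utr_length`, `upstream_neighbor_id`, `at_contig_edge`) and
#'   `contig_lengths` (named integer vector).
#' @export
simulate_geometry <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gene_ids <- sprintf("g%05d", seq_len(config$n_genes))
  per_contig <- ceiling(config$n_genes / config$n_contigs)
  contig_of <- rep(seq_len(config$n_contigs), each = per_contig)[
    seq_len(config$n_genes)]

  set.seed(substream_seed(config$seed, 2L))
  feats <- vector("list", config$n_contigs)
  utrs <- vector("list", config$n_contigs)
  contig_lengths <- integer(0)
  for (ct in unique(contig_of)) {
    ids <- gene_ids[contig_of == ct]
    n <- length(ids)
    long <- runif(n) < config$gap_fraction_long
    gaps <- as.integer(ifelse(long,
                   round(runif(n, config$gap_long_range[1], config$gap_long_range[2])),
                   round(runif(n, config$gap_short_range[1], config$gap_short_range[2]))))
    lens <- as.integer(pmax(300, round(rnorm(n, config$gene_len_mean,
                                             0.2 * config$gene_len_mean))))
    strands <- sample(c("+", "-"), n, replace = TRUE)
    start <- integer(n); end <- integer(n)
    pos <- 0L
    for (i in seq_len(n)) {
      start[i] <- pos + gaps[i] + 1L
      end[i] <- start[i] + lens[i] - 1L
      pos <- end[i]
    }
    contig_name <- sprintf("ctg%02d", ct)
    contig_len <- end[n] + 500L
    contig_lengths[contig_name] <- contig_len

    utr <- integer(n); neighbor <- rep(NA_character_, n); edge <- logical(n)
    for (i in seq_len(n)) {
      if (strands[i] == "+") {
        if (i == 1L) {
          utr[i] <- start[i] - 1L; edge[i] <- TRUE
        } else {
          utr[i] <- start[i] - end[i - 1L] - 1L; neighbor[i] <- ids[i - 1L]
        }
      } else {
        if (i == n) {
          utr[i] <- contig_len - end[i]; edge[i] <- TRUE
        } else {
          utr[i] <- start[i + 1L] - end[i] - 1L; neighbor[i] <- ids[i + 1L]
        }
      }
    }
    feats[[ct]] <- tibble(gene_id = ids, contig = contig_name,
                          start = start, end = end, strand = strands)
    utrs[[ct]] <- tibble(gene_id = ids, utr_length = utr,
                         upstream_neighbor_id = neighbor,
                         at_contig_edge = edge)
  }
  list(features = bind_rows(feats), utrs = bind_rows(utrs),
       contig_lengths = contig_lengths)
}

#' Write a synthetic genome (FASTA) and annotation (GFF3)
#'
#' Emits uniform-random A/C/G/T contig sequences for the geometry produced
#' by [simulate_geometry()] and a GFF3 with one `gene` feature per gene
#' (1-based inclusive coordinates, `ID` attribute, `##sequence-region`
#' directives). Sequence content is deliberately unstructured: only lengths
#' and coordinates matter downstream.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @param geometry Optional result of [simulate_geometry()]; computed from
#'   `config` when omitted.
#' @return A list with `fasta`, `gff3` (paths) and `geometry`.
#' @export
simulate_genome <- function(config, dir, geometry = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (is.null(geometry)) geometry <- simulate_geometry(config)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  set.seed(substream_seed(config$seed, 3L))
  seqs <- vapply(names(geometry$contig_lengths), function(ct) {
    paste(sample(c("A", "C", "G", "T"), geometry$contig_lengths[[ct]],
                 replace = TRUE), collapse = "")
  }, character(1))
  fasta_path <- file.path(dir, "genome.fasta")
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), fasta_path)

  gff3_path <- file.path(dir, "annotation.gff3")
  gr <- GenomicRanges::GRanges(
    seqnames = geometry$features$contig,
    ranges = IRanges::IRanges(geometry$features$start, geometry$features$end),
    strand = geometry$features$strand,
    seqlengths = geometry$contig_lengths
  )
  S4Vectors::mcols(gr)$source <- "promrank"
  S4Vectors::mcols(gr)$type <- "gene"
  S4Vectors::mcols(gr)$ID <- geometry$features$gene_id
  rtracklayer::export(gr, gff3_path, format = "gff3")

  # normalise the header: drop run-dependent comment lines, add
  # sequence-region directives so contig lengths travel with the file
  lines <- readLines(gff3_path)
  body <- lines[!startsWith(lines, "##")]
  regions <- sprintf("##sequence-region %s 1 %d",
                     names(geometry$contig_lengths),
                     unname(geometry$contig_lengths))
  writeLines(c("##gff-version 3", regions, body), gff3_path)

  list(fasta = fasta_path, gff3 = gff3_path, geometry = geometry)
}

#' Generate a complete synthetic study on disk
#'
#' One call writes everything the pipeline consumes: an intensity matrix
#' (TSV, genes x samples), a sample manifest (TSV: `sample_id`,
#' `dataset_id`, `condition`), the genome FASTA, the GFF3 annotation, and a
#' JSON ground-truth file naming the planted constitutive genes and the
#' true gene coordinates and upstream distances.
#'
#' @param config A [sim_config()].
#' @param dir Output directory.
#' @return Invisibly, a named list of file paths plus the in-memory
#'   `collection`, `truth` and `geometry` objects.
#' @export
simulate_study <- function(config, dir) {
  sim <- simulate_expression(config)
  genome <- simulate_genome(config, dir)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)

  matrix_path <- file.path(dir, "expression_matrix.tsv")
  manifest_path <- file.path(dir, "sample_manifest.tsv")
  paths <- write_expression_collection(sim$collection, matrix_path,
                                       manifest_path)

  truth_path <- file.path(dir, "truth.json")
  truth_json <- list(
    constitutive_gene_ids = sim$truth$constitutive_gene_ids,
    gene_coordinates = genome$geometry$features,
    utr_lengths = genome$geometry$utrs,
    seed = config$seed
  )
  jsonlite::write_json(truth_json, truth_path, auto_unbox = TRUE, digits = NA)

  invisible(list(
    matrix = matrix_path, manifest = manifest_path,
    fasta = genome$fasta, gff3 = genome$gff3, truth = truth_path,
    collection = sim$collection,
    truth_obj = sim$truth, geometry = genome$geometry
  ))
}

#' @export
print.sim_truth <- function(x, ...) {
  cat("<sim_truth>\n")
  cat(sprintf("  %d planted constitutive genes of %d; %d datasets\n",
              length(x$constitutive_gene_ids), nrow(x$baseline_mu),
              nrow(x$dataset_conditions)))
  invisible(x)
}
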