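# Shared fixtures and independent oracles, built in code at test time.

small_config <- function(seed = 1, ...) {
  args <- list(n_genes = 120, n_datasets = 6, n_conditions = 3,
               n_constitutive = 4, n_contigs = 2, seed = seed)
  args[names(list(...))] <- list(...)
  do.call(sim_config, args)
}

# hand-built tiny collection: intensities chosen so ranks are forced
toy_collection <- function() {
  as_expression_collection(tibble::tibble(
    dataset_id = rep(c("d1", "d2", "d3"), each = 3),
    condition = rep(c("c1", "c1", "c2"), each = 3),
    gene_id = rep(c("a", "b", "c"), 3),
    intensity = c(10, 7.5, 9.9,   1, 3, 2,   5, 4, 4.5)
  ))
}

# Independent brute-force rank aggregation: sorts intensities per dataset
# with the same documented tie-break, then takes order statistics of the
# per-gene rank vectors by explicit sorting. No promrank code paths.
brute_force_profiles <- function(collection) {
  datasets <- unique(collection$dataset_id)
  genes <- sort(unique(collection$gene_id))
  rank_mat <- matrix(NA_real_, nrow = length(genes), ncol = length(datasets),
                     dimnames = list(genes, datasets))
  for (d in datasets) {
    sub <- collection[collection$dataset_id == d, ]
    ord <- sub$gene_id[order(-sub$intensity, sub$gene_id)]
    rank_mat[ord, d] <- seq_along(ord)
  }
  prof <- data.frame(gene_id = genes,
                     min_rank = NA_real_, max_rank = NA_real_,
                     median_rank = NA_real_)
  for (i in seq_along(genes)) {
    r <- sort(rank_mat[i, ])
    n <- length(r)
    med <- if (n %% 2 == 1) r[(n + 1) / 2] else (r[n / 2] + r[n / 2 + 1]) / 2
    prof$min_rank[i] <- r[1]
    prof$max_rank[i] <- r[n]
    prof$median_rank[i] <- med
  }
  prof[order(prof$median_rank, prof$max_rank, prof$min_rank, prof$gene_id), ]
}

# write a small hand-specified genome + annotation to temp files
write_tiny_genome <- function(genes, contig_seqs) {
  fasta <- tempfile(fileext = ".fasta")
  writeLines(unlist(lapply(names(contig_seqs), function(ct) {
    c(paste0(">", ct), contig_seqs[[ct]])
  })), fasta)
  gff3 <- tempfile(fileext = ".gff3")
  header <- c("##gff-version 3",
              sprintf("##sequence-region %s 1 %d", names(contig_seqs),
                      nchar(contig_seqs)))
  rows <- sprintf("%s\ttest\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  genes$contig, genes$start, genes$end, genes$strand,
                  genes$gene_id)
  writeLines(c(header, rows), gff3)
  list(fasta = fasta, gff3 = gff3)
}

random_seq <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                                collapse = "")
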