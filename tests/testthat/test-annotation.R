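tiny <- function() {
  genes <- tibble::tibble(
    gene_id = c("gA", "gB"),
    contig = "ctg1",
    start = c(101, 501), end = c(300, 900),
    strand = c("+", "-"))
  write_tiny_genome(genes, c(ctg1 = random_seq(2000)))
}

test_that("GFF3 gene features are read, typed and sorted", {
  files <- tiny()
  feats <- read_gene_features(files$gff3)
  expect_equal(feats$gene_id, c("gA", "gB"))
  expect_equal(feats$start, c(101, 501))
  expect_equal(attr(feats, "contig_lengths"), c(ctg1 = 2000L))

  expect_error(read_gene_features(files$gff3, feature_type = "mRNA"),
               "mRNA", class = "promrank_format_error")

  no_id <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3", "ctg1\tt\tgene\t1\t10\t.\t+\t.\tName=x"),
             no_id)
  expect_error(read_gene_features(no_id), "ID",
               class = "promrank_format_error")
})

test_that("upstream distance follows the strand-aware intergenic convention", {
  genes <- tibble::tibble(
    gene_id = c("up", "plus", "minus", "next"),
    contig = "ctg1",
    start = c(3001, 5000, 7100, 8868),
    end = c(3800, 6000, 7900, 9500),
    strand = c("+", "+", "-", "+"))
  utr <- compute_upstream_distance(genes, c(ctg1 = 12000))
  # + gene at [5000,6000] with nearest upstream end 3800 -> 5000-3800-1
  expect_equal(utr$utr_length[utr$gene_id == "plus"], 1199)
  expect_equal(utr$upstream_neighbor_id[utr$gene_id == "plus"], "up")
  # - gene at [7100,7900] with next start 8868 -> 8868-7900-1 = 967
  expect_equal(utr$utr_length[utr$gene_id == "minus"], 967)
  expect_equal(utr$upstream_neighbor_id[utr$gene_id == "minus"], "next")
  # first + gene on the contig: distance to the edge, flagged
  expect_equal(utr$utr_length[utr$gene_id == "up"], 3000)
  expect_true(utr$at_contig_edge[utr$gene_id == "up"])
  expect_identical(is.na(utr$upstream_neighbor_id), utr$at_contig_edge)

  lone <- tibble::tibble(gene_id = "solo", contig = "c", start = 501,
                         end = 900, strand = "+")
  u <- compute_upstream_distance(lone, c(c = 1500))
  expect_equal(u$utr_length, 500)
  expect_true(u$at_contig_edge)

  overlap <- tibble::tibble(
    gene_id = c("o1", "o2"), contig = "c",
    start = c(100, 350), end = c(400, 800), strand = c("+", "+"))
  u2 <- compute_upstream_distance(overlap, c(c = 1000))
  expect_equal(u2$utr_length[u2$gene_id == "o2"], 0)
  expect_equal(u2$upstream_neighbor_id[u2$gene_id == "o2"], "o1")
})

test_that("promoter windows cap at the intergenic space and abut the 5' end", {
  genes <- tibble::tibble(
    gene_id = c("cap", "room"), contig = c("c1", "c2"),
    start = c(7000, 8000), end = c(8000, 9000), strand = "+")
  utrs <- tibble::tibble(gene_id = c("cap", "room"),
                         utr_length = c(967, 6093),
                         upstream_neighbor_id = NA, at_contig_edge = FALSE)
  w <- promoter_windows(genes, utrs, target_length = 1024)
  expect_equal(w$length[w$gene_id == "cap"], 967)
  expect_equal(w$length[w$gene_id == "room"], 1024)
  # 0-based half-open window ends flush at start - 1
  expect_equal(w$end, c(7000, 8000) - 1)
  expect_equal(w$end - w$start, w$length)

  # per-gene override allows a longer tested fragment than the default
  w2 <- promoter_windows(genes, utrs, target_length = 1024,
                         target_overrides = tibble::tibble(
                           gene_id = "room", target_length = 1029))
  expect_equal(w2$length[w2$gene_id == "room"], 1029)

  empty <- promoter_windows(
    tibble::tibble(gene_id = "z", contig = "c", start = 500, end = 600,
                   strand = "-"),
    tibble::tibble(gene_id = "z", utr_length = 0))
  expect_true(empty$is_empty)
  expect_equal(empty$length, 0)
})

test_that("sequence extraction reads 5'->3' toward the start codon", {
  files <- write_tiny_genome(
    tibble::tibble(gene_id = "g", contig = "ctg1", start = 5, end = 6,
                   strand = "+"),
    c(ctg1 = "AAACGT"))
  w <- tibble::tibble(gene_id = "g", contig = "ctg1", start = 1, end = 4,
                      strand = "+", length = 3, is_empty = FALSE)
  expect_equal(extract_promoter_seqs(w, files$fasta)$sequence, "AAC")
  w_minus <- dplyr::mutate(w, strand = "-")
  expect_equal(extract_promoter_seqs(w_minus, files$fasta)$sequence, "GTT")

  oob <- dplyr::mutate(w, end = 99)
  expect_error(extract_promoter_seqs(oob, files$fasta), "bounds",
               class = "promrank_reference_error")
})

test_that("opposite-strand extraction is the reverse complement, over random genes", {
  cfg <- small_config(seed = 21, n_genes = 100)
  dir <- tempfile()
  g <- simulate_genome(cfg, dir)
  utrs <- compute_upstream_distance(g$geometry$features,
                                    g$geometry$contig_lengths)
  w <- promoter_windows(g$geometry$features, utrs, target_length = 200)
  w <- w[!w$is_empty, ][1:100, ]
  fwd <- extract_promoter_seqs(w, g$fasta)
  flip <- extract_promoter_seqs(
    dplyr::mutate(w, strand = ifelse(strand == "+", "-", "+")), g$fasta)
  revcomp <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(flip$sequence)))
  expect_equal(fwd$sequence, unname(revcomp))
})

test_that("synthetic genome files round-trip through the annotation parser", {
  cfg <- small_config(seed = 31)
  g <- simulate_genome(cfg, tempfile())
  feats <- read_gene_features(g$gff3)
  expect_equal(as.data.frame(feats)[, 1:5],
               as.data.frame(g$geometry$features)[, 1:5])
  expect_equal(attr(feats, "contig_lengths"),
               g$geometry$contig_lengths)
  utr <- compute_upstream_distance(feats)
  truth <- g$geometry$utrs
  expect_identical(utr$utr_length[match(truth$gene_id, utr$gene_id)],
                   truth$utr_length)
  # FASTA lengths agree with the GFF3 sequence-region directives
  expect_equal(read_contig_lengths(g$fasta),
               g$geometry$contig_lengths[names(read_contig_lengths(g$fasta))])
})

test_that("windows never overlap any gene body and BED/FASTA outputs are consistent", {
  cfg <- small_config(seed = 41)
  g <- simulate_genome(cfg, tempfile())
  feats <- g$geometry$features
  utrs <- compute_upstream_distance(feats, g$geometry$contig_lengths)
  w <- promoter_windows(feats, utrs)
  # compare every non-empty window against every gene body on its contig
  gr_w <- GenomicRanges::GRanges(w$contig[!w$is_empty],
                                 IRanges::IRanges(w$start[!w$is_empty] + 1,
                                                  w$end[!w$is_empty]))
  gr_g <- GenomicRanges::GRanges(feats$contig,
                                 IRanges::IRanges(feats$start, feats$end))
  expect_equal(sum(GenomicRanges::countOverlaps(gr_w, gr_g)), 0)
  expect_true(all(w$length <= 1024))
  short <- utrs$utr_length < 1024
  expect_equal(w$length[short], utrs$utr_length[short])

  sel <- w[!w$is_empty, ][1:5, ]
  seqs <- extract_promoter_seqs(sel, g$fasta)
  fasta_path <- tempfile(fileext = ".fasta")
  write_promoter_fasta(seqs, fasta_path)
  back <- Biostrings::readDNAStringSet(fasta_path)
  expect_equal(unname(Biostrings::width(back)), sel$length)
  expect_true(all(grepl("\\|len=\\d+$", names(back))))

  bed_path <- tempfile(fileext = ".bed")
  write_promoter_bed(sel, bed_path, score = 1:5)
  bed <- rtracklayer::import(bed_path)
  expect_equal(GenomicRanges::start(bed) - 1L, sel$start)  # BED is 0-based
  expect_equal(GenomicRanges::end(bed), sel$end)
  expect_equal(bed$name, sel$gene_id)
})
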