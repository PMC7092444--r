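fake_profiles <- function(max_rank, utr) {
  n <- length(max_rank)
  list(
    profiles = tibble::tibble(gene_id = sprintf("g%02d", seq_len(n)),
                              min_rank = 1, max_rank = max_rank,
                              median_rank = seq_len(n)),
    utrs = tibble::tibble(gene_id = sprintf("g%02d", seq_len(n)),
                          utr_length = utr)
  )
}

test_that("filter boundaries are inclusive: max rank 1000 and UTR 950 pass", {
  f <- fake_profiles(max_rank = c(1000, 1001, 10), utr = c(950, 2000, 949))
  cand <- apply_filters(f$profiles, f$utrs)
  expect_true(cand$passes_max_rank[cand$gene_id == "g01"])
  expect_true(cand$passes_utr[cand$gene_id == "g01"])
  expect_false(cand$passes_max_rank[cand$gene_id == "g02"])
  expect_false(cand$passes_utr[cand$gene_id == "g03"])
  expect_error(apply_filters(f$profiles, f$utrs, max_rank_threshold = 0),
               class = "promrank_config_error")
})

test_that("genes without annotation are kept, flagged, and fail the UTR filter", {
  f <- fake_profiles(max_rank = c(5, 6), utr = 1500)
  cand <- apply_filters(f$profiles, f$utrs[1, ])
  expect_equal(nrow(cand), 2)
  expect_false(cand$annotated[cand$gene_id == "g02"])
  expect_false(cand$passes_utr[cand$gene_id == "g02"])
})

test_that("the 13-gene worked example selects exactly the six named promoters", {
  top13 <- aflavus_top13()
  screen <- screen_promoters(top13, top13)
  cand <- tidy(screen)
  sel <- cand[cand$selected, ]
  expect_equal(nrow(sel), 6)
  # the six promoter-named genes, and only those, are selected
  named <- top13$gene_id[!is.na(top13$promoter)]
  expect_setequal(sel$gene_id, named)
  # selection order follows ascending median rank with the documented tie-break
  expect_equal(sel$median_rank, sort(sel$median_rank))
  expect_equal(sel$gene_id,
               c("AFLA_090780", "AFLA_014570", "AFLA_025100",
                 "AFLA_113120", "AFLA_052860", "AFLA_030930"))
  # a gene passing both filters but ranked 7th is not selected
  also_passing <- cand[cand$gene_id == "AFLA_006300", ]
  expect_true(also_passing$passes_max_rank & also_passing$passes_utr)
  expect_false(also_passing$selected)
})

test_that("selection handles degenerate candidate sets", {
  f <- fake_profiles(max_rank = c(2000, 3000), utr = c(10, 20))
  cand <- apply_filters(f$profiles, f$utrs)
  expect_warning(sel <- select_top(cand, n = 6), "0 candidate")
  expect_equal(sum(sel$selected), 0)

  f2 <- fake_profiles(max_rank = c(10, 20, 3000), utr = c(1000, 1000, 1000))
  cand2 <- apply_filters(f2$profiles, f2$utrs)
  expect_warning(sel2 <- select_top(cand2, n = 6), "only 2")
  expect_equal(sum(sel2$selected), 2)
  # selected set is a prefix of the passing-ordered list
  pass_idx <- which(sel2$passes_max_rank & sel2$passes_utr)
  expect_equal(which(sel2$selected), pass_idx[1:2])
  expect_error(select_top(cand2, n = 0), class = "promrank_config_error")
})

test_that("the report round-trips and degenerate reports stay valid", {
  top13 <- aflavus_top13()
  screen <- screen_promoters(top13, top13)
  dir <- tempfile()
  paths <- write_report(screen, dir, depth = Inf)
  back <- read_candidates(paths$candidates)
  expect_equal(as.data.frame(back), as.data.frame(tidy(screen)))

  g <- glance(screen)
  expect_equal(g$n_selected, 6)
  expect_equal(g$n_pass_both, 7)
  summary <- jsonlite::read_json(paths$summary)
  expect_equal(summary$n_selected, 6)

  # all-failing screen: header-only TSV and a valid empty FASTA
  f <- fake_profiles(max_rank = 5000, utr = 10)
  suppressWarnings(empty_screen <- screen_promoters(f$profiles, f$utrs))
  w0 <- tibble::tibble(gene_id = character(), contig = character(),
                       start = integer(), end = integer(),
                       strand = character(), length = integer(),
                       is_empty = logical(), sequence = character())
  p0 <- write_report(empty_screen, tempfile(), windows = w0, seqs = w0)
  tab <- readr::read_tsv(p0$candidates, show_col_types = FALSE)
  expect_equal(nrow(tab), 1)  # the single failing gene, unselected
  expect_equal(sum(tab$selected), 0)
  expect_length(Biostrings::readDNAStringSet(p0$fasta), 0)
})

test_that("a selected gene with a short upstream gap yields a capped FASTA record", {
  # UTR 967 with target 1024 -> the written promoter is 967 bp
  genes <- tibble::tibble(gene_id = "hsp", contig = "c1", start = 2000,
                          end = 3000, strand = "+")
  utrs <- tibble::tibble(gene_id = "hsp", utr_length = 967,
                         upstream_neighbor_id = NA, at_contig_edge = FALSE)
  files <- write_tiny_genome(genes, c(c1 = random_seq(4000)))
  profiles <- tibble::tibble(gene_id = "hsp", min_rank = 1, max_rank = 10,
                             median_rank = 3)
  screen <- screen_promoters(profiles, utrs, n = 1)
  w <- promoter_windows(genes, utrs, target_length = 1024)
  s <- extract_promoter_seqs(w, files$fasta)
  paths <- write_report(screen, tempfile(), windows = w, seqs = s)
  rec <- Biostrings::readDNAStringSet(paths$fasta)
  expect_equal(unname(Biostrings::width(rec)), 967)
})

test_that("tidy, glance and autoplot methods behave", {
  top13 <- aflavus_top13()
  screen <- screen_promoters(top13, top13)
  expect_s3_class(tidy(screen), "tbl_df")
  expect_equal(nrow(glance(screen)), 1)
  p <- autoplot(screen)
  expect_s3_class(p, "ggplot")
})
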