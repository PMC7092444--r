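#' Read gene features from a GFF3 file
#'
#' Imports the annotation, keeps features of the requested type and
#' returns them as a tibble of 1-based inclusive intervals, ordered by
#' (contig, start). Contig lengths found in `##sequence-region`
#' directives are attached as the `contig_lengths` attribute; when the
#' file lacks them, supply lengths from the companion FASTA via
#' [read_contig_lengths()].
#'
#' @param gff3_path Path to a GFF3 file.
#' @param feature_type Feature type to keep (default `"gene"`; use
#'   `"CDS"` to anchor promoters at the start codon where the annotation
#'   provides per-gene CDS features).
#' @return A tibble `gene_id`, `contig`, `start`, `end`, `strand` with
#'   attribute `contig_lengths` (named vector, possibly `NA`).
#' @export
read_gene_features <- function(gff3_path, feature_type = "gene") {
  gr <- tryCatch(
    rtracklayer::import(gff3_path, format = "gff3",
                        sequenceRegionsAsSeqinfo = TRUE),
    # files without ##sequence-region directives import without seqinfo
    error = function(e) rtracklayer::import(gff3_path, format = "gff3"))
  keep <- as.character(S4Vectors::mcols(gr)$type) == feature_type
  if (!any(keep)) {
    abort(sprintf("no features of type '%s' in '%s'", feature_type, gff3_path),
          class = "promrank_format_error")
  }
  gr <- gr[keep]
  ids <- S4Vectors::mcols(gr)$ID
  if (is.null(ids) || any(is.na(ids) | ids == "")) {
    abort("every feature needs an ID attribute", class = "promrank_format_error")
  }
  strands <- as.character(GenomicRanges::strand(gr))
  if (any(!strands %in% c("+", "-"))) {
    abort("feature strands must be '+' or '-'", class = "promrank_format_error")
  }
  out <- tibble(
    gene_id = as.character(ids),
    contig = as.character(GenomicRanges::seqnames(gr)),
    start = GenomicRanges::start(gr),
    end = GenomicRanges::end(gr),
    strand = strands
  ) %>% arrange(.data$contig, .data$start, .data$gene_id)
  attr(out, "contig_lengths") <- GenomeInfoDb::seqlengths(gr)
  out
}

#' Contig lengths from a FASTA file
#'
#' @param fasta_path Path to a (possibly multi-record) FASTA file.
#' @return Named integer vector of sequence lengths; names are truncated at
#'   the first whitespace, matching GFF3 contig names.
#' @export
read_contig_lengths <- function(fasta_path) {
  lens <- Biostrings::fasta.seqlengths(fasta_path)
  names(lens) <- sub("\\s.*$", "", names(lens))
  lens
}

#' Strand-aware upstream intergenic distance for every gene
#'
#' For a `+` strand gene the upstream neighbor is the feature (any strand)
#' with the greatest end before the gene's start; the distance is
#' `start - neighbor_end - 1`. For a `-` strand gene it is the feature
#' with the least start past the gene's end; the distance is
#' `neighbor_start - end - 1`. A neighbor overlapping the gene's 5' end
#' yields distance 0. A gene with no upstream neighbor on its contig gets
#' the distance to the contig edge and `at_contig_edge = TRUE`.
#'
#' This intergenic distance is what the screen treats as the gene's
#' available 5'-UTR/promoter space ("5'-UTR size to next gene").
#'
#' @param features Tibble from [read_gene_features()] (or equivalent).
#' @param contig_lengths Named vector of contig lengths; defaults to the
#'   `contig_lengths` attribute of `features`.
#' @return A tibble `gene_id`, `utr_length`, `upstream_neighbor_id`,
#'   `at_contig_edge`, in the row order of `features`.
#' @export
compute_upstream_distance <- function(features,
                                      contig_lengths = attr(features, "contig_lengths")) {
  if (nrow(features) == 0) {
    abort("`features` is empty", class = "promrank_validation_error")
  }
  if (is.null(contig_lengths)) {
    abort("contig lengths are required (GFF3 ##sequence-region or read_contig_lengths())",
          class = "promrank_reference_error")
  }
  unknown <- setdiff(unique(features$contig), names(contig_lengths))
  if (length(unknown) > 0 ||
      any(is.na(contig_lengths[unique(features$contig)]))) {
    abort(sprintf("unknown or unlengthed contig '%s'",
                  c(unknown, "")[1]),
          class = "promrank_reference_error")
  }

  per_contig <- lapply(split(seq_len(nrow(features)), features$contig),
                       function(idx) {
    f <- features[idx, ]
    clen <- contig_lengths[[f$contig[1]]]
    n <- nrow(f)

    # upstream-by-start: running max of end over features sorted by start
    o_s <- order(f$start, f$gene_id)
    starts_s <- f$start[o_s]
    ends_by_start <- f$end[o_s]
    pmax_end <- cummax(ends_by_start)
    arg <- integer(n); best <- 1L
    for (i in seq_len(n)) {
      if (ends_by_start[i] > ends_by_start[best]) best <- i
      arg[i] <- best
    }
    pmax_id <- f$gene_id[o_s][arg]

    # downstream-by-end: running min of start over features sorted by end,
    # taken from the right
    o_e <- order(f$end, f$gene_id)
    ends_s <- f$end[o_e]
    starts_by_end <- f$start[o_e]
    smin_start <- rev(cummin(rev(starts_by_end)))
    arg <- integer(n); best <- n
    for (i in rev(seq_len(n))) {
      if (starts_by_end[i] < starts_by_end[best]) best <- i
      arg[i] <- best
    }
    smin_id <- f$gene_id[o_e][arg]

    utr <- integer(n); neighbor <- rep(NA_character_, n); edge <- logical(n)
    for (i in seq_len(n)) {
      if (f$strand[i] == "+") {
        q <- findInterval(f$start[i] - 0.5, starts_s)
        if (q == 0L) {
          utr[i] <- f$start[i] - 1L; edge[i] <- TRUE
        } else {
          utr[i] <- max(0L, f$start[i] - pmax_end[q] - 1L)
          neighbor[i] <- pmax_id[q]
        }
      } else {
        q <- findInterval(f$end[i] + 0.5, ends_s) + 1L
        if (q > n) {
          utr[i] <- clen - f$end[i]; edge[i] <- TRUE
        } else {
          utr[i] <- max(0L, smin_start[q] - f$end[i] - 1L)
          neighbor[i] <- smin_id[q]
        }
      }
    }
    tibble(.row = idx, gene_id = f$gene_id, utr_length = utr,
           upstream_neighbor_id = neighbor, at_contig_edge = edge)
  })
  out <- bind_rows(per_contig) %>% arrange(.data$.row) %>% select(-".row")
  out
}

#' Promoter window upstream of each gene's 5' end
#'
#' The window has length `min(target_length, utr_length)` and abuts the
#' gene's 5' coordinate: for a `+` gene the 0-based half-open interval
#' `[start - 1 - L, start - 1)`, for a `-` gene the mirrored interval
#' `[end, end + L)` (GFF3 coordinates are 1-based inclusive; emitted
#' windows are 0-based half-open as in BED). A window is never longer than
#' the intergenic space, so it cannot overlap the upstream neighbor's gene
#' body. A gene with `utr_length` 0 gets an empty, flagged window.
#'
#' @param features,utrs Matching tibbles from [read_gene_features()] and
#'   [compute_upstream_distance()].
#' @param target_length Desired promoter length in bp (default 1024).
#' @param target_overrides Optional tibble `gene_id`, `target_length`
#'   overriding the target per gene (e.g. to cut a slightly longer tested
#'   fragment for one promoter).
#' @return A tibble `gene_id`, `contig`, `start`, `end` (0-based
#'   half-open), `strand`, `length`, `is_empty`.
#' @export
promoter_windows <- function(features, utrs, target_length = 1024,
                             target_overrides = NULL) {
  target_length <- check_count(target_length, "target_length")
  x <- left_join(features, utrs[, c("gene_id", "utr_length")], by = "gene_id")
  if (any(is.na(x$utr_length))) {
    abort(sprintf("no UtrRecord for gene '%s'",
                  x$gene_id[is.na(x$utr_length)][1]),
          class = "promrank_validation_error")
  }
  tl <- rep(target_length, nrow(x))
  if (!is.null(target_overrides)) {
    stopifnot(all(c("gene_id", "target_length") %in% names(target_overrides)))
    m <- match(x$gene_id, target_overrides$gene_id)
    tl[!is.na(m)] <- target_overrides$target_length[m[!is.na(m)]]
  }
  len <- pmin(tl, x$utr_length)
  plus <- x$strand == "+"
  tibble(
    gene_id = x$gene_id,
    contig = x$contig,
    start = ifelse(plus, x$start - 1L - len, x$end),
    end = ifelse(plus, x$start - 1L, x$end + len),
    strand = x$strand,
    length = as.integer(len),
    is_empty = len == 0L
  )
}

#' Extract promoter sequences from a genome FASTA
#'
#' Returns each window's sequence reading 5' to 3' toward the downstream
#' gene's start: the plain contig slice for `+` windows, its reverse
#' complement for `-` windows; always uppercase.
#'
#' @param windows Tibble from [promoter_windows()].
#' @param fasta_path Genome FASTA path.
#' @return `windows` with an added character column `sequence`.
#' @export
extract_promoter_seqs <- function(windows, fasta_path) {
  genome <- Biostrings::readDNAStringSet(fasta_path)
  names(genome) <- sub("\\s.*$", "", names(genome))
  seqs <- vapply(seq_len(nrow(windows)), function(i) {
    ct <- windows$contig[i]
    if (!ct %in% names(genome)) {
      abort(sprintf("contig '%s' not in FASTA", ct),
            class = "promrank_reference_error")
    }
    if (windows$start[i] < 0 || windows$end[i] > length(genome[[ct]])) {
      abort(sprintf("window for gene '%s' out of contig bounds",
                    windows$gene_id[i]),
            class = "promrank_reference_error")
    }
    s <- Biostrings::subseq(genome[[ct]], windows$start[i] + 1L,
                            windows$end[i])
    if (windows$strand[i] == "-") s <- Biostrings::reverseComplement(s)
    toupper(as.character(s))
  }, character(1))
  mutate(windows, sequence = seqs)
}

#' Write promoter sequences to FASTA
#'
#' Headers follow `>geneID|contig:start-end(strand)|len=L` with 1-based
#' inclusive coordinates.
#'
#' @param seqs Tibble from [extract_promoter_seqs()].
#' @param path Output FASTA path.
#' @return Invisibly, the path.
#' @export
write_promoter_fasta <- function(seqs, path) {
  stopifnot("sequence" %in% names(seqs))
  headers <- sprintf("%s|%s:%d-%d(%s)|len=%d",
                     seqs$gene_id, seqs$contig, seqs$start + 1L, seqs$end,
                     seqs$strand, seqs$length)
  x <- Biostrings::DNAStringSet(stats::setNames(as.character(seqs$sequence),
                                                headers))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write promoter windows to BED6
#'
#' Name is the gene id, score the (rounded) median expression rank, strand
#' the downstream gene's strand. BED uses 0-based half-open coordinates,
#' matching the windows directly. Empty windows are skipped.
#'
#' @param windows Tibble from [promoter_windows()].
#' @param path Output BED path.
#' @param score Numeric vector (recycled) written to the BED score column.
#' @return Invisibly, the path.
#' @export
write_promoter_bed <- function(windows, path, score = 0) {
  w <- windows[!windows$is_empty, , drop = FALSE]
  score <- round(rep_len(score, nrow(windows)))[!windows$is_empty]
  if (nrow(w) == 0) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  gr <- GenomicRanges::GRanges(w$contig,
                               IRanges::IRanges(w$start + 1L, w$end),
                               strand = w$strand)
  S4Vectors::mcols(gr)$name <- w$gene_id
  S4Vectors::mcols(gr)$score <- score
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
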