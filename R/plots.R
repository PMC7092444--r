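#' Plot a promoter screen in filter space
#'
#' Median rank against maximum rank (both log-scaled) for the head of the
#' prioritized list, coloured by filter outcome, with the maximum-rank
#' threshold drawn. Selected genes are labelled.
#'
#' @param object A `promoter_screen`.
#' @param head_n How many genes from the head of the list to show.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.promoter_screen <- function(object, head_n = 100, ...) {
  d <- head(object$candidates, head_n) %>%
    mutate(outcome = dplyr::case_when(
      .data$selected ~ "selected",
      .data$passes_max_rank & .data$passes_utr ~ "passes, not selected",
      !.data$passes_max_rank ~ "fails max-rank",
      TRUE ~ "fails UTR"
    ))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$median_rank, y = .data$max_rank,
                                  colour = .data$outcome)) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::geom_hline(yintercept = object$params$max_rank_threshold,
                        linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "median rank", y = "maximum rank", colour = NULL,
                  title = sprintf("Promoter screen (top %d genes shown)",
                                  min(head_n, nrow(object$candidates)))) +
    ggplot2::theme_minimal()
}

#' Plot a stability curve
#'
#' Mean top-k overlap with the full-collection list against subset size,
#' with one-standard-error ribbon and the per-replicate points jittered
#' behind.
#'
#' @param object A `stability_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.stability_curve <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$size, y = .data$mean_overlap)) +
    ggplot2::geom_jitter(data = object$replicates,
                         ggplot2::aes(y = .data$overlap),
                         width = 0.15, height = 0.1, alpha = 0.2,
                         colour = "grey50") +
    ggplot2::geom_ribbon(ggplot2::aes(
      ymin = .data$mean_overlap - .data$se_overlap,
      ymax = .data$mean_overlap + .data$se_overlap), alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_hline(yintercept = object$k, linetype = "dotted") +
    ggplot2::labs(x = "datasets in subset",
                  y = sprintf("top-%d overlap with full list", object$k),
                  title = "Stability of the prioritized list under dataset subsampling") +
    ggplot2::theme_minimal()
}
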