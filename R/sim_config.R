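#' Configuration for the synthetic study generator
#'
#' Bundles and validates every knob of the synthetic-data module. The
#' defaults describe the study the package emulates: a fungal genome of
#' 13,481 genes assayed in 83 transcriptome datasets collected under 32
#' culture conditions, with a small set of planted constitutive genes whose
#' promoters the screen should recover.
#'
#' Expression is generated on a log2-like intensity scale:
#' `x(g, d) = mu_g + beta(g, condition(d)) + noise(g, d)`. Planted
#' constitutive genes have `mu_g = mu_high` and `beta == 0`; every other
#' gene draws a baseline `mu_g ~ N(mu_base_mean, mu_base_sd)` truncated
#' strictly below `mu_high` (so that with zero noise the planted genes
#' separate cleanly), and a per-condition effect
#' `beta(g, c) ~ N(0, tau_condition)` shared by all datasets of condition
#' `c`. Datasets are assigned to conditions round-robin.
#'
#' Genome geometry places genes sequentially along `n_contigs` contigs with
#' intergenic gaps drawn from a two-component mixture: short gaps uniform on
#' `gap_short_range` and long gaps uniform on `gap_long_range`, a fraction
#' `gap_fraction_long` being long. The long-range upper bound comfortably
#' covers multi-kb intergenic spaces seen upstream of real fungal genes.
#'
#' @param n_genes Number of genes.
#' @param n_datasets Number of transcriptome datasets.
#' @param n_conditions Number of culture conditions; datasets are assigned
#'   round-robin so conditions with several datasets share condition effects.
#' @param n_constitutive Number of planted constitutively high genes
#'   (must be `< n_genes`).
#' @param mu_high Mean log-intensity of planted genes.
#' @param mu_base_mean,mu_base_sd Baseline log-intensity distribution of the
#'   remaining genes (truncated below `mu_high`).
#' @param tau_condition Standard deviation of per-condition effects for
#'   responsive (non-planted) genes.
#' @param sigma_noise Standard deviation of per-sample noise.
#' @param n_contigs Number of contigs in the synthetic genome.
#' @param gene_len_mean Mean gene length in bp (lengths are drawn around this
#'   with 20% relative spread, floored at 300 bp).
#' @param gap_short_range,gap_long_range Length-2 bp ranges for the short and
#'   long components of the intergenic-gap mixture.
#' @param gap_fraction_long Fraction of gaps drawn from the long component.
#' @param seed Master seed; per-artifact sub-streams (expression, geometry,
#'   sequence) are derived from it deterministically, so one seed fixes every
#'   generated artifact byte-for-byte.
#'
#' @return A validated `sim_config` list.
#' @examples
#' cfg <- sim_config(n_genes = 200, n_datasets = 6, n_conditions = 3,
#'                   n_constitutive = 5, seed = 1)
#' cfg$n_genes
#' @export
sim_config <- function(n_genes = 13481,
                       n_datasets = 83,
                       n_conditions = 32,
                       n_constitutive = 25,
                       mu_high = 12,
                       mu_base_mean = 7,
                       mu_base_sd = 2,
                       tau_condition = 2,
                       sigma_noise = 0.5,
                       n_contigs = 8,
                       gene_len_mean = 1500,
                       gap_short_range = c(50, 949),
                       gap_long_range = c(950, 6500),
                       gap_fraction_long = 0.5,
                       seed = 1) {
  cfg <- list(
    n_genes = check_count(n_genes, "n_genes"),
    n_datasets = check_count(n_datasets, "n_datasets"),
    n_conditions = check_count(n_conditions, "n_conditions"),
    n_constitutive = check_count(n_constitutive, "n_constitutive"),
    mu_high = check_number(mu_high, "mu_high"),
    mu_base_mean = check_number(mu_base_mean, "mu_base_mean"),
    mu_base_sd = check_number(mu_base_sd, "mu_base_sd", min = 0),
    tau_condition = check_number(tau_condition, "tau_condition", min = 0),
    sigma_noise = check_number(sigma_noise, "sigma_noise", min = 0),
    n_contigs = check_count(n_contigs, "n_contigs"),
    gene_len_mean = check_number(gene_len_mean, "gene_len_mean", min = 1),
    gap_short_range = check_range(gap_short_range, "gap_short_range"),
    gap_long_range = check_range(gap_long_range, "gap_long_range"),
    gap_fraction_long = check_number(gap_fraction_long, "gap_fraction_long", min = 0),
    seed = check_count(seed, "seed", min = 0L)
  )
  if (cfg$gap_fraction_long > 1) {
    abort("`gap_fraction_long` must be in [0, 1]", class = "promrank_config_error")
  }
  if (cfg$n_constitutive >= cfg$n_genes) {
    abort("`n_constitutive` must be smaller than `n_genes`",
          class = "promrank_config_error")
  }
  if (cfg$n_contigs > cfg$n_genes) {
    abort("`n_contigs` must not exceed `n_genes`", class = "promrank_config_error")
  }
  if (cfg$mu_base_mean >= cfg$mu_high) {
    abort("`mu_base_mean` must lie below `mu_high`", class = "promrank_config_error")
  }
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d genes (%d planted constitutive), %d datasets / %d conditions\n",
              x$n_genes, x$n_constitutive, x$n_datasets, x$n_conditions))
  cat(sprintf("  intensity: mu_high=%g, baseline N(%g, %g), tau=%g, sigma=%g\n",
              x$mu_high, x$mu_base_mean, x$mu_base_sd, x$tau_condition,
              x$sigma_noise))
  cat(sprintf("  genome: %d contigs, gene length ~%g bp, long-gap fraction %g\n",
              x$n_contigs, x$gene_len_mean, x$gap_fraction_long))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}
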