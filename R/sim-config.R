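#' Simulation configuration
#'
#' Bundles every knob of the synthetic-cohort generator. Defaults emulate a
#' BARCOS-like study: ~1000 genotyped postmenopausal women, 55 biallelic
#' BMD-associated SNPs in Hardy-Weinberg equilibrium with small additive
#' BMD-decreasing effects, Gaussian environmental noise, lumbar-spine and hip
#' Z-scores as two correlated views of one latent phenotype, and optional
#' rare large-effect protective variants.
#'
#' @param n_subjects Cohort size (default 1001, the genotyped BARCOS subset).
#' @param n_snps Number of SNPs on the panel (default 55).
#' @param maf_range Length-2 numeric in (0, 0.5]: minor-allele frequencies are
#'   drawn uniformly in this range (default c(0.1, 0.5)).
#' @param effect_size_distribution List with `name` and parameters for the
#'   per-allele phenotype decrease (arbitrary BMD-like units). Supported:
#'   `list(name = "uniform", min, max)` (default Uniform(0.02, 0.08)) and
#'   `list(name = "lognormal", meanlog, sdlog)`.
#' @param noise_sd Environmental noise SD in phenotype units (default 1).
#' @param missing_rate Probability a genotype call is missing (MCAR),
#'   in \[0, 1) (default 0.02).
#' @param z_correlation Correlation between the lumbar-spine and hip Z-scores
#'   induced by their shared latent phenotype, in (0, 1\] (default 0.6).
#' @param rare_variant_spec `NULL` (default) or
#'   `list(carrier_frequency =, protective_effect =)`: heterozygous carriers
#'   of a rare fully penetrant protective variant get `protective_effect`
#'   added to their latent phenotype Z (default shift +3 SD when used).
#' @param ct_replicate_sd SD of qPCR triplicate noise, in Ct cycles
#'   (default 0.15).
#' @param ct_sample_sd SD of per-gene per-sample biological variation in Ct
#'   cycles for non-reference genes (default 0.25).
#' @param seed Integer seed; identical config + seed gives bit-identical
#'   output.
#' @return A `sim_config` list (validated).
#' @examples
#' cfg <- sim_config(n_subjects = 200, n_snps = 10, seed = 42)
#' @export
sim_config <- function(n_subjects = 1001L,
                       n_snps = 55L,
                       maf_range = c(0.1, 0.5),
                       effect_size_distribution = list(name = "uniform",
                                                       min = 0.02, max = 0.08),
                       noise_sd = 1,
                       missing_rate = 0.02,
                       z_correlation = 0.6,
                       rare_variant_spec = NULL,
                       ct_replicate_sd = 0.15,
                       ct_sample_sd = 0.25,
                       seed = 1L) {
  chk_count <- function(x, nm, min = 1L) {
    if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
      abort(sprintf("`%s` must be a single integer >= %d.", nm, min))
    as.integer(x)
  }
  n_subjects <- chk_count(n_subjects, "n_subjects")
  n_snps <- chk_count(n_snps, "n_snps")
  if (!is.numeric(maf_range) || length(maf_range) != 2L ||
      anyNA(maf_range) || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    abort("`maf_range` must be two frequencies within (0, 0.5], non-decreasing.")
  if (!is.list(effect_size_distribution) ||
      is.null(effect_size_distribution$name) ||
      !effect_size_distribution$name %in% c("uniform", "lognormal"))
    abort("`effect_size_distribution` must name \"uniform\" or \"lognormal\".")
  if (identical(effect_size_distribution$name, "uniform")) {
    mn <- effect_size_distribution$min %||% abort("`effect_size_distribution$min` missing.")
    mx <- effect_size_distribution$max %||% abort("`effect_size_distribution$max` missing.")
    if (mn <= 0 || mx < mn)
      abort("`effect_size_distribution`: need 0 < min <= max (betas are strictly positive).")
  }
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || is.na(noise_sd) || noise_sd <= 0)
    abort("`noise_sd` must be a single positive number.")
  if (!is.numeric(missing_rate) || length(missing_rate) != 1L ||
      is.na(missing_rate) || missing_rate < 0 || missing_rate >= 1)
    abort("`missing_rate` must be in [0, 1).")
  if (!is.numeric(z_correlation) || length(z_correlation) != 1L ||
      is.na(z_correlation) || z_correlation <= 0 || z_correlation > 1)
    abort("`z_correlation` must be in (0, 1].")
  if (!is.null(rare_variant_spec)) {
    cf <- rare_variant_spec$carrier_frequency
    pe <- rare_variant_spec$protective_effect
    if (is.null(cf) || is.null(pe) || !is.numeric(cf) || !is.numeric(pe) ||
        cf <= 0 || cf >= 1)
      abort("`rare_variant_spec` needs carrier_frequency in (0,1) and protective_effect.")
  }
  if (!is.numeric(ct_replicate_sd) || ct_replicate_sd <= 0)
    abort("`ct_replicate_sd` must be positive.")
  if (!is.numeric(ct_sample_sd) || ct_sample_sd < 0)
    abort("`ct_sample_sd` must be non-negative.")
  seed <- chk_count(seed, "seed", min = 0L)
  structure(
    list(n_subjects = n_subjects, n_snps = n_snps, maf_range = maf_range,
         effect_size_distribution = effect_size_distribution,
         noise_sd = noise_sd, missing_rate = missing_rate,
         z_correlation = z_correlation, rare_variant_spec = rare_variant_spec,
         ct_replicate_sd = ct_replicate_sd, ct_sample_sd = ct_sample_sd,
         seed = seed),
    class = "sim_config"
  )
}

#' @export
print.sim_config <- function(x, ...) {
  cat("Synthetic-cohort configuration\n")
  cat(sprintf("  subjects: %d, SNPs: %d, MAF range: [%g, %g]\n",
              x$n_subjects, x$n_snps, x$maf_range[1], x$maf_range[2]))
  cat(sprintf("  effect sizes: %s, noise SD: %g, missing rate: %g\n",
              x$effect_size_distribution$name, x$noise_sd, x$missing_rate))
  cat(sprintf("  LS-hip Z correlation: %g, seed: %d\n", x$z_correlation, x$seed))
  if (!is.null(x$rare_variant_spec))
    cat(sprintf("  rare protective variant: carrier freq %g, effect +%g SD\n",
                x$rare_variant_spec$carrier_frequency,
                x$rare_variant_spec$protective_effect))
  invisible(x)
}

# Draw per-SNP effect sizes according to the configured distribution.
draw_betas <- function(n, dist) {
  switch(dist$name,
    uniform = runif(n, dist$min, dist$max),
    lognormal = stats::rlnorm(n, dist$meanlog %||% log(0.05), dist$sdlog %||% 0.4)
  )
}
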