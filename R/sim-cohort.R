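#' Simulate a SNP effect table
#'
#' Draws a panel of biallelic SNPs with minor-allele frequencies uniform in
#' `config$maf_range` and strictly positive per-allele effect sizes (the
#' effect allele is oriented so that each copy decreases the phenotype, the
#' convention of BMD risk-score panels).
#'
#' @param config A [sim_config()].
#' @return A tibble with columns `rsid`, `effect_allele`, `other_allele`,
#'   `beta` (per-allele phenotype decrease, > 0) and `maf` (effect-allele
#'   frequency).
#' @examples
#' simulate_effect_table(sim_config(n_snps = 5, seed = 1))
#' @export
simulate_effect_table <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  n <- config$n_snps
  bases <- c("A", "C", "G", "T")
  ea <- sample(bases, n, replace = TRUE)
  oa <- vapply(ea, function(b) sample(setdiff(bases, b), 1L), character(1))
  tibble(
    rsid = sprintf("rs%07d", sample.int(9999999L, n)),
    effect_allele = ea,
    other_allele = unname(oa),
    beta = draw_betas(n, config$effect_size_distribution),
    maf = runif(n, config$maf_range[1], config$maf_range[2])
  )
}

#' Simulate a genotype matrix under Hardy-Weinberg equilibrium
#'
#' Risk-allele dosages are drawn per SNP as Binomial(2, MAF); missing calls
#' are injected uniformly at random (MCAR) at `config$missing_rate` and are
#' encoded `NA`, distinct from dosage 0.
#'
#' @param effects Effect table from [simulate_effect_table()].
#' @param config A [sim_config()].
#' @param missing_rate Override for the config's missing rate (e.g. 0 to get
#'   the complete matrix used for phenotype generation).
#' @return A wide tibble: column `id` plus one integer dosage column per rsid.
#' @export
simulate_genotypes <- function(effects, config, missing_rate = config$missing_rate) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(effects) || nrow(effects) == 0L)
    abort("`effects` must be a non-empty effect table.")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  n <- config$n_subjects
  dos <- vapply(effects$maf, function(p) rbinom(n, 2L, p), integer(n))
  if (missing_rate > 0) {
    miss <- matrix(runif(n * nrow(effects)) < missing_rate, nrow = n)
    dos[miss] <- NA_integer_
  }
  colnames(dos) <- effects$rsid
  bind_cols(tibble(id = sprintf("S%04d", seq_len(n))), as_tibble(dos))
}

# Dosage columns of a wide genotype tibble, as a numeric matrix with id rownames.
genotype_matrix <- function(genotypes) {
  if (!is.data.frame(genotypes) || !"id" %in% names(genotypes))
    abort("genotype table must have an `id` column plus one column per rsid.")
  m <- as.matrix(genotypes[setdiff(names(genotypes), "id")])
  storage.mode(m) <- "double"
  rownames(m) <- genotypes$id
  bad <- m[!is.na(m)]
  if (length(bad) && !all(bad %in% c(0, 1, 2)))
    abort("dosages must be 0, 1, 2 or missing (NA).")
  m
}

#' Simulate phenotypes and DXA-style Z-scores for a genotyped cohort
#'
#' The additive model: phenotype = baseline − sum_j beta_j * dosage_ij +
#' Normal(0, noise_sd). The latent phenotype is standardized against the
#' simulated cohort mean/SD; lumbar-spine and hip Z-scores are then two noisy
#' views of that latent Z sharing a fraction `z_correlation` of their
#' variance, so their sum behaves like the sum Z-score used for
#' extreme-phenotype ascertainment. When `config$rare_variant_spec` is set,
#' carriers (Bernoulli at `carrier_frequency`) get `protective_effect` added
#' to their latent Z (heterozygotes fully express the shift: dominance).
#'
#' @param genotypes Complete (no missing dosage) wide genotype tibble.
#' @param effects Matching effect table.
#' @param config A [sim_config()].
#' @param baseline Baseline phenotype level (arbitrary BMD-like units).
#' @return A subject tibble: `id`, `age`, `ls_z`, `hip_z`, `sum_z`, `cohort`,
#'   `dna_available`, `genotyped`, `carrier`, `phenotype` (the raw BMD-like
#'   value, used for bin-level summaries).
#' @export
simulate_phenotypes <- function(genotypes, effects, config, baseline = 0) {
  stopifnot(inherits(config, "sim_config"))
  m <- genotype_matrix(genotypes)
  if (!setequal(colnames(m), effects$rsid) || ncol(m) != nrow(effects))
    abort("genotype columns and effect-table rsids do not match.")
  if (anyNA(m))
    abort(paste("genotype matrix contains missing dosages;",
                "phenotypes must be generated from the complete matrix",
                "(see simulate_cohort())."))
  m <- m[, effects$rsid, drop = FALSE]
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 2L)
  n <- nrow(m)
  g_value <- drop(m %*% effects$beta)
  phenotype <- baseline - g_value + rnorm(n, 0, config$noise_sd)
  latent <- (phenotype - mean(phenotype)) / sd(phenotype)
  carrier <- rep(FALSE, n)
  if (!is.null(config$rare_variant_spec)) {
    carrier <- runif(n) < config$rare_variant_spec$carrier_frequency
    latent[carrier] <- latent[carrier] + config$rare_variant_spec$protective_effect
  }
  rho <- config$z_correlation
  ls_z <- sqrt(rho) * latent + sqrt(1 - rho) * rnorm(n)
  hip_z <- sqrt(rho) * latent + sqrt(1 - rho) * rnorm(n)
  tibble(
    id = rownames(m),
    age = as.integer(round(runif(n, 50, 80))),
    ls_z = ls_z,
    hip_z = hip_z,
    sum_z = ls_z + hip_z,
    cohort = "SIM",
    dna_available = TRUE,
    genotyped = TRUE,
    carrier = carrier,
    phenotype = phenotype
  )
}

#' Simulate a full cohort: effects, genotypes and subjects
#'
#' Chains [simulate_effect_table()], [simulate_genotypes()] (complete matrix
#' for phenotype generation, observed matrix with missing calls for scoring)
#' and [simulate_phenotypes()]. Identical config gives bit-identical output.
#'
#' @inheritParams simulate_effect_table
#' @param baseline Baseline phenotype level.
#' @return An `hbm_cohort` list: `effects`, `genotypes` (observed, with
#'   missingness), `genotypes_complete` (the truth used for phenotypes),
#'   `subjects`, `config`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_subjects = 50, n_snps = 5, seed = 3))
#' head(coh$subjects)
#' @export
simulate_cohort <- function(config, baseline = 0) {
  stopifnot(inherits(config, "sim_config"))
  effects <- simulate_effect_table(config)
  complete <- simulate_genotypes(effects, config, missing_rate = 0)
  subjects <- simulate_phenotypes(complete, effects, config, baseline = baseline)
  observed <- complete
  if (config$missing_rate > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old), add = TRUE)
    set.seed(config$seed + 5L)
    m <- genotype_matrix(complete)
    miss <- matrix(runif(length(m)) < config$missing_rate, nrow = nrow(m))
    m[miss] <- NA
    observed <- bind_cols(tibble(id = complete$id),
                          as_tibble(`storage.mode<-`(m, "integer")))
  }
  structure(
    list(effects = effects, genotypes = observed,
         genotypes_complete = complete, subjects = subjects, config = config),
    class = "hbm_cohort"
  )
}

#' @export
print.hbm_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects x %d SNPs (seed %d)\n",
              nrow(x$subjects), nrow(x$effects), x$config$seed))
  cat(sprintf("  missing dosage fraction: %.4f\n",
              mean(is.na(genotype_matrix(x$genotypes)))))
  cat(sprintf("  subjects with sum Z >= 4: %d\n", sum(x$subjects$sum_z >= 4)))
  invisible(x)
}
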