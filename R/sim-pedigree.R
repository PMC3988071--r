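#' Simulate a nuclear pedigree segregating a protective variant
#'
#' The founder carries (or not) a heterozygous, fully penetrant protective
#' variant; each offspring inherits it with probability 1/2 (Mendelian
#' transmission from a heterozygous parent; the spouse is a non-carrier).
#' Carriers get the protective shift added to their latent phenotype Z, which
#' propagates to lumbar-spine and hip Z-scores exactly as in
#' [simulate_phenotypes()].
#'
#' @param founder_carrier Logical: is the founder a heterozygous carrier?
#' @param n_offspring Number of offspring (>= 1).
#' @param config A [sim_config()]; `rare_variant_spec$protective_effect`
#'   gives the carrier shift (default +3 latent SD when the config has none).
#' @param latent_sd SD of the members' latent Z around 0 (default 1, the
#'   population scale); shrink it towards 0 to study the noise-free limit in
#'   which carrier and non-carrier phenotypes separate completely.
#' @param founder_sum_z Optional observed sum Z-score for the founder (e.g.
#'   an ascertained proband's value); overrides the simulated one.
#' @return A pedigree tibble: `id`, `relation` (founder/spouse/offspring),
#'   `sum_z`, `carrier` ("carrier"/"non-carrier").
#' @examples
#' ped <- simulate_pedigree(TRUE, 2, sim_config(seed = 9))
#' cosegregation_check(ped)
#' @export
simulate_pedigree <- function(founder_carrier, n_offspring, config,
                              latent_sd = 1, founder_sum_z = NULL) {
  stopifnot(inherits(config, "sim_config"))
  if (!is.numeric(n_offspring) || n_offspring < 1L)
    abort("`n_offspring` must be >= 1.")
  n_offspring <- as.integer(n_offspring)
  shift <- if (!is.null(config$rare_variant_spec))
    config$rare_variant_spec$protective_effect else 3
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 3L)

  n <- 2L + n_offspring
  carrier <- c(isTRUE(founder_carrier), FALSE,
               if (isTRUE(founder_carrier)) runif(n_offspring) < 0.5
               else rep(FALSE, n_offspring))
  latent <- rnorm(n, 0, latent_sd) + shift * carrier
  rho <- config$z_correlation
  ls <- sqrt(rho) * latent + sqrt(1 - rho) * rnorm(n, 0, latent_sd)
  hip <- sqrt(rho) * latent + sqrt(1 - rho) * rnorm(n, 0, latent_sd)
  sum_z <- ls + hip
  if (!is.null(founder_sum_z)) sum_z[1] <- founder_sum_z
  tibble(
    id = c("founder", "spouse", sprintf("offspring%02d", seq_len(n_offspring))),
    relation = c("founder", "spouse", rep("offspring", n_offspring)),
    sum_z = sum_z,
    carrier = ifelse(carrier, "carrier", "non-carrier")
  )
}
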