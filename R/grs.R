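#' Per-SNP risk score
#'
#' A SNP's score is its risk-allele dosage times its per-allele effect size:
#' homozygotes for the risk allele score 2x the effect size, heterozygotes
#' 1x, homozygotes for the alternative allele 0. Vectorized. Missing dosages
#' are an error here: they must be routed through mean-score imputation
#' ([impute_missing_scores()]), not silently scored.
#'
#' @param dosage Integer dosage in \{0, 1, 2\}.
#' @param beta Per-allele effect size (> 0).
#' @return `dosage * beta`.
#' @examples
#' snp_score(c(0, 1, 2), 0.05)
#' @export
snp_score <- function(dosage, beta) {
  if (anyNA(dosage))
    abort("missing dosage reached snp_score(); impute first (impute_missing_scores).")
  if (!all(dosage %in% c(0, 1, 2))) abort("dosage must be 0, 1 or 2.")
  if (any(beta <= 0)) abort("`beta` must be strictly positive.")
  dosage * beta
}

#' Mean-score imputation of missing genotypes
#'
#' Each missing genotype's score is replaced by the mean of that SNP's scores
#' over the non-missing subjects of a reference cohort (equivalently
#' beta * mean reference dosage). This preserves the cohort mean score while
#' attenuating its variance. Non-missing cells are scored directly.
#'
#' @param genotypes Wide genotype tibble to score (may contain `NA`).
#' @param effects Effect table covering the genotype columns.
#' @param reference Wide genotype tibble providing the imputation means; must
#'   share the SNP set and have at least one non-missing call per SNP.
#'   Defaults to `genotypes` itself.
#' @return A list: `scores` (wide tibble, `id` + per-rsid score columns, no
#'   missing values) and `n_imputed` (tibble `id`, `n_imputed`).
#' @export
impute_missing_scores <- function(genotypes, effects, reference = genotypes) {
  m <- genotype_matrix(genotypes)
  r <- genotype_matrix(reference)
  if (!setequal(colnames(m), effects$rsid))
    abort("genotype columns and effect-table rsids do not match.")
  if (!all(colnames(m) %in% colnames(r)))
    abort("reference cohort does not cover the SNP set.")
  m <- m[, effects$rsid, drop = FALSE]
  r <- r[, effects$rsid, drop = FALSE]
  ref_n <- colSums(!is.na(r))
  if (any(ref_n == 0L))
    abort(paste("SNP(s) entirely missing in the reference:",
                paste(effects$rsid[ref_n == 0L], collapse = ", ")))
  betas <- effects$beta
  scores <- sweep(m, 2, betas, `*`)
  ref_mean_score <- colMeans(r, na.rm = TRUE) * betas
  n_imp <- rowSums(is.na(m))
  idx <- which(is.na(scores), arr.ind = TRUE)
  if (nrow(idx)) scores[idx] <- ref_mean_score[idx[, 2]]
  list(
    scores = bind_cols(tibble(id = rownames(m)), as_tibble(scores)),
    n_imputed = tibble(id = rownames(m), n_imputed = as.integer(n_imp))
  )
}

#' Global (raw) risk score
#'
#' Sums the per-SNP scores of a complete (post-imputation) score table.
#'
#' @param score_table Wide score tibble from [impute_missing_scores()]
#'   (`id` + per-rsid score columns), or a bare numeric matrix.
#' @return Tibble `id`, `raw_score`.
#' @export
global_score <- function(score_table) {
  if (is.data.frame(score_table)) {
    ids <- score_table$id %||% sprintf("S%04d", seq_len(nrow(score_table)))
    m <- as.matrix(score_table[setdiff(names(score_table), "id")])
  } else {
    ids <- rownames(score_table) %||% sprintf("S%04d", seq_len(nrow(score_table)))
    m <- score_table
  }
  if (anyNA(m)) abort("score table must be complete (post-imputation).")
  tibble(id = ids, raw_score = rowSums(m))
}

#' Normalize a raw risk score to the effective-allele-count scale
#'
#' Divides the raw (effect-size-weighted) score by the mean per-SNP effect
#' size of the panel, giving a dimensionless effective risk-allele count in
#' \[0, 2 x n_snps\]. Multiplying every beta by a constant leaves the
#' normalized score unchanged.
#'
#' @param raw_score Numeric raw score(s).
#' @param effects Effect table whose SNPs entered the score.
#' @return Normalized score(s).
#' @examples
#' normalize_score(2.4, tibble::tibble(beta = c(0.04, 0.05, 0.06)))
#' @export
normalize_score <- function(raw_score, effects) {
  if (!is.data.frame(effects) || nrow(effects) == 0L)
    abort("`effects` must be a non-empty effect table.")
  mb <- mean(effects$beta)
  if (!is.finite(mb) || mb <= 0) abort("mean effect size must be positive.")
  raw_score / mb
}

#' Weighted genetic risk score pipeline
#'
#' Scores every subject of a genotype table: per-SNP 0x/1x/2x scoring,
#' mean-score imputation of missing calls against a reference cohort, row
#' summation, normalization by the panel's mean effect size, and assignment
#' to score bins anchored on the reference cohort.
#'
#' @param genotypes Wide genotype tibble to score.
#' @param effects Effect table.
#' @param reference Reference cohort genotypes for imputation means and bin
#'   anchoring (default: the scored cohort itself).
#' @param exclude Character vector of rsids dropped before scoring (e.g. a
#'   SNP with conflicting genotyping results); the panel mean beta is
#'   recomputed on the retained SNPs.
#' @param n_bins,edges Passed to [assign_bins()].
#' @return A tibble `id`, `raw_score`, `normalized_score`, `n_imputed`,
#'   `bin_index`, `bin_label`, with attributes `edges` (bin edges) and
#'   `mean_beta`.
#' @examples
#' coh <- simulate_cohort(sim_config(n_subjects = 100, n_snps = 8, seed = 2))
#' grs_score(coh$genotypes, coh$effects)
#' @export
grs_score <- function(genotypes, effects, reference = genotypes,
                      exclude = NULL, n_bins = 5L, edges = NULL) {
  if (!is.null(exclude)) {
    effects <- filter(effects, !.data$rsid %in% exclude)
    if (nrow(effects) == 0L) abort("exclusion list removed every SNP.")
    keep <- c("id", effects$rsid)
    genotypes <- genotypes[intersect(names(genotypes), keep)]
    reference <- reference[intersect(names(reference), keep)]
  }
  imp <- impute_missing_scores(genotypes, effects, reference)
  raw <- global_score(imp$scores)
  raw$normalized_score <- normalize_score(raw$raw_score, effects)

  ref_norm <- if (identical(reference, genotypes)) {
    raw$normalized_score
  } else {
    ref_imp <- impute_missing_scores(reference, effects, reference)
    normalize_score(global_score(ref_imp$scores)$raw_score, effects)
  }
  b <- assign_bins(raw$normalized_score, n_bins = n_bins, edges = edges,
                   reference_scores = ref_norm)
  out <- left_join(raw, imp$n_imputed, by = "id")
  out$bin_index <- b$bin_index
  out$bin_label <- b$bin_label
  attr(out, "edges") <- attr(b, "edges")
  attr(out, "mean_beta") <- mean(effects$beta)
  out
}
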