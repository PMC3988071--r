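test_that("per-SNP scoring follows the 0x/1x/2x rule and rejects missing calls", {
  expect_equal(snp_score(2, 0.05), 0.10)
  expect_equal(snp_score(1, 0.05), 0.05)
  expect_equal(snp_score(0, 0.05), 0)
  expect_equal(snp_score(c(0, 1, 2), 0.06), c(0, 0.06, 0.12))
  expect_error(snp_score(NA, 0.05), "impute")
  expect_error(snp_score(3, 0.05), "dosage")
  expect_error(snp_score(1, 0), "positive")
})

test_that("mean-score imputation uses the reference SNP score mean", {
  eff <- tibble::tibble(rsid = "rs1", effect_allele = "A", other_allele = "G",
                        beta = 0.06, maf = 0.3)
  ref <- tibble::tibble(id = c("r1", "r2", "r3"), rs1 = c(0L, 1L, 2L))
  tgt <- tibble::tibble(id = "t1", rs1 = NA_integer_)
  imp <- impute_missing_scores(tgt, eff, ref)
  expect_equal(imp$scores$rs1, 0.06)  # mean of 0, 0.06, 0.12
  expect_equal(imp$n_imputed$n_imputed, 1L)

  # no missing cells: identity with direct scoring, zero imputations
  full <- tibble::tibble(id = c("a", "b"), rs1 = c(2L, 1L))
  imp2 <- impute_missing_scores(full, eff, ref)
  expect_equal(imp2$scores$rs1, c(0.12, 0.06))
  expect_equal(imp2$n_imputed$n_imputed, c(0L, 0L))

  # a SNP with no reference call is a named error
  ref_na <- tibble::tibble(id = c("r1", "r2"), rs1 = c(NA_integer_, NA_integer_))
  expect_error(impute_missing_scores(tgt, eff, ref_na), "rs1")
})

test_that("imputation by the mean preserves the cohort mean score", {
  cfg <- sim_config(n_subjects = 1000, n_snps = 20, missing_rate = 0.1, seed = 21)
  coh <- simulate_cohort(cfg)
  complete_raw <- global_score(
    impute_missing_scores(coh$genotypes_complete, coh$effects)$scores)$raw_score
  imputed_raw <- global_score(
    impute_missing_scores(coh$genotypes, coh$effects,
                          reference = coh$genotypes)$scores)$raw_score
  # means agree within Monte-Carlo error; the imputed variance is attenuated
  expect_equal(mean(imputed_raw), mean(complete_raw),
               tolerance = 3 * sd(complete_raw) / sqrt(1000) / abs(mean(complete_raw)))
  expect_lte(var(imputed_raw), var(complete_raw))
})

test_that("global and normalized scores follow the documented arithmetic", {
  m <- matrix(c(0, 0.05, 0.12), nrow = 1)
  colnames(m) <- paste0("rs", 1:3)
  expect_equal(global_score(m)$raw_score, 0.17)
  expect_equal(global_score(matrix(0, 1, 5))$raw_score, 0)

  eff <- tibble::tibble(beta = c(0.04, 0.05, 0.06))
  expect_equal(normalize_score(2.4, tibble::tibble(beta = rep(0.05, 55))), 48)
  expect_equal(normalize_score(sum(eff$beta), eff), 3) # all het = n_snps
  expect_error(normalize_score(1, tibble::tibble(beta = numeric())), "empty|non-empty")
})

test_that("normalized scores are invariant to rescaling every beta", {
  fix <- grs_micro_fixture()
  base <- grs_score(fix$genotypes, fix$effects)
  for (k in c(0.1, 3, 42)) {
    eff_k <- dplyr::mutate(fix$effects, beta = beta * k)
    scaled <- grs_score(fix$genotypes, eff_k)
    expect_equal(scaled$normalized_score, base$normalized_score)
  }
})

test_that("micro-fixture pipeline matches the hand-written oracle cell for cell", {
  fix <- grs_micro_fixture()
  out <- grs_score(fix$genotypes, fix$effects)
  expect_equal(out$id, fix$expected$id)
  expect_equal(out$raw_score, fix$expected$raw_score)
  expect_equal(out$normalized_score, fix$expected$normalized_score)
  expect_equal(out$n_imputed, fix$expected$n_imputed)
  # scores stay within the effective-allele-count bounds
  expect_true(all(out$normalized_score >= 0 &
                  out$normalized_score <= 2 * nrow(fix$effects)))
})

test_that("bin assignment uses half-open intervals with a closed last bin", {
  b <- assign_bins(c(44, 47.9, 48), edges = c(44, 48, 52))
  expect_equal(b$bin_index, c(1L, 1L, 2L))
  expect_identical(b$bin_label, c("44-48", "44-48", "48-52"))
  # the maximum score lands in the last (closed) bin
  expect_equal(assign_bins(52, edges = c(44, 48, 52))$bin_index, 2L)
  expect_error(assign_bins(1, edges = c(4, 4, 8)), "increasing")
  expect_warning(assign_bins(c(43, 53), edges = c(44, 48, 52)), "clamped")
})

test_that("default five bins partition the cohort", {
  cfg <- sim_config(n_subjects = 500, n_snps = 30, seed = 22)
  coh <- simulate_cohort(cfg)
  s <- grs_score(coh$genotypes, coh$effects)
  expect_equal(sort(unique(s$bin_index)), 1:5)
  expect_equal(length(s$bin_index), 500)
  edges <- attr(s, "edges")
  expect_equal(diff(edges), rep(4, 5))
  expect_true(all(edges %% 4 == 0))
})

test_that("bin summaries report counts, means and standard errors", {
  scored <- tibble::tibble(
    bin_index = c(1L, 1L, 2L, 3L),
    bin_label = c("0-4", "0-4", "4-8", "8-12"),
    phenotype = c(1, 3, 5, 7)
  )
  attr(scored, "edges") <- c(0, 4, 8, 12)
  s <- bin_summary(scored)
  expect_equal(s$n, c(2L, 1L, 1L))
  expect_equal(s$mean_phenotype, c(2, 5, 7))
  expect_equal(s$se_phenotype[1], sd(c(1, 3)) / sqrt(2))
  expect_true(is.na(s$se_phenotype[2]))  # single subject: SE undefined
  expect_equal(s$midpoint, c(2, 6, 10))

  # constant phenotype: all means equal, all (defined) SEs zero
  const <- dplyr::mutate(scored, phenotype = 2)
  attr(const, "edges") <- c(0, 4, 8, 12)
  sc <- bin_summary(const)
  expect_true(all(sc$mean_phenotype == 2))
  expect_true(all(sc$se_phenotype[sc$n > 1] == 0))

  # empty bins are kept with n = 0
  attr(scored, "edges") <- c(0, 4, 8, 12, 16)
  expect_equal(bin_summary(scored)$n, c(2L, 1L, 1L, 0L))
})

test_that("bin correlation handles exact, degenerate and undersized cases", {
  lin <- tibble::tibble(bin_index = 1:4, bin_label = "x",
                        midpoint = c(2, 6, 10, 14), n = c(5L, 5L, 5L, 5L),
                        mean_phenotype = c(8, 6, 4, 2), se_phenotype = 0)
  r <- bin_correlation(lin)
  expect_equal(r$pearson_r, -1)
  expect_equal(r$r_squared, 1)

  flat <- dplyr::mutate(lin, mean_phenotype = 3)
  expect_true(is.na(bin_correlation(flat)$pearson_r))

  expect_error(bin_correlation(lin[1:2, ]), "3 non-empty")
})

test_that("normalized score recovers the true genetic liability as noise vanishes", {
  cfg <- sim_config(n_subjects = 400, n_snps = 25, noise_sd = 1e-4,
                    missing_rate = 0, seed = 23)
  coh <- simulate_cohort(cfg)
  s <- grs_score(coh$genotypes, coh$effects)
  m <- as.matrix(coh$genotypes_complete[-1])
  liability <- drop(m %*% coh$effects$beta)
  expect_gt(cor(s$normalized_score, liability, method = "spearman"), 0.999)
  # and the score is anti-correlated with the phenotype
  expect_lt(cor(s$normalized_score, coh$subjects$phenotype), -0.99)
})

test_that("SNP exclusion drops the SNP and recomputes the panel mean beta", {
  fix <- grs_micro_fixture()
  out <- grs_score(fix$genotypes, fix$effects, exclude = "rs1")
  expect_equal(attr(out, "mean_beta"), mean(c(0.05, 0.06)))
  # S3: dosages rs2=2, rs3=1 -> raw 0.16, normalized 0.16/0.055
  expect_equal(out$raw_score[3], 0.16)
  expect_equal(out$normalized_score[3], 0.16 / 0.055)
  expect_error(grs_score(fix$genotypes, fix$effects,
                         exclude = fix$effects$rsid), "every SNP")
})
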