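test_that("config validation names the offending field", {
  expect_error(sim_config(maf_range = c(0, 0.5)), "maf_range")
  expect_error(sim_config(maf_range = c(0.1, 0.6)), "maf_range")
  expect_error(sim_config(missing_rate = 1), "missing_rate")
  expect_error(sim_config(noise_sd = 0), "noise_sd")
  expect_error(sim_config(n_snps = 0), "n_snps")
  expect_error(sim_config(rare_variant_spec = list(carrier_frequency = 2,
                                                   protective_effect = 3)),
               "rare_variant_spec")
})

test_that("effect tables have positive effects, in-range MAFs, and are reproducible", {
  cfg <- sim_config(n_snps = 55, seed = 1)
  eff <- simulate_effect_table(cfg)
  expect_equal(nrow(eff), 55)
  expect_true(all(eff$beta > 0))
  expect_true(all(eff$maf >= 0.1 & eff$maf <= 0.5))
  expect_false(anyDuplicated(eff$rsid) > 0)
  expect_identical(eff, simulate_effect_table(cfg))

  # degenerate MAF range pins the frequency
  one <- simulate_effect_table(sim_config(n_snps = 1, maf_range = c(0.3, 0.3)))
  expect_equal(one$maf, 0.3)
})

test_that("genotypes follow HWE dosage sampling and the missingness rate", {
  cfg <- sim_config(n_subjects = 10000, n_snps = 1, maf_range = c(0.5, 0.5),
                    missing_rate = 0, seed = 2)
  eff <- simulate_effect_table(cfg)
  g <- simulate_genotypes(eff, cfg)
  dos <- g[[2]]
  expect_false(anyNA(dos))
  # observed allele frequency within 3 binomial SDs of 0.5
  af <- mean(dos) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 10000))
  expect_lt(abs(af - 0.5), 3 * se)

  cfg2 <- sim_config(n_subjects = 1000, n_snps = 55, missing_rate = 0.1, seed = 3)
  eff2 <- simulate_effect_table(cfg2)
  g2 <- simulate_genotypes(eff2, cfg2)
  fr <- mean(is.na(as.matrix(g2[-1])))
  se2 <- sqrt(0.1 * 0.9 / (1000 * 55))
  expect_lt(abs(fr - 0.1), 3 * se2)
})

test_that("null model gives unit phenotype variance and centred Z-scores", {
  # all effect sizes ~0: phenotype is pure noise with sd 1
  cfg <- sim_config(n_subjects = 5000, n_snps = 3,
                    effect_size_distribution = list(name = "uniform",
                                                    min = 1e-9, max = 1e-8),
                    noise_sd = 1, missing_rate = 0, seed = 4)
  coh <- simulate_cohort(cfg)
  expect_equal(var(coh$subjects$phenotype), 1, tolerance = 0.1)
  expect_equal(mean(coh$subjects$ls_z), 0, tolerance = 0.05)
  expect_equal(mean(coh$subjects$hip_z), 0, tolerance = 0.05)
  expect_equal(sd(coh$subjects$ls_z), 1, tolerance = 0.05)
})

test_that("heritability bookkeeping: genetic variance share matches theory", {
  cfg <- sim_config(n_subjects = 20000, n_snps = 30, noise_sd = 0.3,
                    missing_rate = 0, seed = 5)
  coh <- simulate_cohort(cfg)
  eff <- coh$effects
  vg_theory <- sum(2 * eff$maf * (1 - eff$maf) * eff$beta^2)
  h2_theory <- vg_theory / (vg_theory + cfg$noise_sd^2)
  m <- as.matrix(coh$genotypes_complete[-1])
  g_value <- drop(m %*% eff$beta)
  h2_obs <- var(g_value) / var(coh$subjects$phenotype)
  expect_equal(h2_obs, h2_theory, tolerance = 0.05)
})

test_that("true risk score correlates negatively with phenotype for any seed", {
  for (s in c(11, 22, 33)) {
    cfg <- sim_config(n_subjects = 800, n_snps = 20, noise_sd = 0.3,
                      missing_rate = 0, seed = s)
    coh <- simulate_cohort(cfg)
    m <- as.matrix(coh$genotypes_complete[-1])
    score <- drop(m %*% coh$effects$beta)
    expect_lt(cor(score, coh$subjects$phenotype), 0)
    expect_lt(cor(score, coh$subjects$sum_z), 0)
  }
})

test_that("identical config reproduces the cohort bit for bit", {
  cfg <- sim_config(n_subjects = 100, n_snps = 10, seed = 6,
                    rare_variant_spec = list(carrier_frequency = 0.05,
                                             protective_effect = 3))
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$subjects, b$subjects)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$effects, b$effects)
})

test_that("rare protective carriers sit far above the non-carrier mean", {
  cfg <- sim_config(n_subjects = 4000, n_snps = 10, seed = 7,
                    rare_variant_spec = list(carrier_frequency = 0.05,
                                             protective_effect = 3))
  sub <- simulate_cohort(cfg)$subjects
  expect_gt(sum(sub$carrier), 0)
  expect_gt(mean(sub$sum_z[sub$carrier]), mean(sub$sum_z[!sub$carrier]) + 2)
})

test_that("phenotype generation refuses an incomplete genotype matrix", {
  cfg <- sim_config(n_subjects = 50, n_snps = 5, missing_rate = 0.2, seed = 8)
  eff <- simulate_effect_table(cfg)
  g <- simulate_genotypes(eff, cfg)
  expect_error(simulate_phenotypes(g, eff, cfg), "missing")
  # dimension mismatch is caught explicitly
  g0 <- simulate_genotypes(eff, cfg, missing_rate = 0)
  expect_error(simulate_phenotypes(g0[-2], eff, cfg), "match")
})

test_that("pedigree simulation transmits the variant Mendelianly", {
  cfg <- sim_config(seed = 9,
                    rare_variant_spec = list(carrier_frequency = 0.01,
                                             protective_effect = 3))
  none <- simulate_pedigree(FALSE, 50, cfg)
  expect_identical(unique(none$carrier), "non-carrier")

  big <- simulate_pedigree(TRUE, 10000, cfg)
  off <- big[big$relation == "offspring", ]
  frac <- mean(off$carrier == "carrier")
  expect_lt(abs(frac - 0.5), 3 * sqrt(0.25 / 10000))

  # penetrant effect, vanishing individual variation: carriers separate
  tiny <- simulate_pedigree(TRUE, 30, cfg, latent_sd = 1e-3)
  expect_gt(min(tiny$sum_z[tiny$carrier == "carrier"]),
            max(tiny$sum_z[tiny$carrier == "non-carrier"]))
})

test_that("Ct panels encode the designed structure", {
  cfg <- sim_config(seed = 10)
  sheet <- tibble::tibble(sample = sprintf("s%d", 1:6),
                          sum_z = c(5.1, 5.3, 2.4, 0.4, -0.7, -2.2))
  expect_error(simulate_ct_panel(5, sheet, c(NOPE = 1), cfg), "not in panel")

  panel <- simulate_ct_panel(10, sheet, c(G01 = 0.3), cfg)
  expect_equal(nrow(panel), 10 * 6 * 3)
  # reference gene has the minimum cross-sample CV by construction
  ref <- select_reference_gene(panel, unique(panel$gene))
  expect_identical(as.character(ref), "REF")
  # the trend gene's mean Ct rises with sum Z
  m <- panel |>
    dplyr::filter(gene == "G01") |>
    dplyr::group_by(sample) |>
    dplyr::summarise(ct = mean(ct)) |>
    dplyr::left_join(sheet, by = "sample")
  expect_gt(cor(m$ct, m$sum_z), 0.5)

  expect_identical(panel, simulate_ct_panel(10, sheet, c(G01 = 0.3), cfg))
})
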