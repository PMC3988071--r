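# hbmgrs

Tools for dissecting **high bone mass (HBM)** as an extreme phenotype in
DXA-scanned postmenopausal cohorts: is an unusually dense skeleton the lucky
end of a polygenic continuum, or the signature of a rare, highly penetrant
protective allele?

The package is aimed at statistical geneticists and bone-biology groups who
work with subject tables of DXA Z-scores, SNP effect panels, genotype
matrices, nuclear pedigrees and qPCR Ct panels. Everything takes a data
frame first and returns a tibble, so the stages chain with the pipe.

## What it computes

- **Extreme-phenotype ascertainment** — HBM cases are subjects with
  *sum Z-score* = lumbar-spine Z + hip Z ≥ 4; prevalence among scanned
  subjects; DNA/genotyping availability filters. A 16-case published subject
  table ships as the canonical fixture (`hbm_table1()`).
- **Weighted genetic risk score** — per SNP, score = dosage × β, where β is
  the BMD decrease per risk allele (homozygous risk 2β, heterozygous β,
  other homozygote 0); missing genotypes imputed by the reference cohort's
  mean SNP score; per-subject sums normalized by the panel's mean β to an
  effective risk-allele count

  `GRS_i = (Σ_j g_ij β_j) / mean(β)`

  then sorted into five width-4 bins with per-bin counts, mean phenotype,
  standard errors, and the bin-level Pearson correlation.
- **Robust skewness** — the medcouple MC ∈ [−1, 1] (median of the kernel
  `h(x_i, x_j) = ((x_j − m) − (m − x_i))/(x_j − x_i)` over pairs straddling
  the sample median, O(n log n) C++ implementation), tail weights LMC/RMC,
  seeded percentile-bootstrap confidence intervals, and a two-group
  CI-overlap comparison.
- **Cosegregation** — dominant fully penetrant model in nuclear pedigrees,
  with concordance/discordance counts (fixtures: `hbm_pedigree()`).
- **qPCR expression screen** — reference gene by minimum coefficient of
  variation, ΔCt relative expression (`2^−ΔCt`), symmetric ≥2-fold
  case/control screen, expression-vs-Z linear trends (slope, R², no
  p-values), and ≥5-fold outlier flags.
- **Synthetic cohorts** — Hardy–Weinberg genotypes, additive phenotypes with
  Gaussian noise, correlated lumbar-spine/hip Z-scores, optional rare
  protective variants, Mendelian pedigrees and Ct panels, all bit-for-bit
  reproducible from a seed (`sim_config()`, `simulate_cohort()`), so the
  whole pipeline is testable without any subject-level data.

## Worked example

```r
library(hbmgrs)
library(dplyr)

# 1. Ascertain HBM cases in the published subject table
t1 <- hbm_table1()
cases <- ascertain_hbm(t1, threshold = 4)           # 16 cases
prevalence(nrow(filter(cases, cohort == "BARCOS")), 1600)
#> 0.625 with label "0.63%"

# 2. Score a cohort-scale simulation (one SNP excluded: 54 effective)
coh <- simulate_cohort(sim_config(n_subjects = 1001, n_snps = 55, seed = 1))
sc  <- grs_score(coh$genotypes, coh$effects, exclude = coh$effects$rsid[1])
scph <- left_join(sc, coh$subjects[c("id", "sum_z", "phenotype")], by = "id")
attr(scph, "edges") <- attr(sc, "edges")
bins <- bin_summary(scph)
bin_correlation(bins)
#>   pearson_r p_value r_squared n_bins
#>      -0.977 0.00425     0.954      5

# 3. Compare skewness of the cohort vs its extreme top tail
cmp <- compare_skewness(scph$normalized_score,
                        scph$normalized_score[scph$sum_z >= 4],
                        n_boot = 2000, seed = 2)
cmp
#> Skewness comparison (medcouple bootstrap CI overlap rule)
#>   group x: MC = -0.007599, CI (-0.09218, 0.04426), n = 1001
#>   group y: MC = 0.48, CI (-0.5648, 0.7978), n = 15
#>   verdict: overlapping (no difference in skewness can be claimed)

# 4. Dominant-model cosegregation in the published trio
cosegregation_check(hbm_pedigree("hbm15"))
#> Cosegregation (dominant, fully penetrant; sum Z threshold 4)
#>   verdict: consistent (3 concordant, 0 discordant, 0 uninformative)
```

Reading the output: the five score bins hold 86/191/298/265/161 subjects
and their mean phenotype declines as the effective risk-allele count rises
(bin-level Pearson r = −0.977) — the polygenic signature. The extreme
subgroup's score distribution sits lower but its skewness interval is far
too wide at n = 15 to claim a distributional difference — the small-sample
conclusion this analysis is designed to make honestly. The trio's carrier
members are exactly its affected members, consistent with a dominant
protective variant.

`run_pipeline(hbm_config(...))` chains all stages (simulate → ascertain →
score → skew → segregate → express) and writes per-stage TSVs plus a
deterministic human-readable report; `plot_grs_bins()` and `autoplot()`
methods draw the bin histogram with phenotype means, the CI comparison and
expression trends. The methods vignette
(`vignettes/hbm-analysis-methods.Rmd`) documents the model, defaults and
numerical choices.

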