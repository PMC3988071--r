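---
title: "Methods: polygenic scores, robust skewness and expression screening for high bone mass cohorts"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic scores, robust skewness and expression screening for high bone mass cohorts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hbmgrs)
library(dplyr)
```

# The scientific problem

Bone mineral density (BMD) is approximately Gaussian in the general
population. The two tails of that distribution are of genetic interest:
individuals with extremely high BMD ("high bone mass", HBM) may carry rare,
highly penetrant protective alleles, or may simply sit at the fortunate end
of a polygenic continuum of common variants with small additive effects. The
two hypotheses make different predictions about an HBM case's burden of
common BMD-decreasing risk alleles: under the polygenic model HBM cases
should carry *fewer* risk alleles than the population; under the Mendelian
model their common-variant burden should look ordinary (or even high), with
one large-effect variant doing the work.

`hbmgrs` implements the analysis pipeline for testing these predictions in a
DXA-scanned postmenopausal cohort:

1. **Ascertainment.** HBM cases are subjects whose *sum Z-score* — lumbar
   spine Z plus hip (femoral) Z — is at least 4. We use "hip" throughout for
   what some tables call the total femoral neck Z-score; the two names refer
   to the same column. The threshold is inclusive (≥ 4): every case in the
   packaged 16-row case table satisfies both the inclusive and the strict
   reading, but the inclusive rule is the one the ascertainment text states.
2. **Weighted genetic risk score (GRS).** Per SNP, score = risk-allele dosage
   × effect size β (the BMD decrease per allele, so homozygous risk = 2β,
   heterozygous = β, other homozygote = 0). Missing genotypes receive the
   mean of that SNP's scores in a reference cohort; per-subject scores are
   the row sums, normalized by the mean β of the panel to an *effective
   risk-allele count* in [0, 2·n_snps], then sorted into five width-4 bins.
3. **Robust skewness.** The score distributions of the full cohort and the
   tiny HBM subgroup are compared by the medcouple (MC) with left/right
   tail-weight measures (LMC, RMC) and bootstrap confidence intervals;
   overlapping intervals mean no difference may be claimed.
4. **Cosegregation.** Candidate rare variants are checked against nuclear
   pedigrees under a dominant, fully penetrant model.
5. **Expression screen.** A qPCR panel is normalized by the ΔCt method
   against a reference gene chosen by minimum coefficient of variation,
   genes with ≥ 2-fold case/control differences are selected, and selected
   genes are regressed on sum Z-scores (slope, R²; deliberately no p-value —
   with a handful of primary-culture samples the regression assumptions
   cannot be verified).

# The synthetic-cohort generator

No subject-level genotype or DXA data are distributable, so the package
ships a generator whose defaults encode the study conditions the analysis
assumes, and every stage is exercised end to end on its output.

## Generative model

For subject $i$ with dosage $g_{ij} \sim \mathrm{Binomial}(2, p_j)$ at SNP
$j$ (Hardy–Weinberg, no linkage disequilibrium):

$$\mathrm{phenotype}_i = \mathrm{baseline} - \sum_j \beta_j g_{ij} +
\varepsilon_i, \qquad \varepsilon_i \sim N(0, \sigma^2).$$

The latent phenotype is standardized against the simulated cohort, giving a
latent Z. Lumbar-spine and hip Z-scores are two noisy views of that latent Z
sharing a fraction $\rho$ of their variance:

$$\mathrm{lsZ}_i = \sqrt{\rho}\, L_i + \sqrt{1-\rho}\, e_{1i}, \qquad
\mathrm{hipZ}_i = \sqrt{\rho}\, L_i + \sqrt{1-\rho}\, e_{2i},$$

so each is standard Gaussian marginally, their correlation is $\rho$, and
the sum Z-score has variance $2 + 2\rho$. An optional rare protective
variant adds a fixed shift (default +3 latent SD) to heterozygous carriers —
dominance with full penetrance, which is what a three-person pedigree can
speak to.

## Defaults and why

| parameter | default | rationale |
|---|---|---|
| `n_subjects` | 1001 | the genotyped cohort subset size |
| `n_snps` | 55 | one SNP per autosomal BMD locus on the panel |
| `maf_range` | (0.1, 0.5) | common GWAS variants |
| β distribution | Uniform(0.02, 0.08) | mean 0.05, the per-allele scale on which a raw score of 2.4 normalizes to 48 effective alleles |
| `noise_sd` | 1 | environmental variance dominates; the 55 loci explain a few percent of phenotype variance, as GWAS panels do |
| `missing_rate` | 0.02 | realistic genotyping failure, MCAR |
| `z_correlation` ρ | 0.6 | within-subject LS–hip correlation; no empirical value is published for this design, so 0.6 is a design guess to be varied in sensitivity analyses, not an inference |
| protective shift | +3 SD | large enough that carriers are usually ascertained, small enough that not all are |
| Ct replicate SD | 0.15 cycles | typical qPCR triplicate noise |
| Ct per-sample SD | 0.25 cycles | modest biological variation between donors for non-reference genes; gives a near-zero false-positive rate in the 2-fold screen at triplicate noise |

With ρ = 0.6 the tail probability $P(\text{sum Z} \ge 4) \approx 1.3\%$,
the same order of magnitude as the ~0.6% prevalence seen in a real scanned
cohort. We kept the stated ρ default rather than back-solving ρ from the
prevalence, because ρ is a measurement-design quantity and prevalence is an
output, not a dial.

## What the generator does *not* emulate

No linkage disequilibrium between SNPs, no age or menopause covariates, no
genotype-calling error model, no plate effects in qPCR. Passing tests on
synthetic cohorts therefore demonstrate that the *procedures* are correct
under the stated model — they cannot certify conclusions about any real
cohort where those ignored structures matter.

# Numerical and design choices

**Medcouple.** MC is the median of the kernel
$h(x_i, x_j) = \frac{(x_j - m) - (m - x_i)}{x_j - x_i}$ over pairs
$x_i \le m \le x_j$ ($m$ the sample median; even-sized samples use the mean
of the two central order statistics). Pairs of observations tied at the
median use the standard index-based tie kernel, whose $k \times k$ block is,
as a multiset, $\{-1^{(k(k-1)/2)}, 0^{(k)}, +1^{(k(k-1)/2)}\}$ — keeping MC
well defined for heavily tied small samples such as an 11-score subgroup.
The implementation is the $O(n \log n)$ selection algorithm on the
implicitly sorted kernel matrix (written in C++), selecting both central
order statistics so the result equals the naive full-enumeration median
exactly; the test suite verifies that equality against an independent
brute-force enumeration on hundreds of random samples. Degenerate inputs
(n < 3 or zero spread) return `NA` rather than raising, so batch pipelines
survive degenerate bins.

**Confidence intervals.** The interval for MC is a percentile bootstrap
(default B = 2000, seeded, deterministic). The construction is pluggable so
an influence-function asymptotic interval can be added later; the bootstrap
was chosen as default because it is distribution-free and directly testable
by coverage simulation — the suite checks 93–97% coverage at n = 1000 over
500 replicates (B = 199 per replicate inside the simulation loop, a
problem-size choice that leaves coverage at nominal level). Two-group
comparison uses the CI-overlap rule: overlap ⇒ no claim of difference. At
n = 11 the interval is wide (span typically > 1), which is exactly the
small-sample behaviour that prevents formal claims about an extreme
subgroup.

**Tail weights.** LMC = −MC of the half-sample at or below the median,
RMC = +MC of the half-sample at or above it (tail-weight sign convention):
for a Gaussian both sit near 0.2; a right-heavy sample has RMC > LMC.

**Score normalization.** "Mean effect size" is read as the mean of the
per-SNP βs over the panel actually scored — the only reading that lands
scores on the effective-allele-count scale on which five-bin labels like
"44–48" and "48–52" make sense. Excluded SNPs (e.g. one with conflicting
genotyping results) are dropped *before* the mean is taken.

**Bins.** Width-4 bins anchored at multiples of 4, positioned so the middle
bin contains the reference cohort's median score; scores outside the edges
are clamped into the terminal bins (a five-bin partition cannot literally
cover a 54-SNP cohort's score range, and the published bin counts imply
exactly this clamping). Intervals are left-closed/right-open with a closed
last bin so the maximum is never lost. Bin–phenotype correlation uses bin
midpoints (equivalent to bin indices for equal widths, but stated for
reproducibility) and the conventional two-sided t-test on n_bins − 2 degrees
of freedom.

**Imputation.** Mean-score imputation preserves the cohort mean and shrinks
the variance — the suite verifies both. The reference cohort for imputation
defaults to the scored cohort itself; when scoring a small proband set, pass
the population cohort explicitly (probands are then *not* part of the
reference means, the conservative reading where the design is ambiguous).

**ΔCt, not ΔΔCt.** The screen compares group means of reference-normalized
expression, so any calibrator sample would cancel; amplification efficiency
is fixed at 2.0 (perfect doubling). The reference-gene CV is computed on the
per-sample mean Ct scale, the scale on which reference stability is
conventionally assessed. A replicate-outlier rule (drop a replicate > 1
cycle from the triplicate median) is available but off by default.

**Cosegregation.** The dominant model is fully penetrant: one discordant
informative member makes the verdict "inconsistent"; fewer than two
informative members make it "uninformative". Discordance counts are always
reported so partial-penetrance reasoning stays possible downstream. The
packaged family-of-the-outlier-case pedigree has phenotypes but no
genotypes, and is correctly uninformative.

# Problem sizes in the test suite

The suite's simulations are sized to be decisive yet quick: 500 random
samples for medcouple/brute-force equality; 500 seeded replicates (n = 1000,
B = 199) for bootstrap coverage; 50 seeds of a 1001 × 55 cohort (one SNP
excluded, 54 effective) for the bin-gradient distributional checks; 40 seeds
of a 2000-subject cohort with a 2% carrier frequency for the rare-variant
discordance scenario; 25 seeds of the 88-gene panel for the screen funnel.
These sizes are the package's own choices for stable Monte-Carlo behaviour.

# Known limitations

- The published per-subject scores behind the printed skewness intervals are
  unavailable, so those intervals serve only as qualitative width references
  (one of them even extends below −1, outside MC's range; we make no attempt
  to reproduce that construction).
- The bin-level Pearson r of any real cohort is likewise not recomputable;
  the package instead verifies the distributional property (strongly
  negative bin-level r under additive architecture) across seeds.
- No LD pruning or clumping+thresholding PRS variants, no covariate
  adjustment, no LOD-score linkage — all out of scope for this design.
- The two-group skewness comparison is an interval-overlap heuristic, not a
  formal test; that conservatism is intentional and matches the inference
  rule the analysis is built around.

# A compact end-to-end run

```{r pipeline, eval = FALSE}
cfg <- hbm_config(sim = list(n_subjects = 1001, n_snps = 55), seed = 1)
run <- run_pipeline(cfg, out_dir = "hbm_run")
print(run)
```

The report echoes every threshold and seed, per-stage TSVs land next to it,
and an identical config reproduces the report byte for byte.
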