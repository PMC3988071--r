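# Independent brute-force medcouple: explicit double loop over all pairs
# (x_i <= m <= x_j) with the index-based tie kernel, written directly from the
# estimator's definition. Deliberately shares no code with the package path.
mc_bruteforce <- function(x) {
  x <- sort(x[is.finite(x)])
  n <- length(x)
  if (n < 3L || x[1] == x[n]) return(NA_real_)
  m <- if (n %% 2 == 1) x[(n + 1) / 2] else (x[n / 2] + x[n / 2 + 1]) / 2
  lo <- x[x <= m]          # ascending
  up <- x[x >= m]          # ascending
  k <- sum(x == m)
  H <- numeric(0)
  for (ai in seq_along(lo)) {
    for (bj in seq_along(up)) {
      a <- lo[ai]; b <- up[bj]
      if (a == m && b == m) {
        i <- ai - (length(lo) - k)   # 1..k among the lower-half ties
        j <- bj                      # 1..k among the upper-half ties
        H <- c(H, sign(i + j - 1 - k))
      } else {
        H <- c(H, ((b - m) - (m - a)) / (b - a))
      }
    }
  }
  median(H)
}

# Random test samples: mixture of continuous and heavily tied integer draws.
random_mc_sample <- function(n, tied = FALSE) {
  if (tied) as.numeric(sample(-3:3, n, replace = TRUE))
  else rnorm(n)
}

# Hand-computed micro-fixture: 3 subjects x 3 SNPs, betas 0.04/0.05/0.06.
# S2's missing call at snp1 is imputed from the mean snp1 score of the other
# two subjects: mean(dosage 2, 1) = 1.5 -> score 1.5 * 0.04 = 0.06.
grs_micro_fixture <- function() {
  effects <- tibble::tibble(
    rsid = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "C", "G"),
    other_allele = c("G", "T", "A"),
    beta = c(0.04, 0.05, 0.06),
    maf = c(0.3, 0.2, 0.4)
  )
  genotypes <- tibble::tibble(
    id = c("S1", "S2", "S3"),
    rs1 = c(2L, NA, 1L),
    rs2 = c(1L, 0L, 2L),
    rs3 = c(0L, 2L, 1L)
  )
  # hand oracle (mean beta = 0.05):
  #   S1 raw = 2*.04 + 1*.05 + 0*.06            = 0.13 -> normalized 2.6
  #   S2 raw = 0.06 (imputed) + 0 + 2*.06       = 0.18 -> normalized 3.6
  #   S3 raw = 1*.04 + 2*.05 + 1*.06            = 0.20 -> normalized 4.0
  expected <- tibble::tibble(
    id = c("S1", "S2", "S3"),
    raw_score = c(0.13, 0.18, 0.20),
    normalized_score = c(2.6, 3.6, 4.0),
    n_imputed = c(0L, 1L, 0L)
  )
  list(effects = effects, genotypes = genotypes, expected = expected)
}
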