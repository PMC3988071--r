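#' Sum Z-score
#'
#' The ascertainment statistic for high bone mass: lumbar-spine Z plus
#' hip (femoral) Z. Vectorized.
#'
#' @param ls_z,hip_z Finite numeric Z-scores (dimensionless).
#' @return `ls_z + hip_z`.
#' @examples
#' compute_sum_z(3.4, 2.7) # 6.1
#' @export
compute_sum_z <- function(ls_z, hip_z) {
  if (!is.numeric(ls_z) || !is.numeric(hip_z) ||
      !all(is.finite(ls_z)) || !all(is.finite(hip_z)))
    abort("`ls_z` and `hip_z` must be finite numerics.")
  ls_z + hip_z
}

# Ensure a subject table has a sum_z column, computing or checking it.
# Printed tables are rounded to one decimal, so |sum - (ls + hip)| <= 0.05
# is treated as consistent.
ensure_sum_z <- function(subjects, tol = 0.05) {
  if (!all(c("ls_z", "hip_z") %in% names(subjects)) &&
      !"sum_z" %in% names(subjects))
    abort("subject table needs `sum_z` or both `ls_z` and `hip_z`.")
  if (!"sum_z" %in% names(subjects)) {
    subjects$sum_z <- compute_sum_z(subjects$ls_z, subjects$hip_z)
  } else if (all(c("ls_z", "hip_z") %in% names(subjects))) {
    dev <- abs(subjects$sum_z - (subjects$ls_z + subjects$hip_z))
    if (any(dev > tol, na.rm = TRUE))
      warn(sprintf(
        "%d row(s) fail the sum_z = ls_z + hip_z consistency check (> %.2f): %s",
        sum(dev > tol, na.rm = TRUE), tol,
        paste(utils::head(subjects$id[which(dev > tol)], 5), collapse = ", ")))
  }
  subjects
}

#' Ascertain high-bone-mass cases from a subject table
#'
#' Keeps the rows whose sum Z-score is at or above `threshold` (default 4,
#' the conventional HBM criterion), preserving the input order. `sum_z` is
#' computed from `ls_z + hip_z` when absent; when both are present a
#' consistency warning is emitted for rows where they disagree by more than
#' 0.05 (one-decimal rounding tolerance).
#'
#' @param subjects Subject tibble (see [hbm_table1()] for the canonical
#'   columns).
#' @param threshold HBM sum Z-score cutoff, inclusive (default 4).
#' @return The qualifying rows, as a tibble.
#' @examples
#' ascertain_hbm(hbm_table1())            # all 16 printed cases
#' ascertain_hbm(hbm_table1(), threshold = 7)
#' @export
ascertain_hbm <- function(subjects, threshold = 4) {
  if (!is.data.frame(subjects)) abort("`subjects` must be a data frame.")
  subjects <- as_tibble(subjects)
  if (nrow(subjects) == 0L) return(subjects)
  subjects <- ensure_sum_z(subjects)
  filter(subjects, .data$sum_z >= threshold)
}

#' Prevalence of cases among scanned individuals
#'
#' @param n_cases Number of cases (0 <= n_cases <= n_scanned).
#' @param n_scanned Number of individuals scanned (> 0).
#' @param digits Rounding for the formatted report string (default 2).
#' @return The percentage `100 * n_cases / n_scanned`, with attribute
#'   `"label"` holding the rounded report string (e.g. "0.63%").
#' @examples
#' prevalence(10, 1600) # 0.625, reported "0.63%"
#' @export
prevalence <- function(n_cases, n_scanned, digits = 2) {
  if (!is.numeric(n_cases) || !is.numeric(n_scanned) ||
      length(n_cases) != 1L || length(n_scanned) != 1L ||
      is.na(n_cases) || is.na(n_scanned))
    abort("`n_cases` and `n_scanned` must be single counts.")
  if (n_scanned <= 0) abort("`n_scanned` must be > 0.")
  if (n_cases < 0 || n_cases > n_scanned)
    abort("need 0 <= n_cases <= n_scanned.")
  p <- 100 * n_cases / n_scanned
  # half-up rounding (0.625 -> 0.63), not the IEEE half-even of round()
  r <- floor(p * 10^digits + 0.5) / 10^digits
  structure(p, label = paste0(format(r, nsmall = digits), "%"))
}

#' Filter a subject table on an availability flag
#'
#' @param subjects Subject tibble with logical availability flags.
#' @param flag Which flag to require: `"dna_available"` or `"genotyped"`.
#' @return The rows where the flag is `TRUE`.
#' @examples
#' filter_available(hbm_table1(), "dna_available") # 13 of 16
#' @export
filter_available <- function(subjects, flag = c("dna_available", "genotyped")) {
  flag <- match.arg(flag)
  if (!flag %in% names(subjects))
    abort(sprintf("subject table has no `%s` column.", flag))
  filter(as_tibble(subjects), .data[[flag]])
}

#' The 16 published HBM cases (packaged fixture)
#'
#' The canonical subject table of the study this package models: sixteen
#' postmenopausal women with sum Z-score >= 4 (ten ascertained in the BARCOS
#' cohort of 1600 scanned women, six recruited at other centres), with
#' lumbar-spine and hip Z-scores, age, cohort label, and availability flags.
#' DNA was unavailable for HBM1, HBM8 and HBM11; genotyping failed for HBM14
#' and HBM16, leaving 11 genotyped cases.
#'
#' @return A 16-row subject tibble.
#' @examples
#' hbm_table1()
#' @export
hbm_table1 <- function() {
  path <- system.file("extdata", "hbm_cases_table1.tsv", package = "hbmgrs",
                      mustWork = TRUE)
  read_subjects(path)
}
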