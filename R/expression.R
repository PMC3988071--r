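#' Select a reference gene by minimum coefficient of variation
#'
#' Among candidate genes, picks the one whose per-sample mean Ct has the
#' smallest coefficient of variation (sd/mean) across samples — the
#' conventional stability criterion on the Ct scale. Candidates missing in
#' some samples are excluded with a warning; exact CV ties are broken by
#' candidate order, with a warning.
#'
#' @param panel Long Ct tibble (`gene`, `sample`, `replicate`, `ct`).
#' @param candidates Character vector of candidate gene names (must be panel
#'   genes).
#' @return The selected gene name, with attribute `"cv"` (named CVs of all
#'   valid candidates).
#' @export
select_reference_gene <- function(panel, candidates) {
  if (!all(candidates %in% panel$gene))
    abort(paste("candidate(s) not in panel:",
                paste(setdiff(candidates, panel$gene), collapse = ", ")))
  n_samples <- dplyr::n_distinct(panel$sample)
  means <- panel |>
    filter(.data$gene %in% candidates) |>
    group_by(.data$gene, .data$sample) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop")
  counts <- dplyr::count(means, .data$gene)
  incomplete <- counts$gene[counts$n < n_samples]
  if (length(incomplete)) {
    warn(paste("candidate(s) not measured in every sample, excluded:",
               paste(incomplete, collapse = ", ")))
    means <- filter(means, !.data$gene %in% incomplete)
  }
  if (nrow(means) == 0L) abort("no valid reference candidate remains.")
  cv <- means |>
    group_by(.data$gene) |>
    summarise(cv = sd(.data$mean_ct) / mean(.data$mean_ct), .groups = "drop")
  # candidate order, not alphabetical, breaks ties
  cv <- cv[order(match(cv$gene, candidates)), ]
  best <- which(cv$cv == min(cv$cv))
  if (length(best) > 1L)
    warn("CV tie between candidates; keeping the first in candidate order.")
  structure(cv$gene[best[1]], cv = setNames(cv$cv, cv$gene))
}

#' Relative expression by the delta-Ct method
#'
#' Expression of each gene in each sample relative to the reference gene,
#' with perfect doubling per cycle: `2^-(meanCt_gene - meanCt_ref)`.
#' Replicates are aggregated by their mean Ct. Optionally, a replicate more
#' than `outlier_cycles` from the triplicate median can be dropped first
#' (off by default).
#'
#' @param panel Long Ct tibble.
#' @param reference Reference gene name (measured in every sample).
#' @param drop_replicate_outliers Drop replicates deviating more than
#'   `outlier_cycles` from their gene-by-sample median Ct (default FALSE).
#' @param outlier_cycles Deviation threshold in cycles (default 1).
#' @return A tibble `gene`, `sample`, `delta_ct`, `expression` (fold units,
#'   reference-normalized; the reference gene itself is 1 everywhere).
#' @export
relative_expression <- function(panel, reference,
                                drop_replicate_outliers = FALSE,
                                outlier_cycles = 1) {
  if (!reference %in% panel$gene) abort("reference gene not in panel.")
  if (drop_replicate_outliers) {
    panel <- panel |>
      group_by(.data$gene, .data$sample) |>
      filter(abs(.data$ct - median(.data$ct)) <= outlier_cycles) |>
      ungroup()
  }
  means <- panel |>
    group_by(.data$gene, .data$sample) |>
    summarise(mean_ct = mean(.data$ct), .groups = "drop")
  ref <- means |>
    filter(.data$gene == reference) |>
    select("sample", ref_ct = "mean_ct")
  if (dplyr::n_distinct(ref$sample) < dplyr::n_distinct(panel$sample))
    abort("reference gene must be measured in every sample.")
  means |>
    left_join(ref, by = "sample") |>
    mutate(delta_ct = .data$mean_ct - .data$ref_ct,
           expression = 2^(-.data$delta_ct)) |>
    select("gene", "sample", "delta_ct", "expression")
}

#' Two-fold (or k-fold) candidate screen on group mean expression
#'
#' A gene is selected when the ratio of its mean expression in cases to its
#' mean expression in controls is at least `threshold` or at most
#' `1/threshold`. The rule is symmetric: a gene selected at ratio r is
#' selected at 1/r.
#'
#' @param expression Tibble from [relative_expression()].
#' @param cases,controls Character vectors of sample names (>= 1 each).
#' @param threshold Fold-change cutoff (default 2).
#' @return A tibble `gene`, `case_mean`, `control_mean`, `fold_change`,
#'   `selected`, `screenable` (FALSE with NA ratio when the control mean is
#'   zero).
#' @export
fold_change_screen <- function(expression, cases, controls, threshold = 2) {
  if (length(cases) < 1L || length(controls) < 1L)
    abort("need at least one case and one control sample.")
  missing <- setdiff(c(cases, controls), expression$sample)
  if (length(missing))
    abort(paste("sample(s) not in expression table:",
                paste(missing, collapse = ", ")))
  expression |>
    group_by(.data$gene) |>
    summarise(
      case_mean = mean(.data$expression[.data$sample %in% cases]),
      control_mean = mean(.data$expression[.data$sample %in% controls]),
      .groups = "drop"
    ) |>
    mutate(
      screenable = is.finite(.data$control_mean) & .data$control_mean > 0,
      fold_change = ifelse(.data$screenable,
                           .data$case_mean / .data$control_mean, NA_real_),
      selected = .data$screenable &
        (.data$fold_change >= threshold | .data$fold_change <= 1 / threshold)
    )
}

#' Linear trend of expression against sum Z-score
#'
#' Ordinary least squares of relative expression on sum Z across samples.
#' Only slope, intercept and R-squared are reported: with a handful of
#' primary-culture samples the regression assumptions (normality,
#' homoscedasticity) are rarely met, so no p-value is attached.
#'
#' @param expression Tibble from [relative_expression()], restricted to (or
#'   filtered by) `gene`.
#' @param samples Tibble `sample`, `sum_z`.
#' @param gene Gene to fit (default: the single gene present).
#' @return An `expression_trend` list: `gene`, `slope`, `intercept`,
#'   `r_squared`, `n`, `data` (per-sample points), `fit` (the lm object).
#' @export
expression_z_trend <- function(expression, samples, gene = NULL) {
  if (is.null(gene)) {
    gene <- unique(expression$gene)
    if (length(gene) != 1L)
      abort("several genes present; say which one with `gene=`.")
  }
  d <- expression |>
    filter(.data$gene == !!gene) |>
    left_join(samples[c("sample", "sum_z")], by = "sample") |>
    filter(!is.na(.data$expression), !is.na(.data$sum_z))
  if (nrow(d) < 3L)
    abort("expression-Z trend needs at least 3 samples with both values.")
  fit <- lm(expression ~ sum_z, data = d)
  structure(
    list(gene = gene, slope = unname(coef(fit)[2]),
         intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n = nrow(d),
         data = d, fit = fit),
    class = "expression_trend"
  )
}

#' @export
print.expression_trend <- function(x, ...) {
  cat(sprintf("Expression ~ sum Z trend for %s (n = %d)\n", x$gene, x$n))
  cat(sprintf("  slope %.4g, intercept %.4g, R-squared %.3f\n",
              x$slope, x$intercept, x$r_squared))
  cat("  (no p-value: small-sample regression assumptions not relied on)\n")
  invisible(x)
}

#' @rdname expression_z_trend
#' @param x An `expression_trend` object.
#' @param ... Unused.
#' @export
tidy.expression_trend <- function(x, ...) {
  tibble(term = c("(Intercept)", "sum_z"),
         estimate = c(x$intercept, x$slope))
}

#' @rdname expression_z_trend
#' @export
glance.expression_trend <- function(x, ...) {
  tibble(gene = x$gene, slope = x$slope, intercept = x$intercept,
         r_squared = x$r_squared, n = x$n)
}

#' Flag a case sample whose expression is a fold-change outlier
#'
#' Raised when the case's expression is at least `fold` times the control
#' mean (direction `"up"`) or at most the control mean divided by `fold`
#' (`"down"`).
#'
#' @param expression Tibble from [relative_expression()] for one gene.
#' @param case Sample name of the case.
#' @param controls Sample names of the controls (>= 1).
#' @param fold Fold threshold (default 5).
#' @param gene Gene to assess (default: the single gene present).
#' @return A tibble `gene`, `case`, `case_expression`, `control_mean`,
#'   `ratio`, `flagged`, `direction` (`"up"`, `"down"` or NA).
#' @export
outlier_flag <- function(expression, case, controls, fold = 5, gene = NULL) {
  if (length(controls) < 1L) abort("need at least one control.")
  if (is.null(gene)) {
    gene <- unique(expression$gene)
    if (length(gene) != 1L)
      abort("several genes present; say which one with `gene=`.")
  }
  d <- filter(expression, .data$gene == !!gene)
  ce <- d$expression[d$sample == case]
  if (length(ce) != 1L) abort("case sample not found (or duplicated).")
  cm <- mean(d$expression[d$sample %in% controls])
  if (!is.finite(cm) || cm <= 0)
    return(tibble(gene = gene, case = case, case_expression = ce,
                  control_mean = cm, ratio = NA_real_, flagged = NA,
                  direction = NA_character_))
  ratio <- ce / cm
  flagged <- ratio >= fold || ratio <= 1 / fold
  tibble(gene = gene, case = case, case_expression = ce, control_mean = cm,
         ratio = ratio, flagged = flagged,
         direction = if (!flagged) NA_character_
                     else if (ratio >= fold) "up" else "down")
}
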