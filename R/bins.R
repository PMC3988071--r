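#' Sort normalized risk scores into bins
#'
#' Default edges are `n_bins` width-4 intervals at multiples of 4, positioned
#' so the middle bin contains the reference cohort's median score (giving the
#' conventional "44-48", "48-52", ... allele-count labels). Intervals are
#' left-closed, right-open, except the last bin which is closed, so the
#' maximum score is never lost. Scores outside the edges are clamped to the
#' terminal bins — silently for the default (clamping is how the five-bin
#' partition covers the whole cohort), with a warning when `edges` were
#' supplied by the caller.
#'
#' @param scores Normalized scores to bin.
#' @param n_bins Number of bins (>= 2, default 5).
#' @param edges Optional strictly increasing numeric vector of
#'   `n_bins + 1` edges; overrides the default anchoring.
#' @param reference_scores Scores used to anchor the default edges (default:
#'   `scores` themselves).
#' @return A tibble `bin_index` (1..n_bins), `bin_label`, with attribute
#'   `"edges"`.
#' @examples
#' assign_bins(c(44, 47.9, 48), edges = c(44, 48, 52), n_bins = 2)
#' @export
assign_bins <- function(scores, n_bins = 5L, edges = NULL,
                        reference_scores = scores) {
  if (is.null(edges)) {
    if (n_bins < 2L) abort("`n_bins` must be >= 2.")
    anchor <- 4 * floor(median(reference_scores) / 4)
    left <- anchor - 4 * ((n_bins - 1L) %/% 2L)
    edges <- seq(left, by = 4, length.out = n_bins + 1L)
    user_edges <- FALSE
  } else {
    if (any(diff(edges) <= 0)) abort("`edges` must be strictly increasing.")
    n_bins <- length(edges) - 1L
    if (n_bins < 1L) abort("need at least two edges.")
    user_edges <- TRUE
  }
  idx <- findInterval(scores, edges, rightmost.closed = TRUE)
  outside <- idx < 1L | idx > n_bins
  if (any(outside) && user_edges)
    warn(sprintf("%d score(s) outside the supplied edges were clamped to terminal bins.",
                 sum(outside)))
  idx <- pmin(pmax(idx, 1L), n_bins)
  labels <- sprintf("%g-%g", edges[-length(edges)], edges[-1])
  structure(
    tibble(bin_index = as.integer(idx), bin_label = labels[idx]),
    edges = edges
  )
}

#' Per-bin counts and phenotype summaries
#'
#' For each score bin: subject count, mean phenotype, and standard error of
#' the mean (sd/sqrt(n)). Empty bins are kept with count 0 and NA summaries;
#' single-subject bins have an NA standard error.
#'
#' @param scored A tibble with `bin_index`, `bin_label` (e.g. from
#'   [grs_score()]) and a phenotype column.
#' @param phenotype Name of the phenotype column (default `"phenotype"`).
#' @return A tibble `bin_index`, `bin_label`, `midpoint`, `n`,
#'   `mean_phenotype`, `se_phenotype`, one row per bin.
#' @export
bin_summary <- function(scored, phenotype = "phenotype") {
  if (!all(c("bin_index", "bin_label") %in% names(scored)))
    abort("`scored` needs `bin_index` and `bin_label` columns.")
  if (!phenotype %in% names(scored))
    abort(sprintf("no `%s` column in `scored`.", phenotype))
  if (anyNA(scored[[phenotype]]))
    abort("every scored subject needs a phenotype value.")
  edges <- attr(scored, "edges")
  if (is.null(edges)) {
    # no edge metadata: reconstruct skeleton (and midpoints) from the labels
    skel <- dplyr::distinct(scored, .data$bin_index, .data$bin_label) |>
      arrange(.data$bin_index)
    skel$midpoint <- vapply(strsplit(skel$bin_label, "(?<=[0-9])-(?=[0-9.-])", perl = TRUE),
                            function(p) mean(as.numeric(p)), numeric(1))
  } else {
    nb <- length(edges) - 1L
    skel <- tibble(
      bin_index = seq_len(nb),
      bin_label = sprintf("%g-%g", edges[-length(edges)], edges[-1]),
      midpoint = (edges[-length(edges)] + edges[-1]) / 2
    )
  }
  smry <- scored |>
    group_by(.data$bin_index) |>
    summarise(
      n = dplyr::n(),
      mean_phenotype = mean(.data[[phenotype]]),
      se_phenotype = sd(.data[[phenotype]]) / sqrt(dplyr::n()),
      .groups = "drop"
    )
  left_join(skel, smry, by = "bin_index") |>
    mutate(n = ifelse(is.na(.data$n), 0L, as.integer(.data$n))) |>
    arrange(.data$bin_index)
}

#' Bin-level Pearson correlation between score and phenotype
#'
#' Correlates bin midpoints with bin mean phenotypes across non-empty bins
#' (the bin-level summary of how phenotype declines as the genetic risk score
#' rises). The p-value is the conventional two-sided t-transform with
#' n_bins - 2 degrees of freedom.
#'
#' @param summary A [bin_summary()] tibble.
#' @return A tibble `pearson_r`, `p_value`, `r_squared`, `n_bins`. `pearson_r`
#'   is NA (undefined-marked) when the bin means have zero variance.
#' @export
bin_correlation <- function(summary) {
  s <- filter(summary, .data$n > 0, !is.na(.data$midpoint))
  if (nrow(s) < 3L)
    abort("bin correlation needs at least 3 non-empty bins.")
  if (sd(s$mean_phenotype) == 0 || sd(s$midpoint) == 0)
    return(tibble(pearson_r = NA_real_, p_value = NA_real_,
                  r_squared = NA_real_, n_bins = nrow(s)))
  ct <- cor.test(s$midpoint, s$mean_phenotype, method = "pearson")
  tibble(pearson_r = unname(ct$estimate), p_value = ct$p.value,
         r_squared = unname(ct$estimate)^2, n_bins = nrow(s))
}
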