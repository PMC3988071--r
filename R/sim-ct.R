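#' Simulate a qPCR Ct panel
#'
#' Generates triplicate cycle-threshold values for a custom gene panel run on
#' a set of samples with known sum Z-scores. The model per gene g, sample s,
#' replicate r is
#' \deqn{Ct = base_g + slope_g \cdot sumZ_s + u_{gs} + e_{gsr}}
#' with gene baselines uniform on 20-30 cycles, per-sample biological
#' variation \eqn{u} (SD `config$ct_sample_sd`, zero for the designated
#' reference gene, which models a perfectly stable transcript) and replicate
#' noise \eqn{e} (SD `config$ct_replicate_sd`). A negative expression trend
#' with Z corresponds to a positive Ct slope (more cycles = less transcript).
#'
#' @param n_genes Total number of genes including the reference (>= 2).
#' @param samples Tibble with columns `sample`, `sum_z` (and optionally
#'   `group`).
#' @param trend_genes Named numeric vector mapping gene name to Ct slope per
#'   sum-Z unit (empty for a null panel). Names must be panel genes.
#' @param config A [sim_config()].
#' @param reference_gene Name of the designated stable gene (default "REF").
#' @return A long tibble: `gene`, `sample`, `replicate` (1-3), `ct`.
#' @examples
#' sheet <- tibble::tibble(sample = c("c1", "c2"), sum_z = c(0, 5))
#' simulate_ct_panel(3, sheet, c(G01 = 0.3), sim_config(seed = 2))
#' @export
simulate_ct_panel <- function(n_genes, samples, trend_genes = numeric(),
                              config, reference_gene = "REF") {
  stopifnot(inherits(config, "sim_config"))
  if (!is.data.frame(samples) || !all(c("sample", "sum_z") %in% names(samples)))
    abort("`samples` must have columns `sample` and `sum_z`.")
  if (n_genes < 2L) abort("`n_genes` must be >= 2 (reference plus targets).")
  genes <- c(reference_gene, sprintf("G%02d", seq_len(n_genes - 1L)))
  if (length(trend_genes)) {
    if (is.null(names(trend_genes)) || !all(names(trend_genes) %in% genes))
      abort("trend gene not in panel: ",
            paste(setdiff(names(trend_genes), genes), collapse = ", "))
    if (reference_gene %in% names(trend_genes))
      abort("the reference gene cannot be a trend gene.")
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 4L)

  slope <- setNames(numeric(length(genes)), genes)
  slope[names(trend_genes)] <- trend_genes
  base <- setNames(runif(length(genes), 20, 30), genes)
  n_s <- nrow(samples)
  grid <- tidyr::expand_grid(gene = genes, sample = samples$sample)
  grid <- left_join(grid, samples[c("sample", "sum_z")], by = "sample")
  grid$mu <- base[grid$gene] + slope[grid$gene] * grid$sum_z +
    rnorm(nrow(grid), 0, config$ct_sample_sd) *
      (grid$gene != reference_gene)
  out <- tidyr::expand_grid(grid[c("gene", "sample", "mu")], replicate = 1:3)
  out$ct <- out$mu + rnorm(nrow(out), 0, config$ct_replicate_sd)
  out$mu <- NULL
  as_tibble(out)
}
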