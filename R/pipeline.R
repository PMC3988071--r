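#' Pipeline configuration
#'
#' Builds (or reads from YAML) the configuration driving [run_pipeline()]:
#' stage toggles, thresholds, seeds and the synthetic-cohort settings. Any
#' argument overrides the YAML value, which overrides the default.
#'
#' @param path Optional YAML file whose top-level keys mirror the arguments
#'   (`sim` is a nested map of [sim_config()] arguments, `stages` a map of
#'   logical toggles).
#' @param stages Named logical list toggling `simulate`, `ascertain`,
#'   `score`, `skew`, `segregate`, `express`.
#' @param hbm_threshold Sum Z-score ascertainment cutoff (default 4).
#' @param n_scanned Denominator for the prevalence line (default 1600 DXA
#'   scans).
#' @param subjects_file Subject table for the ascertainment stage; `NULL`
#'   uses the packaged 16-case table.
#' @param exclude_snps rsids excluded before scoring (default none).
#' @param n_bins Number of score bins (default 5).
#' @param fold_threshold Expression screen fold cutoff (default 2).
#' @param outlier_fold Expression outlier fold cutoff (default 5).
#' @param alpha,n_boot Skewness CI level and bootstrap size.
#' @param seed Master seed (also seeds the simulation unless `sim$seed` is
#'   given).
#' @param sim List of [sim_config()] overrides for the simulate stage.
#' @return A `run_config` list.
#' @export
hbm_config <- function(path = NULL, stages = list(), hbm_threshold = NULL,
                       n_scanned = NULL, subjects_file = NULL,
                       exclude_snps = NULL, n_bins = NULL,
                       fold_threshold = NULL, outlier_fold = NULL,
                       alpha = NULL, n_boot = NULL, seed = NULL, sim = list()) {
  defaults <- list(
    stages = list(simulate = TRUE, ascertain = TRUE, score = TRUE,
                  skew = TRUE, segregate = TRUE, express = TRUE),
    hbm_threshold = 4, n_scanned = 1600, subjects_file = NULL,
    exclude_snps = character(), n_bins = 5L, fold_threshold = 2,
    outlier_fold = 5, alpha = 0.05, n_boot = 2000L, seed = 1L, sim = list()
  )
  cfg <- defaults
  if (!is.null(path)) {
    y <- yaml::read_yaml(path)
    for (k in intersect(names(y), names(cfg))) {
      cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(y[[k]]))
        utils::modifyList(cfg[[k]], y[[k]]) else y[[k]]
    }
  }
  override <- list(stages = stages, hbm_threshold = hbm_threshold,
                   n_scanned = n_scanned, subjects_file = subjects_file,
                   exclude_snps = exclude_snps, n_bins = n_bins,
                   fold_threshold = fold_threshold, outlier_fold = outlier_fold,
                   alpha = alpha, n_boot = n_boot, seed = seed, sim = sim)
  for (k in names(override)) {
    v <- override[[k]]
    if (is.list(v) && length(v) == 0) next
    if (!is.list(v) && is.null(v)) next
    cfg[[k]] <- if (is.list(cfg[[k]]) && is.list(v))
      utils::modifyList(cfg[[k]], v) else v
  }
  unknown <- setdiff(names(cfg$stages),
                     c("simulate", "ascertain", "score", "skew", "segregate",
                       "express"))
  if (length(unknown))
    abort(paste("unknown stage(s):", paste(unknown, collapse = ", ")))
  structure(cfg, class = "run_config")
}

fmt <- function(...) sprintf(...)

#' Run the full analysis pipeline
#'
#' Sequences the stages simulate -> ascertain -> score -> skew -> segregate
#' -> express on a synthetic cohort plus the packaged fixtures, writes
#' per-stage TSVs and a single human-readable report to `out_dir`, and
#' returns the results. Deterministic: the same config (and seeds) gives a
#' byte-identical report.
#'
#' @param config A [hbm_config()].
#' @param out_dir Output directory (created if missing).
#' @return An `hbm_report` list with `report` (character lines), `files`
#'   (written paths) and per-stage results, invisibly.
#' @examples
#' \donttest{
#' cfg <- hbm_config(sim = list(n_subjects = 120, n_snps = 10), seed = 7)
#' run <- run_pipeline(cfg, out_dir = tempfile("hbm_run_"))
#' }
#' @export
run_pipeline <- function(config, out_dir = tempfile("hbm_run_")) {
  stopifnot(inherits(config, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  on <- config$stages
  files <- character()
  res <- list()
  rpt <- c(
    "High bone mass analysis pipeline report",
    "========================================",
    fmt("seed: %d | HBM threshold: sum Z >= %g | bins: %d | fold screen: %g | outlier fold: %g | alpha: %g | bootstrap: %d",
        config$seed, config$hbm_threshold, config$n_bins,
        config$fold_threshold, config$outlier_fold, config$alpha,
        config$n_boot),
    ""
  )
  save_tsv <- function(x, name, writer = readr::write_tsv) {
    p <- file.path(out_dir, name)
    writer(x, p)
    files[[name]] <<- p
  }

  ## -- simulate ------------------------------------------------------------
  rpt <- c(rpt, "[simulate] synthetic cohort")
  cohort <- NULL
  if (isTRUE(on$simulate)) {
    sim_args <- config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    cohort <- simulate_cohort(scfg)
    save_tsv(cohort$subjects, "subjects.tsv", write_subjects)
    save_tsv(cohort$effects, "effect_table.tsv", write_effect_table)
    save_tsv(cohort$genotypes, "genotypes.tsv", write_genotypes)
    rpt <- c(rpt,
      fmt("  %d subjects x %d SNPs (sim seed %d), missing dosage fraction %.4f",
          nrow(cohort$subjects), nrow(cohort$effects), scfg$seed,
          mean(is.na(genotype_matrix(cohort$genotypes)))))
  } else rpt <- c(rpt, "  skipped")
  rpt <- c(rpt, "")

  ## -- ascertain -----------------------------------------------------------
  rpt <- c(rpt, "[ascertain] extreme-phenotype cases")
  if (isTRUE(on$ascertain)) {
    subjects <- if (is.null(config$subjects_file)) hbm_table1()
                else read_subjects(config$subjects_file)
    cases <- ascertain_hbm(subjects, threshold = config$hbm_threshold)
    barcos <- filter(cases, .data$cohort == "BARCOS")
    prev <- prevalence(nrow(barcos), config$n_scanned)
    with_dna <- filter_available(cases, "dna_available")
    genotyped <- filter_available(with_dna, "genotyped")
    res$ascertain <- list(cases = cases, n_barcos = nrow(barcos),
                          prevalence = prev, n_dna = nrow(with_dna),
                          n_genotyped = nrow(genotyped))
    save_tsv(cases, "hbm_cases.tsv", write_subjects)
    rpt <- c(rpt,
      fmt("  %d cases at sum Z >= %g; %d in BARCOS of %d scanned (prevalence %s)",
          nrow(cases), config$hbm_threshold, nrow(barcos), config$n_scanned,
          attr(prev, "label")),
      fmt("  DNA available: %d; successfully genotyped: %d",
          nrow(with_dna), nrow(genotyped)))
    if (isTRUE(on$simulate)) {
      sim_cases <- ascertain_hbm(cohort$subjects, config$hbm_threshold)
      sim_prev <- prevalence(nrow(sim_cases), nrow(cohort$subjects))
      res$ascertain$sim_cases <- sim_cases
      rpt <- c(rpt, fmt("  simulated cohort: %d of %d subjects (%s)",
                        nrow(sim_cases), nrow(cohort$subjects),
                        attr(sim_prev, "label")))
    }
  } else rpt <- c(rpt, "  skipped")
  rpt <- c(rpt, "")

  ## -- score ---------------------------------------------------------------
  rpt <- c(rpt, "[score] weighted genetic risk score")
  scored <- NULL
  if (isTRUE(on$score)) {
    if (is.null(cohort))
      abort("stage 'score' requires the simulate stage (no genotypes available).")
    scored <- grs_score(cohort$genotypes, cohort$effects,
                        exclude = config$exclude_snps, n_bins = config$n_bins)
    scored_ph <- left_join(scored,
                           cohort$subjects[c("id", "sum_z", "phenotype")],
                           by = "id")
    attr(scored_ph, "edges") <- attr(scored, "edges")
    bins <- bin_summary(scored_ph, phenotype = "phenotype")
    corr <- bin_correlation(bins)
    res$score <- list(scores = scored, bins = bins, correlation = corr)
    save_tsv(scored, "risk_scores.tsv")
    save_tsv(bins, "bin_summary.tsv")
    rpt <- c(rpt,
      fmt("  mean beta %.4f; %d SNPs scored%s", attr(scored, "mean_beta"),
          sum(!names(cohort$genotypes) %in% c("id", config$exclude_snps)),
          if (length(config$exclude_snps))
            fmt(" (excluded: %s)", paste(config$exclude_snps, collapse = ", "))
          else ""),
      fmt("  bin counts: %s", paste(bins$n, collapse = ", ")),
      fmt("  bin means vs midpoints: Pearson r = %.3f, p = %.4g, r^2 = %.3f",
          corr$pearson_r, corr$p_value, corr$r_squared))
  } else rpt <- c(rpt, "  skipped")
  rpt <- c(rpt, "")

  ## -- skew ----------------------------------------------------------------
  rpt <- c(rpt, "[skew] medcouple comparison, cohort vs extreme subgroup")
  if (isTRUE(on$skew)) {
    if (is.null(scored))
      abort("stage 'skew' requires the score stage (no risk scores available).")
    extreme_ids <- ascertain_hbm(cohort$subjects, config$hbm_threshold)$id
    x <- scored$normalized_score
    y <- scored$normalized_score[scored$id %in% extreme_ids]
    cmp <- compare_skewness(x, y, alpha = config$alpha,
                            n_boot = config$n_boot, seed = config$seed)
    res$skew <- cmp
    save_tsv(tidy(cmp), "skewness.tsv")
    rpt <- c(rpt,
      fmt("  cohort (n=%d): MC %.3f, CI (%.3f, %.3f)", cmp$report_x$n,
          cmp$report_x$mc, cmp$report_x$ci_low, cmp$report_x$ci_high),
      fmt("  extreme subgroup (n=%d): MC %.3f, CI (%.3f, %.3f)",
          cmp$report_y$n, cmp$report_y$mc, cmp$report_y$ci_low,
          cmp$report_y$ci_high),
      fmt("  verdict: %s%s", cmp$verdict,
          if (cmp$verdict == "overlapping")
            " -- no difference in skewness can be claimed" else ""))
  } else rpt <- c(rpt, "  skipped")
  rpt <- c(rpt, "")

  ## -- segregate -----------------------------------------------------------
  rpt <- c(rpt, "[segregate] dominant-model cosegregation")
  if (isTRUE(on$segregate)) {
    peds <- list(hbm15 = hbm_pedigree("hbm15"), hbm9 = hbm_pedigree("hbm9"))
    res$segregate <- lapply(peds, cosegregation_check,
                            threshold = config$hbm_threshold)
    for (nm in names(peds)) {
      v <- res$segregate[[nm]]
      rpt <- c(rpt, fmt("  %s pedigree: %s (%d concordant, %d discordant)",
                        nm, v$verdict, v$n_concordant, v$n_discordant))
    }
    save_tsv(bind_rows(lapply(names(res$segregate), function(nm)
      mutate(glance(res$segregate[[nm]]), pedigree = nm))), "cosegregation.tsv")
  } else rpt <- c(rpt, "  skipped")
  rpt <- c(rpt, "")

  ## -- express -------------------------------------------------------------
  rpt <- c(rpt, "[express] qPCR screen on synthetic panel")
  if (isTRUE(on$express)) {
    sim_args <- config$sim
    if (is.null(sim_args$seed)) sim_args$seed <- config$seed
    scfg <- do.call(sim_config, sim_args)
    sheet <- tibble(
      sample = c("HBM_A", "HBM_B", "CTRL_A", "CTRL_B"),
      sum_z = c(5.1, 5.3, -0.7, -2.2),
      group = c("case", "case", "control", "control")
    )
    trend <- setNames(rep(0.3, 11), sprintf("G%02d", 1:11))
    panel <- simulate_ct_panel(88, sheet, trend, scfg)
    ref <- select_reference_gene(panel, c("REF", "G20", "G30"))
    expr <- relative_expression(panel, ref)
    screen <- fold_change_screen(expr, cases = sheet$sample[sheet$group == "case"],
                                 controls = sheet$sample[sheet$group == "control"],
                                 threshold = config$fold_threshold)
    hits <- filter(screen, .data$selected)
    trends <- lapply(hits$gene, function(g)
      glance(expression_z_trend(expr, sheet, gene = g)))
    res$express <- list(panel = panel, reference = ref, screen = screen,
                        trends = bind_rows(trends))
    save_tsv(screen, "expression_screen.tsv")
    save_tsv(res$express$trends, "expression_trends.tsv")
    rpt <- c(rpt,
      fmt("  reference gene by minimum CV: %s", as.character(ref)),
      fmt("  %d of %d genes pass the %g-fold screen: %s",
          nrow(hits), dplyr::n_distinct(screen$gene), config$fold_threshold,
          paste(hits$gene, collapse = ", ")),
      fmt("  trend R^2 over selected genes: %s",
          paste(sprintf("%.3f", res$express$trends$r_squared), collapse = ", ")))
  } else rpt <- c(rpt, "  skipped")

  report_path <- file.path(out_dir, "report.txt")
  writeLines(rpt, report_path)
  files[["report.txt"]] <- report_path
  out <- structure(list(report = rpt, files = files, results = res,
                        config = config, out_dir = out_dir),
                   class = "hbm_report")
  invisible(out)
}

#' @export
print.hbm_report <- function(x, ...) {
  cat(paste(x$report, collapse = "\n"), "\n")
  invisible(x)
}
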