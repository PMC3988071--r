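make_panel <- function(df) {
  # df: gene, sample, ct (one row per replicate via rep)
  tidyr::uncount(df, 3, .id = "replicate") |>
    dplyr::mutate(replicate = as.integer(replicate)) |>
    dplyr::select(gene, sample, replicate, ct)
}

test_that("reference-gene selection minimizes the cross-sample CV of mean Ct", {
  panel <- make_panel(tidyr::expand_grid(
    gene = c("A", "B", "C"), sample = c("s1", "s2", "s3")
  ) |>
    dplyr::mutate(ct = dplyr::case_when(
      gene == "A" ~ 25,                           # zero variance
      gene == "B" ~ 25 + c(0, 1, 2)[match(sample, c("s1", "s2", "s3"))],
      gene == "C" ~ 20 + c(0, 5, 0)[match(sample, c("s1", "s2", "s3"))]
    )))
  sel <- select_reference_gene(panel, c("B", "A", "C"))
  expect_identical(as.character(sel), "A")
  cv <- attr(sel, "cv")
  expect_equal(unname(cv["A"]), 0)

  # minimum rule between two imperfect candidates
  expect_identical(as.character(select_reference_gene(panel, c("B", "C"))), "B")
  # candidate order breaks exact ties
  tied <- dplyr::bind_rows(panel,
    dplyr::mutate(dplyr::filter(panel, gene == "A"), gene = "D"))
  expect_warning(sel2 <- select_reference_gene(tied, c("D", "A")), "tie")
  expect_identical(as.character(sel2), "D")

  # candidates missing a sample are excluded with a warning
  holey <- dplyr::filter(panel, !(gene == "A" & sample == "s3"))
  expect_warning(sel3 <- select_reference_gene(holey, c("A", "B")), "excluded")
  expect_identical(as.character(sel3), "B")
  expect_error(select_reference_gene(panel, "ZZZ"), "not in panel")
})

test_that("delta-Ct relative expression doubles per cycle", {
  panel <- make_panel(tibble::tibble(
    gene = c("REF", "up", "down", "same"),
    sample = "s1",
    ct = c(25, 24, 26, 25)
  ))
  e <- relative_expression(panel, "REF")
  get <- function(g) e$expression[e$gene == g]
  expect_equal(get("same"), 1)    # delta Ct 0
  expect_equal(get("down"), 0.5)  # delta Ct +1
  expect_equal(get("up"), 2)      # delta Ct -1
  expect_equal(get("REF"), 1)     # reference vs itself
})

test_that("relative expression is invariant to a per-sample global Ct shift", {
  set.seed(51)
  panel <- make_panel(tidyr::expand_grid(
    gene = c("REF", "g1", "g2"), sample = c("s1", "s2")
  ) |> dplyr::mutate(ct = runif(dplyr::n(), 20, 30)))
  base <- relative_expression(panel, "REF")
  shifted <- panel |>
    dplyr::mutate(ct = ct + ifelse(sample == "s1", 3.3, -1.7))
  expect_equal(relative_expression(shifted, "REF")$expression, base$expression)
})

test_that("replicate outlier dropping is available but off by default", {
  panel <- tibble::tibble(
    gene = rep(c("REF", "g"), each = 3),
    sample = "s1",
    replicate = rep(1:3, 2),
    ct = c(25, 25, 25, 24, 24, 30)  # one aberrant replicate for g
  )
  default <- relative_expression(panel, "REF")
  cleaned <- relative_expression(panel, "REF", drop_replicate_outliers = TRUE)
  expect_equal(default$expression[default$gene == "g"], 2^-(26 - 25))
  expect_equal(cleaned$expression[cleaned$gene == "g"], 2^-(24 - 25))
})

test_that("fold-change screen applies a symmetric two-fold rule", {
  expr <- tibble::tibble(
    gene = rep(c("hit", "miss", "downhit"), each = 4),
    sample = rep(c("case1", "case2", "ctl1", "ctl2"), 3),
    delta_ct = 0,
    expression = c(4, 4, 1.9, 1.9,   # ratio 2.105 -> selected
                   1, 1, 1.9, 1.9,   # ratio 0.526 -> not selected
                   1, 1, 4.2, 4.2)   # ratio 0.238 -> selected (down)
  )
  s <- fold_change_screen(expr, c("case1", "case2"), c("ctl1", "ctl2"))
  sel <- setNames(s$selected, s$gene)
  expect_true(sel[["hit"]])
  expect_false(sel[["miss"]])
  expect_true(sel[["downhit"]])

  # symmetry: swapping cases and controls selects the same genes
  s2 <- fold_change_screen(expr, c("ctl1", "ctl2"), c("case1", "case2"))
  expect_equal(dplyr::arrange(s, gene)$selected, dplyr::arrange(s2, gene)$selected)

  # zero control mean is unscreenable, not an error
  z <- dplyr::mutate(expr, expression = ifelse(sample %in% c("ctl1", "ctl2"),
                                               0, expression))
  sz <- fold_change_screen(z, c("case1", "case2"), c("ctl1", "ctl2"))
  expect_true(all(!sz$screenable))
  expect_true(all(is.na(sz$fold_change)))
  expect_error(fold_change_screen(expr, character(), "ctl1"), "at least one")
})

test_that("expression-Z trend fits OLS and reports R-squared without p-values", {
  samples <- tibble::tibble(sample = c("a", "b", "c", "d"),
                            sum_z = c(0, 1, 2, 3))
  colinear <- tibble::tibble(gene = "g", sample = samples$sample,
                             delta_ct = 0, expression = 5 - samples$sum_z)
  fit <- suppressWarnings(expression_z_trend(colinear, samples)) # perfect fit
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, -1)
  expect_equal(fit$intercept, 5)
  expect_false("p.value" %in% names(glance(fit)))
  expect_s3_class(autoplot(fit), "ggplot")

  expect_error(expression_z_trend(colinear[1:2, ], samples), "3 samples")

  # flat construction: slope near 0, R-squared near 0 over seeds
  set.seed(52)
  r2 <- replicate(20, {
    flat <- tibble::tibble(gene = "g", sample = samples$sample, delta_ct = 0,
                           expression = 2 + rnorm(4, 0, 0.1))
    glance(expression_z_trend(flat, samples))$r_squared
  })
  expect_lt(median(r2), 0.5)
})

test_that("fold outliers are flagged with direction", {
  expr <- tibble::tibble(
    gene = "g", sample = c("case", "c1", "c2"),
    delta_ct = 0, expression = c(6, 1, 1)
  )
  up <- outlier_flag(expr, "case", c("c1", "c2"), fold = 5)
  expect_true(up$flagged)
  expect_identical(up$direction, "up")

  down <- outlier_flag(dplyr::mutate(expr,
    expression = c(0.2, 1, 1)), "case", c("c1", "c2"), fold = 5)
  expect_true(down$flagged)
  expect_identical(down$direction, "down")

  mid <- outlier_flag(dplyr::mutate(expr,
    expression = c(2, 1, 1)), "case", c("c1", "c2"), fold = 5)
  expect_false(mid$flagged)
  expect_true(is.na(mid$direction))

  zero <- outlier_flag(dplyr::mutate(expr,
    expression = c(2, 0, 0)), "case", c("c1", "c2"))
  expect_true(is.na(zero$flagged))
})

test_that("screen false positives under a null panel are rare at low noise", {
  sheet <- tibble::tibble(
    sample = c("h1", "h2", "c1", "c2"),
    sum_z = c(5.1, 5.3, -0.7, -2.2),
    group = c("case", "case", "control", "control")
  )
  fp <- vapply(1:15, function(s) {
    cfg <- sim_config(seed = 200 + s, ct_replicate_sd = 0.05)
    panel <- simulate_ct_panel(40, sheet, numeric(), cfg)
    e <- relative_expression(panel, "REF")
    sum(fold_change_screen(e, c("h1", "h2"), c("c1", "c2"))$selected)
  }, numeric(1))
  # directly simulated false-positive rate: essentially zero per panel
  expect_lt(mean(fp), 0.5)
})
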