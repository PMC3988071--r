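#' Plot a score-bin summary
#'
#' Bars give the number of subjects per genetic-risk-score bin; points with
#' error bars (rescaled onto the count axis) give the bin mean phenotype +/-
#' one standard error, the conventional display of a polygenic score's
#' phenotype gradient.
#'
#' @param bins A [bin_summary()] tibble.
#' @return A ggplot object.
#' @export
plot_grs_bins <- function(bins) {
  b <- filter(bins, .data$n > 0)
  rng <- range(b$mean_phenotype, na.rm = TRUE)
  if (diff(rng) == 0) rng <- rng + c(-0.5, 0.5)
  scale <- max(b$n) / diff(rng)
  shift <- rng[1]
  b <- mutate(b,
    y = (.data$mean_phenotype - shift) * scale,
    ymin = (.data$mean_phenotype - .data$se_phenotype - shift) * scale,
    ymax = (.data$mean_phenotype + .data$se_phenotype - shift) * scale
  )
  ggplot2::ggplot(b, ggplot2::aes(x = .data$bin_label)) +
    ggplot2::geom_col(ggplot2::aes(y = .data$n), fill = "grey70") +
    ggplot2::geom_pointrange(
      ggplot2::aes(y = .data$y, ymin = .data$ymin, ymax = .data$ymax),
      shape = 17, colour = "black"
    ) +
    ggplot2::scale_y_continuous(
      "subjects per bin",
      sec.axis = ggplot2::sec_axis(~ . / scale + shift, name = "mean phenotype")
    ) +
    ggplot2::labs(x = "normalized genetic risk score (effective allele count)") +
    ggplot2::theme_minimal()
}

#' @rdname expression_z_trend
#' @param object An `expression_trend` object.
#' @export
autoplot.expression_trend <- function(object, ...) {
  ggplot2::ggplot(object$data,
                  ggplot2::aes(x = .data$sum_z, y = .data$expression)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "steelblue") +
    ggplot2::labs(
      x = "sum Z-score", y = "relative expression (fold)",
      title = sprintf("%s: R² = %.3f", object$gene, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}

#' @rdname compare_skewness
#' @param object A `skew_comparison` object.
#' @export
autoplot.skew_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$group, y = .data$mc)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high)
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(y = "medcouple (bootstrap CI)", x = NULL,
                  title = sprintf("CI overlap verdict: %s", object$verdict)) +
    ggplot2::theme_minimal()
}
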