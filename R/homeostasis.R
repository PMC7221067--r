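# Metabolic-rate homeostasis test: OLS regression of mean segment MR on
# activity index, pooled across flies of one group. A significant positive
# slope means the group fails to hold its metabolic rate constant across
# activity levels ("lost" homeostasis).

#' Regression test of metabolic-rate homeostasis
#'
#' Ordinary least-squares fit of `mean_mr` on `activity_index` over 5-min
#' segments pooled across flies of one group, with a two-sided t-test of
#' the slope. Homeostasis is declared "lost" when the slope is significantly
#' positive at level `alpha`, "maintained" otherwise.
#'
#' @param segments Tibble of segments as produced by [segment_metrics()]
#'   (rows from several flies may be bound together). If `group` is given
#'   and a `genotype` column is present, rows are filtered to that group.
#' @param group Group label for the output (and optional filter).
#' @param alpha Significance level for the slope test. Default 0.05.
#' @return One-row tibble of class `homeostasis_result`: `group`,
#'   `n_segments`, `slope`, `intercept`, `r_squared`, `p_slope`,
#'   `ci_lo`, `ci_hi` (95% CI on the slope) and `verdict`.
#' @export
homeostasis_regression <- function(segments, group = NULL, alpha = 0.05) {
  stopifnot(is.data.frame(segments),
            all(c("mean_mr", "activity_index") %in% names(segments)))
  if (!is.null(group) && "genotype" %in% names(segments) &&
      group %in% segments$genotype) {
    segments <- segments[segments$genotype == group, , drop = FALSE]
  }
  n <- nrow(segments)
  if (n < 3) stop("need at least 3 segments, got ", n)
  x <- segments$activity_index
  y <- segments$mean_mr
  if (stats::var(x) == 0) stop("degenerate regressor: activity index has ",
                               "zero variance")

  fit <- stats::lm(y ~ x)
  sm <- summary(fit)
  slope <- unname(stats::coef(fit)[2])
  ci <- stats::confint(fit, "x", level = 0.95)
  p_slope <- sm$coefficients["x", "Pr(>|t|)"]
  verdict <- if (p_slope < alpha && slope > 0) "lost" else "maintained"

  out <- tibble::tibble(
    group = if (is.null(group)) NA_character_ else as.character(group),
    n_segments = n,
    slope = slope,
    intercept = unname(stats::coef(fit)[1]),
    r_squared = sm$r.squared,
    p_slope = unname(p_slope),
    ci_lo = ci[1, 1],
    ci_hi = ci[1, 2],
    verdict = verdict
  )
  class(out) <- c("homeostasis_result", class(out))
  out
}

#' Plot metabolic rate against activity index with the fitted line
#'
#' Diagnostic scatter of pooled 5-min segments, one fitted OLS line per
#' group. Requires ggplot2.
#'
#' @param segments Segment tibble (possibly several groups).
#' @return A ggplot object.
#' @export
plot_homeostasis <- function(segments) {
  if (!requireNamespace("ggplot2", quietly = TRUE)) {
    stop("ggplot2 is required for plotting")
  }
  ggplot2::ggplot(segments,
                  ggplot2::aes(x = .data$activity_index, y = .data$mean_mr,
                               colour = .data$genotype)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = TRUE) +
    ggplot2::labs(x = "Activity index (a.u. / min)",
                  y = expression("Metabolic rate (" * mu * W ~ mg^-0.856 * ")"))
}
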