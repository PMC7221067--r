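# Lifespan machinery: Kaplan-Meier curves (via the survival package),
# median/maximum lifespan summaries, log-rank and Gehan-Wilcoxon rank tests
# over risk sets, multiple-comparison correction, and the double-mutant
# additivity report.

#' Construct / validate a survival event table
#'
#' @param x Data frame with columns `fly_id`, `genotype`, `condition`,
#'   `time` (> 0; days, or hours for starvation assays) and `status`
#'   (1 = death, 0 = right-censored).
#' @param time_unit `"days"` or `"hours"`; stored as an attribute, never
#'   inferred.
#' @return A tibble of class `survival_table`.
#' @export
survival_table <- function(x, time_unit = c("days", "hours")) {
  time_unit <- match.arg(time_unit)
  need <- c("fly_id", "genotype", "condition", "time", "status")
  missing_cols <- setdiff(need, names(x))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (any(!is.finite(x$time)) || any(x$time <= 0)) {
    stop("event times must be positive and finite")
  }
  if (!all(x$status %in% c(0, 1))) {
    stop("status must be 0 (censored) or 1 (death)")
  }
  if (any(!nzchar(x$genotype)) || any(!nzchar(x$condition))) {
    stop("genotype and condition labels must be non-empty")
  }
  out <- tibble::as_tibble(x[need])
  out$status <- as.integer(out$status)
  attr(out, "time_unit") <- time_unit
  class(out) <- c("survival_table", class(out))
  out
}

group_subset <- function(table, group, by = "genotype") {
  stopifnot(by %in% names(table))
  sub <- table[table[[by]] == group, , drop = FALSE]
  if (nrow(sub) == 0) stop("group `", group, "` not found in `", by, "`")
  sub
}

#' Kaplan-Meier curve for one group
#'
#' Product-limit estimator with right censoring (ties handled by
#' simultaneous decrement), computed with [survival::survfit()].
#'
#' @param table A [survival_table()].
#' @param group Group label.
#' @param by Column the label refers to. Default `"genotype"`.
#' @return A tibble of class `km_curve`: `time`, `n_risk`, `n_event`,
#'   `n_censor`, `surv`, carrying the group label and time unit as
#'   attributes.
#' @export
km_estimate <- function(table, group, by = "genotype") {
  sub <- group_subset(table, group, by)
  if (sum(sub$status) < 1) stop("group `", group, "` has no death events")
  fit <- survival::survfit(survival::Surv(time, status) ~ 1, data = sub)
  out <- tibble::tibble(time = fit$time, n_risk = fit$n.risk,
                        n_event = fit$n.event, n_censor = fit$n.censor,
                        surv = fit$surv)
  attr(out, "group") <- group
  attr(out, "n") <- nrow(sub)
  attr(out, "time_unit") <- attr(table, "time_unit")
  class(out) <- c("km_curve", class(out))
  out
}

#' Median lifespan from a Kaplan-Meier curve
#'
#' Smallest time at which the survival function reaches 0.5 or less. When
#' the curve never reaches 0.5 (heavy censoring) the median is undefined:
#' `NA` is returned with attribute `censored_median = TRUE`.
#'
#' @param curve A [km_estimate()] result.
#' @return Scalar time, with attribute `censored_median`.
#' @export
median_lifespan <- function(curve) {
  stopifnot(inherits(curve, "km_curve"))
  hit <- which(curve$surv <= 0.5)
  if (length(hit) == 0) {
    return(structure(NA_real_, censored_median = TRUE))
  }
  structure(curve$time[hit[1]], censored_median = FALSE)
}

#' Maximum lifespan of a group
#'
#' The longest-lived tail summarized under an explicitly tagged definition:
#' `"top_decile_mean"` (default; mean death age of the longest-lived 10% of
#' dying flies, requiring >= 10 deaths), `"last_death"`, or
#' `"percentile_90"` (linear-interpolation percentile of death ages). With
#' fewer than 10 deaths `top_decile_mean` falls back to `last_death` and is
#' flagged.
#'
#' @inheritParams km_estimate
#' @param definition Which definition to use; always echoed in the output.
#' @return One-row tibble: `group`, `n`, `n_deaths`, `maximum`,
#'   `definition`, `fallback`.
#' @export
maximum_lifespan <- function(table, group,
                             definition = c("top_decile_mean", "last_death",
                                            "percentile_90"),
                             by = "genotype") {
  definition <- match.arg(definition)
  sub <- group_subset(table, group, by)
  deaths <- sort(sub$time[sub$status == 1])
  nd <- length(deaths)
  if (nd == 0) stop("group `", group, "` has no death events")
  fallback <- FALSE
  if (definition == "top_decile_mean" && nd < 10) {
    definition <- "last_death"
    fallback <- TRUE
  }
  maximum <- switch(definition,
    top_decile_mean = mean(deaths[(nd - ceiling(0.1 * nd) + 1):nd]),
    last_death = deaths[nd],
    percentile_90 = stats::quantile(deaths, 0.9, names = FALSE, type = 7))
  tibble::tibble(group = group, n = nrow(sub), n_deaths = nd,
                 maximum = maximum, definition = definition,
                 fallback = fallback)
}

#' Lifespan summary (median + maximum) for one group
#'
#' @inheritParams maximum_lifespan
#' @return One-row tibble: `group`, `n`, `median`, `censored_median`,
#'   `maximum`, `max_definition`.
#' @export
lifespan_summary <- function(table, group,
                             definition = "top_decile_mean",
                             by = "genotype") {
  med <- median_lifespan(km_estimate(table, group, by))
  mx <- maximum_lifespan(table, group, definition, by)
  tibble::tibble(group = group, n = mx$n, median = as.numeric(med),
                 censored_median = isTRUE(attr(med, "censored_median")),
                 maximum = mx$maximum, max_definition = mx$definition)
}

# Weighted two-sample rank test over risk sets. At each distinct death time
# t_j: n_j at risk overall, n1_j at risk in group A, d_j deaths, d1_j deaths
# in A. U = sum w_j (d1_j - d_j n1_j / n_j),
# V = sum w_j^2 d_j (n_j - d_j)/(n_j - 1) * (n1_j/n_j)(1 - n1_j/n_j),
# chi^2 = U^2 / V on 1 df. w = 1 is the log-rank test; w = n_j is
# Gehan-Breslow (early deaths weighted by the number still at risk).
surv_rank_test <- function(table, group_a, group_b,
                           weight = c("logrank", "gehan"), by = "genotype") {
  weight <- match.arg(weight)
  sub_a <- group_subset(table, group_a, by)
  sub_b <- group_subset(table, group_b, by)
  if (sum(sub_a$status) < 1 || sum(sub_b$status) < 1) {
    stop("both groups need at least one death event")
  }
  time <- c(sub_a$time, sub_b$time)
  status <- c(sub_a$status, sub_b$status)
  in_a <- rep(c(TRUE, FALSE), c(nrow(sub_a), nrow(sub_b)))

  dtimes <- sort(unique(time[status == 1]))
  st <- sort(time)
  st_a <- sort(time[in_a])
  # at risk just before t: count of times >= t
  n_j <- length(st) - findInterval(dtimes, st, left.open = TRUE)
  n1_j <- length(st_a) - findInterval(dtimes, st_a, left.open = TRUE)
  d_j <- vapply(dtimes, function(t) sum(time == t & status == 1), numeric(1))
  d1_j <- vapply(dtimes, function(t) sum(time == t & status == 1 & in_a),
                 numeric(1))

  w <- if (weight == "logrank") rep(1, length(dtimes)) else n_j
  u_terms <- w * (d1_j - d_j * n1_j / n_j)
  v_terms <- ifelse(n_j > 1,
                    w^2 * d_j * (n_j - d_j) / (n_j - 1) *
                      (n1_j / n_j) * (1 - n1_j / n_j),
                    0)
  u <- sum(u_terms)
  v <- sum(v_terms)
  stat <- if (v > 0) u^2 / v else 0
  p <- stats::pchisq(stat, df = 1, lower.tail = FALSE)

  tibble::tibble(
    group_a = group_a, group_b = group_b,
    test = if (weight == "logrank") "log-rank" else "gehan-wilcoxon",
    statistic = stat, df = 1L, p_raw = p,
    p_adjusted = NA_real_, correction = "none",
    n_a = nrow(sub_a), n_b = nrow(sub_b))
}

#' Log-rank test between two groups
#'
#' Standard (unweighted) two-sample log-rank chi-square on 1 df with a
#' two-sided p-value, computed from the risk-set sums.
#'
#' @inheritParams km_estimate
#' @param group_a,group_b Group labels.
#' @return One-row tibble (`SurvTestResult` layout): groups, test name,
#'   statistic, df, `p_raw`, `p_adjusted` (NA until corrected), per-group n.
#' @export
logrank_test <- function(table, group_a, group_b, by = "genotype") {
  surv_rank_test(table, group_a, group_b, "logrank", by)
}

#' Gehan-Wilcoxon test between two groups
#'
#' Gehan-Breslow weighting (weight = number at risk) applied to the same
#' risk-set sums as the log-rank test, emphasizing early differences.
#'
#' @inheritParams logrank_test
#' @return One-row tibble as in [logrank_test()].
#' @export
gehan_wilcoxon_test <- function(table, group_a, group_b, by = "genotype") {
  surv_rank_test(table, group_a, group_b, "gehan", by)
}

#' Pairwise survival comparisons with multiple-testing correction
#'
#' Runs both the log-rank and Gehan-Wilcoxon tests for every requested pair
#' and adjusts p-values across the m pairs within each test family
#' (Bonferroni `min(1, m p)` by default, or Holm step-down).
#'
#' @inheritParams km_estimate
#' @param comparisons List of length-2 character vectors (or `"A:B"`
#'   strings) of group labels. Duplicate pairs are rejected.
#' @param method `"bonferroni"` (default) or `"holm"`.
#' @return Tibble with one row per pair and test, `p_adjusted` filled in.
#' @export
multi_compare <- function(table, comparisons,
                          method = c("bonferroni", "holm"),
                          by = "genotype") {
  method <- match.arg(method)
  if (is.character(comparisons)) comparisons <- strsplit(comparisons, ":")
  stopifnot(is.list(comparisons), length(comparisons) >= 1,
            all(lengths(comparisons) == 2))
  keys <- vapply(comparisons,
                 function(p) paste(sort(p), collapse = ":"), character(1))
  if (anyDuplicated(keys)) {
    stop("duplicate comparison: ", keys[duplicated(keys)][1])
  }
  res <- do.call(rbind, lapply(comparisons, function(p) {
    rbind(logrank_test(table, p[1], p[2], by),
          gehan_wilcoxon_test(table, p[1], p[2], by))
  }))
  for (tst in unique(res$test)) {
    sel <- res$test == tst
    res$p_adjusted[sel] <- stats::p.adjust(res$p_raw[sel], method = method)
  }
  res$correction <- method
  res
}

#' Double-mutant additivity report
#'
#' Tests whether a double mutant's lifespan effect is additive over its two
#' single mutants. Runs corrected pairwise comparisons of each single and
#' the double against the control, and of the double against each single.
#' Verdict (based on the corrected log-rank p-values at level `alpha`):
#' * `"non-additive"` — both singles differ from control but the double
#'   differs from neither single (the double phenocopies the singles);
#' * `"additive-consistent"` — the double differs from both singles in the
#'   direction of longer survival (higher KM median);
#' * `"inconclusive"` — anything else.
#'
#' @inheritParams km_estimate
#' @param control,single_a,single_b,double Group labels.
#' @param alpha Significance level applied to corrected p-values.
#' @param method Correction method passed to [multi_compare()].
#' @return List of class `additivity_report`: `verdict`, `tests` (all
#'   component results), `medians`.
#' @export
additivity_report <- function(table, control, single_a, single_b, double,
                              alpha = 0.05,
                              method = c("bonferroni", "holm"),
                              by = "genotype") {
  method <- match.arg(method)
  for (g in c(control, single_a, single_b, double)) group_subset(table, g, by)
  pairs <- list(c(single_a, control), c(single_b, control),
                c(double, control), c(double, single_a),
                c(double, single_b))
  tests <- multi_compare(table, pairs, method = method, by = by)
  lr <- tests[tests$test == "log-rank", ]
  p_of <- function(a, b) lr$p_adjusted[lr$group_a == a & lr$group_b == b]

  med <- vapply(c(control, single_a, single_b, double), function(g) {
    as.numeric(median_lifespan(km_estimate(table, g, by)))
  }, numeric(1))
  names(med) <- c("control", "single_a", "single_b", "double")

  singles_differ <- p_of(single_a, control) < alpha &&
    p_of(single_b, control) < alpha
  double_vs_singles_null <- p_of(double, single_a) >= alpha &&
    p_of(double, single_b) >= alpha
  double_beats_singles <- p_of(double, single_a) < alpha &&
    p_of(double, single_b) < alpha &&
    !is.na(med["double"]) && med["double"] > med["single_a"] &&
    med["double"] > med["single_b"]

  verdict <- if (singles_differ && double_vs_singles_null) {
    "non-additive"
  } else if (double_beats_singles) {
    "additive-consistent"
  } else {
    "inconclusive"
  }
  structure(list(verdict = verdict, tests = tests, medians = med,
                 alpha = alpha, correction = method),
            class = "additivity_report")
}

#' @export
print.additivity_report <- function(x, ...) {
  cat("<additivity_report> verdict:", x$verdict, "\n")
  cat("  medians:", paste(names(x$medians), format(x$medians), sep = "=",
                          collapse = ", "), "\n")
  cat("  corrected (", x$correction, ") log-rank p-values:\n", sep = "")
  lr <- x$tests[x$tests$test == "log-rank", ]
  for (i in seq_len(nrow(lr))) {
    cat(sprintf("    %s vs %s: p_adj = %.4g\n",
                lr$group_a[i], lr$group_b[i], lr$p_adjusted[i]))
  }
  invisible(x)
}
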