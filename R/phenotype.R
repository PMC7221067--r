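# Normality-gated statistical dispatch for phenotype measurements
# (triglycerides, mass, activity, densitometry ratios), two-way ANOVA with
# Sidak post hoc, and the climbing-score reduction.

#' Normality-gated two-group / multi-group comparison
#'
#' Applies a Shapiro-Wilk test to every group; if all groups look normal
#' (p >= `alpha_norm`) the parametric branch is used (unpaired t-test for
#' two groups, one-way ANOVA for more), otherwise the rank-based branch
#' (Mann-Whitney / Kruskal-Wallis). The gate decision and the per-group
#' normality p-values are always part of the result.
#'
#' @param data Long-format data frame with columns `group` and `value`.
#' @param alpha_norm Normality gate level. Default 0.05.
#' @param welch Use the Welch (unequal-variance) t-test instead of the
#'   classical pooled unpaired t-test. Default FALSE.
#' @return List of class `dispatch_result`: chosen `test`, `gate` tibble
#'   (group, n, shapiro_p, normal), `statistic`, `p_value`, `direction`
#'   (sign of mean difference group2 - group1 for two groups), and
#'   `posthoc` (pairwise table for > 2 groups, Holm-adjusted).
#' @export
dispatch_test <- function(data, alpha_norm = 0.05, welch = FALSE) {
  stopifnot(is.data.frame(data), all(c("group", "value") %in% names(data)),
            is.numeric(data$value))
  data$group <- as.character(data$group)
  counts <- table(data$group)
  if (any(counts < 3)) {
    stop("every group needs >= 3 samples; offending group(s): ",
         paste(names(counts)[counts < 3], collapse = ", "))
  }
  groups <- names(counts)
  k <- length(groups)
  stopifnot(k >= 2)

  shapiro_p <- vapply(groups, function(g) {
    v <- data$value[data$group == g]
    if (stats::sd(v) == 0) 0 else stats::shapiro.test(v)$p.value
  }, numeric(1))
  gate <- tibble::tibble(group = groups, n = as.integer(counts),
                         shapiro_p = shapiro_p,
                         normal = shapiro_p >= alpha_norm)
  parametric <- all(gate$normal)

  posthoc <- NULL
  if (k == 2) {
    v1 <- data$value[data$group == groups[1]]
    v2 <- data$value[data$group == groups[2]]
    if (parametric) {
      ht <- stats::t.test(v1, v2, var.equal = !welch)
      test <- if (welch) "welch t-test" else "unpaired t-test"
    } else {
      ht <- stats::wilcox.test(v1, v2, exact = FALSE)
      test <- "mann-whitney"
    }
    statistic <- unname(ht$statistic)
    p_value <- ht$p.value
    direction <- sign(mean(v2) - mean(v1))
  } else {
    if (parametric) {
      fit <- stats::aov(value ~ group, data = data)
      sm <- summary(fit)[[1]]
      statistic <- sm[["F value"]][1]
      p_value <- sm[["Pr(>F)"]][1]
      test <- "one-way anova"
      ph <- stats::pairwise.t.test(data$value, data$group,
                                   p.adjust.method = "holm")
    } else {
      ht <- stats::kruskal.test(value ~ group, data = data)
      statistic <- unname(ht$statistic)
      p_value <- ht$p.value
      test <- "kruskal-wallis"
      ph <- stats::pairwise.wilcox.test(data$value, data$group,
                                        p.adjust.method = "holm",
                                        exact = FALSE)
    }
    posthoc <- ph$p.value
    direction <- NA_real_
  }

  structure(list(test = test, gate = gate, parametric = parametric,
                 statistic = statistic, p_value = p_value,
                 direction = direction, posthoc = posthoc,
                 alpha_norm = alpha_norm),
            class = "dispatch_result")
}

#' @export
print.dispatch_result <- function(x, ...) {
  cat("<dispatch_result> ", x$test,
      " (gate: ", if (x$parametric) "all groups normal" else "non-normal",
      " at alpha_norm = ", x$alpha_norm, ")\n", sep = "")
  cat("  statistic = ", format(x$statistic), ", p = ", format(x$p_value),
      "\n", sep = "")
  print(x$gate)
  invisible(x)
}

#' Sidak adjustment of a p-value
#'
#' p_adj = 1 - (1 - p)^m for m comparisons; the identity at m = 1 and
#' always between p and the Bonferroni bound min(1, m p).
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Number of comparisons, >= 1.
#' @return Adjusted p-value(s).
#' @export
sidak_adjust <- function(p, m) {
  stopifnot(all(p >= 0 & p <= 1), m >= 1)
  1 - (1 - p)^m
}

#' Two-way ANOVA with Sidak multiple-comparison post hoc
#'
#' Fits `value ~ f1 * f2` (main effects and interaction) by ordinary
#' two-way ANOVA, then compares levels of `f1` pairwise within each level
#' of `f2` with t contrasts on the pooled residual mean square,
#' Sidak-adjusted over all such comparisons.
#'
#' @param data Data frame with columns `value`, `f1`, `f2`; every factor
#'   cell must be non-empty.
#' @return List of class `two_way_result`: `anova` tibble (term, df, F, p),
#'   `posthoc` tibble (f2 level, pair, estimate, t, df, p_raw, p_sidak),
#'   `m` (number of post-hoc comparisons).
#' @export
two_way_anova_sidak <- function(data) {
  stopifnot(is.data.frame(data),
            all(c("value", "f1", "f2") %in% names(data)))
  data$f1 <- factor(data$f1)
  data$f2 <- factor(data$f2)
  cells <- table(data$f1, data$f2)
  if (any(cells == 0)) {
    stop("empty factor cell(s): ",
         paste(which(cells == 0, arr.ind = TRUE), collapse = ", "))
  }
  fit <- stats::aov(value ~ f1 * f2, data = data)
  sm <- summary(fit)[[1]]
  terms <- trimws(rownames(sm))
  anova_tbl <- tibble::tibble(term = terms, df = sm$Df,
                              statistic = sm[["F value"]],
                              p_value = sm[["Pr(>F)"]])

  mse <- sm[["Mean Sq"]][terms == "Residuals"]
  df_res <- sm$Df[terms == "Residuals"]
  lv1 <- levels(data$f1)
  pairs <- utils::combn(lv1, 2, simplify = FALSE)
  rows <- list()
  for (l2 in levels(data$f2)) {
    for (p in pairs) {
      va <- data$value[data$f1 == p[1] & data$f2 == l2]
      vb <- data$value[data$f1 == p[2] & data$f2 == l2]
      est <- mean(vb) - mean(va)
      se <- sqrt(mse * (1 / length(va) + 1 / length(vb)))
      tval <- est / se
      rows[[length(rows) + 1L]] <- tibble::tibble(
        f2 = l2, pair = paste(p[1], p[2], sep = " vs "),
        estimate = est, t = tval, df = df_res,
        p_raw = 2 * stats::pt(-abs(tval), df_res))
    }
  }
  posthoc <- do.call(rbind, rows)
  m <- nrow(posthoc)
  posthoc$p_sidak <- sidak_adjust(posthoc$p_raw, m)

  structure(list(anova = anova_tbl, posthoc = posthoc, m = m),
            class = "two_way_result")
}

#' @export
print.two_way_result <- function(x, ...) {
  cat("<two_way_result>\n")
  print(x$anova)
  cat("Sidak post hoc (m = ", x$m, "):\n", sep = "")
  print(x$posthoc)
  invisible(x)
}

#' Climbing score from five trials
#'
#' Mean over the five trials of the per-trial mean fly height at the 4-s
#' mark, one scalar per vial session. Invariant to fly and trial ordering.
#'
#' @param trials Data frame with columns `trial` (exactly the values
#'   1..5), `fly`, `height` (in \[0, 1\]), e.g. from
#'   [gen_climbing_trials()].
#' @return Scalar score in \[0, 1\] with attribute `trial_means`.
#' @export
climbing_score <- function(trials) {
  stopifnot(is.data.frame(trials),
            all(c("trial", "height") %in% names(trials)))
  present <- sort(unique(trials$trial))
  if (!identical(as.integer(present), 1:5)) {
    stop("expected exactly 5 trials (1..5); got trials ",
         paste(present, collapse = ", "))
  }
  if (any(trials$height < 0 | trials$height > 1)) {
    stop("heights must be normalized to [0, 1]")
  }
  tm <- vapply(1:5, function(k) mean(trials$height[trials$trial == k]),
               numeric(1))
  structure(mean(tm), trial_means = tm)
}
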