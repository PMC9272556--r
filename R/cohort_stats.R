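#' Two-group comparison of a continuous summary
#'
#' Independent two-sample t-test, two-tailed. `"welch"` (default) does not
#' assume equal variances; `"pooled"` is the classical equal-variance test.
#' Missing values are dropped within each group. When both groups are
#' constant with equal means the statistic is 0 and p = 1 (the test is
#' otherwise undefined there).
#'
#' @param values_a,values_b Numeric vectors, at least 2 non-missing values
#'   each after dropping NA.
#' @param mode `"welch"` or `"pooled"`.
#' @param group_a,group_b Labels carried into the result.
#' @return A one-row tibble: `group_a`, `group_b`, `n_a`, `n_b`, `mean_a`,
#'   `mean_b`, `statistic`, `p_value`, `test`.
#' @export
compare_groups <- function(values_a, values_b, mode = c("welch", "pooled"),
                           group_a = "A", group_b = "B") {
  mode <- match.arg(mode)
  a <- values_a[!is.na(values_a)]
  b <- values_b[!is.na(values_b)]
  if (length(a) < 2L || length(b) < 2L) {
    abort("compare_groups needs >= 2 non-missing values per group")
  }
  if (stats::sd(a) == 0 && stats::sd(b) == 0) {
    if (mean(a) == mean(b)) {
      stat <- 0; p <- 1
    } else {
      stat <- sign(mean(a) - mean(b)) * Inf; p <- 0
    }
  } else {
    tt <- t.test(a, b, var.equal = (mode == "pooled"))
    stat <- unname(tt$statistic); p <- tt$p.value
  }
  tibble(
    group_a = group_a, group_b = group_b,
    n_a = length(a), n_b = length(b),
    mean_a = mean(a), mean_b = mean(b),
    statistic = stat, p_value = p,
    test = paste0("t_", mode)
  )
}

#' One-way ANOVA across several groups
#'
#' @param groups A named or unnamed list of numeric vectors, each with at
#'   least 2 non-missing values.
#' @return A one-row tibble: `n_groups`, `n_total`, `statistic` (F),
#'   `df_between`, `df_within`, `p_value`, `test`.
#' @export
anova_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2L) abort("anova_groups needs >= 2 groups")
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (any(lengths(groups) < 2L)) abort("each group needs >= 2 non-missing values")
  dat <- tibble(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(seq_along(groups), lengths(groups)))
  )
  fit <- aov(value ~ group, data = dat)
  s <- summary(fit)[[1]]
  f <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  if (is.na(f) && s[["Mean Sq"]][1] == 0) { f <- 0; p <- 1 }
  tibble(
    n_groups = length(groups), n_total = nrow(dat),
    statistic = f, df_between = s[["Df"]][1], df_within = s[["Df"]][2],
    p_value = p, test = "anova"
  )
}

#' Pearson correlation with two-tailed p-value
#'
#' @param x,y Numeric vectors of equal length >= 3; pairs with missing
#'   values are dropped.
#' @return A one-row tibble: `n`, `r`, `statistic`, `p_value`.
#' @export
pearson_corr <- function(x, y) {
  if (length(x) != length(y)) abort("x and y must have equal length")
  keep <- !is.na(x) & !is.na(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) abort("pearson_corr needs >= 3 complete pairs")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    abort("undefined correlation: zero variance")
  }
  ct <- cor.test(x, y, method = "pearson")
  tibble(n = length(x), r = unname(ct$estimate),
         statistic = unname(ct$statistic), p_value = ct$p.value)
}

#' Area under the ROC curve
#'
#' Rank-based (Mann-Whitney) AUC of a continuous score against a binary
#' label: the probability that a random positive scores above a random
#' negative, with ties counting 1/2.
#'
#' @param score Numeric vector.
#' @param label Binary vector (logical, 0/1, or a two-level factor whose
#'   second level is the positive class).
#' @return The AUC, a fraction in [0, 1].
#' @export
roc_auc <- function(score, label) {
  if (length(score) != length(label)) abort("score and label must have equal length")
  keep <- !is.na(score) & !is.na(label)
  score <- score[keep]; label <- label[keep]
  if (is.factor(label)) label <- label == levels(label)[2]
  label <- as.logical(label)
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L) abort("roc_auc needs both classes present")
  r <- rank(score, ties.method = "average")
  (sum(r[label]) - n_pos * (n_pos + 1) / 2) / (n_pos * n_neg)
}

#' Filter samples by percent-spliced-in value
#'
#' Keeps samples whose PSI for the isoform of interest is strictly greater
#' than the threshold (default 0.9), restricting an expression cohort to
#' samples where that isoform dominates.
#'
#' @param records A data frame with columns `sample_id` and `psi`.
#' @param threshold Strict lower bound on PSI.
#' @return The retained rows, as a tibble.
#' @export
filter_psi <- function(records, threshold = 0.9) {
  records <- as_tibble(records)
  miss <- setdiff(c("sample_id", "psi"), names(records))
  if (length(miss) > 0L) {
    abort(sprintf("PSI table missing column(s): %s", paste(miss, collapse = ", ")))
  }
  if (any(records$psi < 0 | records$psi > 1, na.rm = TRUE)) {
    abort("psi values must lie in [0, 1]")
  }
  records %>% filter(!is.na(.data$psi), .data$psi > threshold)
}

#' Multiple-testing adjustment for a comparison table
#'
#' Optional Benjamini-Hochberg adjustment over the p-values of a comparison
#' report; the primary analyses use unadjusted two-tailed p < alpha.
#'
#' @param comparisons A tibble with a `p_value` column.
#' @param method Passed to [stats::p.adjust()].
#' @return The table with a `p_adjusted` column appended.
#' @export
adjust_comparisons <- function(comparisons, method = "BH") {
  comparisons %>% mutate(p_adjusted = stats::p.adjust(.data$p_value, method = method))
}
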