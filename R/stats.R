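#' Two-group comparison tests
#'
#' The comparison tests used for region- and task-level contrasts: Wilcoxon
#' rank-sum, two-sample t, and paired t. All p-values are two-tailed. For the
#' rank-sum test the reported statistic is the sum of (mid)ranks of the
#' first group in the pooled sample, the convention in which rank-sum
#' statistics are quoted; the p-value is exact for small tie-free samples
#' and normal-approximated otherwise. The two-sample t-test defaults to the
#' equal-variance (Student) form; `welch = TRUE` switches to Welch. Paired
#' or two-sample data that are entirely constant (zero variance, equal
#' means) return statistic 0 and p = 1 rather than an error.
#'
#' @param a,b Numeric vectors; for `paired_t` they must have equal length.
#' @param test `"ranksum"`, `"t2"` or `"paired_t"`.
#' @param welch Use the Welch (unequal-variance) form of the two-sample
#'   t-test.
#' @return data.frame (one row) with `test`, `statistic`, `p_value`, `n_a`,
#'   `n_b`, `paired`.
#' @export
compare_groups <- function(a, b, test = c("ranksum", "t2", "paired_t"),
                           welch = FALSE) {
  test <- match.arg(test)
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (test == "ranksum") {
    if (length(a) < 1 || length(b) < 1)
      stop("ranksum requires at least 1 value per group")
    ranks <- rank(c(a, b))
    statistic <- sum(ranks[seq_along(a)])
    p <- suppressWarnings(stats::wilcox.test(a, b)$p.value)
  } else if (test == "t2") {
    if (length(a) < 2 || length(b) < 2)
      stop("two-sample t-test requires at least 2 values per group")
    if (stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b)) {
      statistic <- 0; p <- 1
    } else {
      tt <- stats::t.test(a, b, var.equal = !welch)
      statistic <- unname(tt$statistic); p <- tt$p.value
    }
  } else {
    if (length(a) != length(b))
      stop("paired t-test requires equal-length samples")
    if (length(a) < 2) stop("paired t-test requires at least 2 pairs")
    d <- a - b
    if (stats::sd(d) == 0) {
      statistic <- if (mean(d) == 0) 0 else sign(mean(d)) * Inf
      p <- if (mean(d) == 0) 1 else 0
    } else {
      tt <- stats::t.test(a, b, paired = TRUE)
      statistic <- unname(tt$statistic); p <- tt$p.value
    }
  }
  data.frame(test = test, statistic = statistic, p_value = p,
             n_a = length(a), n_b = length(b),
             paired = test == "paired_t")
}

#' One-way analysis of variance
#'
#' Standard one-way ANOVA F-test across two or more groups (used, e.g., to
#' test whether median RGR differs across imaging depths). Degenerate input
#' in which every group has zero variance and all group means are equal
#' returns F = 0, p = 1.
#'
#' @param groups A list of numeric vectors (>= 2 groups, >= 2 values each).
#' @return data.frame (one row) with `test`, `statistic` (F), `p_value`,
#'   `df_between`, `df_within`, `n_groups`.
#' @export
anova_oneway <- function(groups) {
  stopifnot(is.list(groups))
  groups <- lapply(groups, function(v) v[!is.na(v)])
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, 1L) < 2))
    stop("each group needs at least 2 values")
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 1L)))
  df_b <- nlevels(g) - 1L
  df_w <- length(values) - nlevels(g)
  if (stats::var(values) == 0)
    return(data.frame(test = "anova_oneway", statistic = 0, p_value = 1,
                      df_between = df_b, df_within = df_w,
                      n_groups = length(groups)))
  ow <- stats::oneway.test(values ~ g, var.equal = TRUE)
  data.frame(test = "anova_oneway", statistic = unname(ow$statistic),
             p_value = ow$p.value, df_between = df_b, df_within = df_w,
             n_groups = length(groups))
}

#' Regress a behavioral variable on regional activity
#'
#' Simple linear regression of a per-mouse behavioral score on the per-mouse
#' regional median RGR, with the F-test of the fitted model against the
#' constant (intercept-only) model. With a single predictor this F equals
#' the square of the slope's t statistic and its p-value is the two-tailed
#' p-value of the slope.
#'
#' @param rgr Per-mouse regional median RGR (predictor).
#' @param behavior Per-mouse behavioral variable (response), same length.
#' @param region,variable Optional labels carried into the output.
#' @return data.frame (one row): `region`, `variable`, `n`, `slope`,
#'   `intercept`, `r_squared`, `f_statistic`, `p_value`.
#' @export
correlate_behavior <- function(rgr, behavior, region = NA_character_,
                               variable = NA_character_) {
  stopifnot(length(rgr) == length(behavior))
  keep <- !is.na(rgr) & !is.na(behavior)
  rgr <- rgr[keep]; behavior <- behavior[keep]
  if (length(rgr) < 3) stop("need at least 3 paired observations")
  if (stats::sd(rgr) == 0) stop("zero variance in the RGR predictor")
  fit <- stats::lm(behavior ~ rgr)
  sm <- summary(fit)
  fstat <- unname(sm$fstatistic)
  p <- stats::pf(fstat[1], fstat[2], fstat[3], lower.tail = FALSE)
  data.frame(region = region, variable = variable, n = length(rgr),
             slope = unname(stats::coef(fit)[2]),
             intercept = unname(stats::coef(fit)[1]),
             r_squared = sm$r.squared, f_statistic = fstat[1],
             p_value = p)
}
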