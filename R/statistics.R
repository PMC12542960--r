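# Statistical test selection and power analysis. Normality (Shapiro-Wilk
# and Anderson-Darling, both at 0.05) routes two-group comparisons to
# Student's/Welch's t (after an F test on variances) or to rank tests;
# multi-group comparisons to ANOVA + Tukey, Welch ANOVA + Games-Howell, or
# Kruskal-Wallis + Dunn. Sample size uses the noncentral-t formulation.

normality_check <- function(x, alpha = 0.05) {
  n <- length(x)
  if (n < 3) stop("normality testing requires at least 3 observations per group")
  sw <- stats::shapiro.test(x)
  ad_p <- if (n >= 8) nortest::ad.test(x)$p.value else NA_real_
  pass <- sw$p.value >= alpha && (is.na(ad_p) || ad_p >= alpha)
  list(shapiro_p = sw$p.value, ad_p = ad_p, normal = pass)
}

#' Two-group comparison via the test-selection decision tree
#'
#' Both groups are screened for normality (Shapiro-Wilk and Anderson-
#' Darling, each at p >= 0.05; for n < 8 only Shapiro-Wilk is available).
#' If both pass: independent data get an F test on variances and then
#' Student's t (equal variances) or Welch's t (unequal); paired data get the
#' paired t test. Any normality failure routes to the Mann-Whitney U test
#' (independent) or Wilcoxon signed-rank test (paired). All tests
#' two-sided.
#'
#' @param x,y numeric measurement vectors.
#' @param paired logical; paired designs require equal lengths.
#' @param alpha_assumption level for the normality and variance screens.
#' @return object of class `test_decision`: `test` (name), `statistic`,
#'   `p_value`, and `branch` (the full screening trace).
#' @export
decide_and_test <- function(x, y, paired = FALSE, alpha_assumption = 0.05) {
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (paired && length(x) != length(y)) stop("paired groups must have equal n")
  nx <- normality_check(x, alpha_assumption)
  ny <- normality_check(y, alpha_assumption)
  branch <- list(normality_x = nx, normality_y = ny, variance_f_p = NA_real_,
                 equal_variances = NA, paired = paired)
  if (nx$normal && ny$normal) {
    if (paired) {
      ht <- stats::t.test(x, y, paired = TRUE)
      test <- "Paired Student's t test"
    } else {
      vt <- stats::var.test(x, y)
      branch$variance_f_p <- vt$p.value
      branch$equal_variances <- vt$p.value >= alpha_assumption
      ht <- stats::t.test(x, y, var.equal = branch$equal_variances)
      test <- if (branch$equal_variances) "Student's t test" else "Welch's t test"
    }
  } else if (paired) {
    ht <- stats::wilcox.test(x, y, paired = TRUE, exact = NULL)
    test <- "Wilcoxon signed-rank test"
  } else {
    ht <- stats::wilcox.test(x, y, exact = NULL)
    test <- "Mann-Whitney U test"
  }
  structure(list(test = test, statistic = unname(ht$statistic),
                 p_value = ht$p.value, branch = branch, htest = ht),
            class = "test_decision")
}

#' @export
print.test_decision <- function(x, ...) {
  cat(sprintf("<test_decision> %s: statistic = %.4g, p = %.4g\n",
              x$test, x$statistic, x$p_value))
  bx <- x$branch
  if (!is.null(bx$normality_x))
    cat(sprintf("  normality: group1 %s, group2 %s",
                if (bx$normality_x$normal) "normal" else "non-normal",
                if (bx$normality_y$normal) "normal" else "non-normal"))
  if (!is.null(bx$all_normal))
    cat(sprintf("  normality: %s", if (bx$all_normal) "all normal" else "non-normal"))
  vp <- if (!is.null(bx$variance_f_p)) bx$variance_f_p else bx$variance_p
  if (!is.null(vp) && !is.na(vp))
    cat(sprintf("; variances %s (p = %.3g)",
                if (isTRUE(bx$equal_variances)) "equal" else "unequal", vp))
  cat("\n")
  if (!is.null(x$posthoc)) {
    cat(sprintf("  post hoc (%s):\n", x$posthoc_method))
    print(x$posthoc, digits = 4)
  }
  invisible(x)
}

games_howell <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  m <- vapply(groups, mean, 0)
  v <- vapply(groups, stats::var, 0)
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    se2 <- v[i] / n[i] + v[j] / n[j]
    tstat <- abs(m[i] - m[j]) / sqrt(se2)
    df <- se2^2 / ((v[i] / n[i])^2 / (n[i] - 1) + (v[j] / n[j])^2 / (n[j] - 1))
    p <- stats::ptukey(tstat * sqrt(2), k, df, lower.tail = FALSE)
    out <- rbind(out, data.frame(group1 = i, group2 = j,
                                 diff = m[i] - m[j], p_adj = p))
  }
  out
}

dunn_test <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 0L)
  all_v <- unlist(groups)
  N <- length(all_v)
  r <- rank(all_v)
  grp <- rep(seq_len(k), n)
  rbar <- tapply(r, grp, mean)
  ties <- table(all_v)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_corr
  m <- k * (k - 1) / 2
  out <- NULL
  for (i in 1:(k - 1)) for (j in (i + 1):k) {
    z <- (rbar[i] - rbar[j]) / sqrt(s2 * (1 / n[i] + 1 / n[j]))
    p <- min(1, 2 * stats::pnorm(-abs(z)) * m)   # Bonferroni
    out <- rbind(out, data.frame(group1 = i, group2 = j, z = unname(z), p_adj = p))
  }
  out
}

#' Multi-group comparison via the decision tree
#'
#' All groups normal and variances equal (Bartlett): one-way ANOVA with
#' Tukey's HSD. All normal, variances unequal: Welch's ANOVA with
#' Games-Howell. Any normality failure: Kruskal-Wallis with Dunn's test
#' (Bonferroni-adjusted).
#'
#' @param groups list of >= 3 numeric vectors (each n >= 3).
#' @param alpha_assumption level for the normality/variance screens.
#' @return a `test_decision` with omnibus statistic and p-value plus a
#'   `posthoc` pairwise table.
#' @export
multi_group_test <- function(groups, alpha_assumption = 0.05) {
  stopifnot(length(groups) >= 3)
  norm <- lapply(groups, normality_check, alpha = alpha_assumption)
  all_normal <- all(vapply(norm, function(z) z$normal, TRUE))
  vals <- unlist(groups)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  branch <- list(normality = norm, all_normal = all_normal,
                 variance_p = NA_real_, equal_variances = NA)
  if (all_normal) {
    bt <- stats::bartlett.test(vals, g)
    branch$variance_p <- bt$p.value
    branch$equal_variances <- bt$p.value >= alpha_assumption
    if (branch$equal_variances) {
      fit <- stats::aov(vals ~ g)
      s <- summary(fit)[[1]]
      tk <- stats::TukeyHSD(fit)$g
      res <- list(test = "One-way ANOVA", statistic = s[["F value"]][1],
                  p_value = s[["Pr(>F)"]][1],
                  posthoc = data.frame(comparison = rownames(tk),
                                       diff = tk[, "diff"], p_adj = tk[, "p adj"]),
                  posthoc_method = "Tukey HSD")
    } else {
      ow <- stats::oneway.test(vals ~ g, var.equal = FALSE)
      res <- list(test = "Welch's ANOVA", statistic = unname(ow$statistic),
                  p_value = ow$p.value, posthoc = games_howell(groups),
                  posthoc_method = "Games-Howell")
    }
  } else {
    kw <- stats::kruskal.test(groups)
    res <- list(test = "Kruskal-Wallis test", statistic = unname(kw$statistic),
                p_value = kw$p.value, posthoc = dunn_test(groups),
                posthoc_method = "Dunn (Bonferroni)")
  }
  res$branch <- branch
  class(res) <- "test_decision"
  res
}

#' Power of the two-sided two-sample t test
#'
#' Noncentral-t formulation: with `n` per group, `df = 2n - 2` and
#' noncentrality `d * sqrt(n / 2)` for standardized effect `d`.
#'
#' @param n per-group sample size (>= 2).
#' @param d standardized effect size (difference in means / SD).
#' @param alpha two-sided significance level.
#' @return power (probability of rejection).
#' @export
achieved_power <- function(n, d, alpha = 0.05) {
  stopifnot(n >= 2)
  df <- 2 * n - 2
  ncp <- d * sqrt(n / 2)
  q <- stats::qt(1 - alpha / 2, df)
  stats::pt(q, df, ncp, lower.tail = FALSE) + stats::pt(-q, df, ncp)
}

#' Minimal per-group sample size for a two-sample t test
#'
#' Smallest integer n per group whose noncentral-t power reaches the
#' target. The default specification — control mean 100, SD 25, effect 50%
#' of control, power 0.80, alpha 0.05 — is the planning standard for
#' per-cell imaging metrics and yields n = 6.
#'
#' @param control_mean control group mean (sets the effect scale).
#' @param sd common standard deviation, in the same units.
#' @param effect_pct effect size as a percentage of the control mean (> 0).
#' @param power target power in (0, 1).
#' @param alpha two-sided significance level.
#' @return integer sample size per group.
#' @export
sample_size_two_sample_t <- function(control_mean = 100, sd = 25,
                                     effect_pct = 50, power = 0.8,
                                     alpha = 0.05) {
  stopifnot(effect_pct > 0, sd > 0, power > 0, power < 1, alpha > 0, alpha < 1)
  d <- (effect_pct / 100 * control_mean) / sd
  for (n in 2:1000000)
    if (achieved_power(n, d, alpha) >= power) return(n)
  stop("target power unreachable within n <= 1e6")
}
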