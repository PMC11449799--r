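# Statistical layer: KS normality on standardized samples, two-group t
# test, one-way ANOVA with Tukey-Kramer multiple comparisons, two-way ANOVA
# for longitudinal MEA data, and the significance-star convention.

#' Kolmogorov-Smirnov normality check on standardized data
#'
#' The sample is centered by its mean and scaled by its SD, then compared to
#' the standard normal with a one-sample KS test. Because the parameters are
#' estimated from the same sample, the test is anti-conservative relative to
#' nominal alpha; it is used as a screen, matching common practice.
#'
#' @param sample Numeric vector, n >= 5.
#' @return A list of class `test_result`: `statistic`, `p_value`, `df`,
#'   `method`.
#' @export
ks_normality <- function(sample) {
  sample <- sample[is.finite(sample)]
  assert_that(length(sample) >= 5L, "need at least 5 observations")
  s <- stats::sd(sample)
  if (!is.finite(s) || s == 0) {
    stop_twinephys("zero-variance sample: normality undefined",
                   "degenerate_sample_error")
  }
  z <- (sample - mean(sample)) / s
  kt <- suppressWarnings(stats::ks.test(z, "pnorm"))
  test_result(unname(kt$statistic), kt$p.value, NA_real_,
              "one-sample KS vs N(0,1) after standardization")
}

test_result <- function(statistic, p_value, df, method, pairwise = NULL) {
  assert_that(p_value >= 0 && p_value <= 1, "p-value outside [0, 1]")
  structure(list(statistic = statistic, p_value = p_value, df = df,
                 method = method, pairwise = pairwise),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("<test_result> %s\n  statistic = %.4g, df = %s, p = %.4g %s\n",
              x$method, x$statistic, paste(signif(x$df, 4), collapse = ","),
              x$p_value, significance_stars(x$p_value)))
  if (!is.null(x$pairwise)) {
    print(x$pairwise)
  }
  invisible(x)
}

#' Two-group comparison (t test)
#'
#' Welch's unequal-variance t test by default; `var_equal = TRUE` restores
#' the classic pooled-variance form.
#'
#' @param a,b Numeric vectors.
#' @param var_equal Use the pooled-variance t test.
#' @return A `test_result` with the t statistic, df and p-value.
#' @export
two_group_test <- function(a, b, var_equal = FALSE) {
  tt <- stats::t.test(a, b, var.equal = var_equal)
  test_result(unname(tt$statistic), tt$p.value, unname(tt$parameter),
              tt$method)
}

#' One-way ANOVA with Tukey-Kramer pairwise comparisons
#'
#' Omnibus F over the groups plus adjusted pairwise p-values
#' (Tukey-Kramer by default, the documented default of MATLAB's
#' `multcompare`; Bonferroni available).
#'
#' @param table A data.frame with columns `group` and `value` (or a column
#'   named by `variable` plus a `variable` filter on long tables).
#' @param variable Optional: if `table` is long (`variable`/`value`
#'   columns), the variable to test.
#' @param p_adjust `"tukey"` or `"bonferroni"`.
#' @return A `test_result`; `$pairwise` is a data.frame with `pair`, `diff`,
#'   `p_adj`.
#' @export
one_way_anova_multcompare <- function(table, variable = NULL,
                                      p_adjust = c("tukey", "bonferroni")) {
  p_adjust <- match.arg(p_adjust)
  if (!is.null(variable) && "variable" %in% names(table)) {
    table <- table[table$variable == variable, ]
  }
  assert_that(all(c("group", "value") %in% names(table)),
              "table needs group and value columns")
  table$group <- factor(table$group)
  if (nlevels(table$group) < 2L) {
    stop_twinephys("one-way ANOVA needs at least 2 groups", "design_error")
  }
  fit <- stats::aov(value ~ group, data = table)
  an <- summary(fit)[[1]]
  if (p_adjust == "tukey") {
    tk <- stats::TukeyHSD(fit)$group
    pw <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                     p_adj = tk[, "p adj"], row.names = NULL)
  } else {
    pt <- stats::pairwise.t.test(table$value, table$group,
                                 p.adjust.method = "bonferroni", pool.sd = TRUE)
    m <- pt$p.value
    pairs <- which(!is.na(m), arr.ind = TRUE)
    pw <- data.frame(pair = paste(rownames(m)[pairs[, 1]],
                                  colnames(m)[pairs[, 2]], sep = "-"),
                     diff = NA_real_, p_adj = m[pairs], row.names = NULL)
  }
  test_result(an[1, "F value"], an[1, "Pr(>F)"],
              c(an[1, "Df"], an[2, "Df"]),
              sprintf("one-way ANOVA + %s", p_adjust), pairwise = pw)
}

#' Two-way ANOVA for longitudinal (group x day) data
#'
#' Main effects of group and day plus their interaction, from a linear model
#' on well (or subject) means. Day is treated as a factor.
#'
#' @param table A data.frame with columns `group`, `day`, `value` (a long
#'   table may be filtered via `variable`).
#' @param variable Optional variable filter for long tables.
#' @param interaction Include the group:day interaction (default TRUE;
#'   requires replication within cells).
#' @return A list of class `anova2_result` with one `test_result` per
#'   effect: `$group`, `$day`, and `$interaction` (when fitted).
#' @export
two_way_anova <- function(table, variable = NULL, interaction = TRUE) {
  if (!is.null(variable) && "variable" %in% names(table)) {
    table <- table[table$variable == variable, ]
  }
  assert_that(all(c("group", "day", "value") %in% names(table)),
              "table needs group, day, value columns")
  table$group <- factor(table$group)
  table$day <- factor(table$day)
  assert_that(nlevels(table$group) >= 2L && nlevels(table$day) >= 2L,
              "need at least 2 groups and 2 days", "design_error")
  form <- if (interaction) value ~ group * day else value ~ group + day
  an <- summary(stats::aov(form, data = table))[[1]]
  rn <- trimws(rownames(an))
  res_df <- an[rn == "Residuals", "Df"]
  eff <- function(name) {
    i <- which(rn == name)
    test_result(an[i, "F value"], an[i, "Pr(>F)"], c(an[i, "Df"], res_df),
                sprintf("two-way ANOVA: %s", name))
  }
  out <- list(group = eff("group"), day = eff("day"))
  if (interaction && "group:day" %in% rn) out$interaction <- eff("group:day")
  structure(out, class = "anova2_result")
}

#' Significance stars
#'
#' The figure-legend convention: `*` p < 0.05, `**` p < 0.01, `***`
#' p < 0.001, `****` p < 0.0001; `"ns"` otherwise.
#'
#' @param p P-value(s).
#' @return Character vector of star labels.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (!is.finite(pi)) return(NA_character_)
    if (pi < 1e-4) "****"
    else if (pi < 1e-3) "***"
    else if (pi < 1e-2) "**"
    else if (pi < 0.05) "*"
    else "ns"
  }, character(1))
}
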