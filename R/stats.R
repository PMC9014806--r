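#' One-way ANOVA with Tukey HSD pairwise comparisons
#'
#' For endpoint-only quantities (e.g. histology H-scores) across treatment
#' arms: one-way analysis of variance followed by Tukey's honestly
#' significant difference test for multiple-comparison-adjusted pairwise
#' p-values. Significance is flagged at p < 0.05.
#'
#' @param values numeric response.
#' @param groups factor (or coercible) of group labels, >= 2 groups with
#'   >= 2 values each.
#' @return list `f`, `p`, `pairs` (data.frame: `contrast`, `diff`, `p_adj`,
#'   `significant`), `fit`.
#' @export
anova_tukey <- function(values, groups) {
  groups <- factor(groups)
  stop_if(length(values) != length(groups), "length mismatch")
  stop_if(nlevels(groups) < 2, "need at least 2 groups")
  stop_if(any(table(groups) < 2), "every group needs at least 2 values")
  wvar <- stats::aggregate(values, list(groups), stats::var)$x
  stop_if(all(wvar == 0),
          "degenerate input: zero within-group variance everywhere")
  fit <- stats::aov(values ~ groups)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$groups
  pairs <- data.frame(contrast = rownames(tk), diff = tk[, "diff"],
                      p_adj = tk[, "p adj"],
                      significant = tk[, "p adj"] < 0.05,
                      row.names = NULL)
  list(f = an[["F value"]][1], p = an[["Pr(>F)"]][1], pairs = pairs,
       fit = fit)
}

#' Longitudinal ANCOVA with pre-treatment covariate
#'
#' Fits `post ~ pre + group` and tests the treatment-group effect with the
#' nested-model F test (`post ~ pre` vs full), the longitudinal design that
#' adjusts endpoint values for each tumor's own baseline. Adjusted means are
#' the model predictions per arm at the grand mean of the covariate.
#'
#' @param post,pre paired per-tumor endpoint and baseline values (no missing
#'   baselines).
#' @param groups treatment arm per tumor.
#' @return list `p_group`, `f_group`, `coefficients`, `adjusted_means`,
#'   `fit`.
#' @export
ancova_longitudinal <- function(post, pre, groups) {
  groups <- factor(groups)
  stop_if(length(post) != length(pre) || length(post) != length(groups),
          "length mismatch")
  stop_if(anyNA(pre), "missing pre-treatment value: every tumor needs a baseline")
  stop_if(anyNA(post), "missing post-treatment value")
  stop_if(nlevels(groups) < 2, "need at least 2 groups")
  df <- data.frame(post = post, pre = pre, groups = groups)
  full <- stats::lm(post ~ pre + groups, data = df)
  null <- stats::lm(post ~ pre, data = df)
  rss_full <- sum(stats::resid(full)^2)
  rss_null <- sum(stats::resid(null)^2)
  if (rss_null - rss_full <= 1e-12 * max(rss_null, .Machine$double.eps)) {
    # the arms explain nothing beyond the covariate (including the exact
    # post == f(pre) case, where the F ratio degenerates)
    p_group <- 1; f_group <- 0
  } else {
    cmp <- stats::anova(null, full)
    p_group <- cmp[["Pr(>F)"]][2]; f_group <- cmp[["F"]][2]
  }
  adj <- vapply(levels(groups), function(g) {
    stats::predict(full, data.frame(pre = mean(pre), groups = g))
  }, numeric(1))
  list(p_group = p_group, f_group = f_group,
       coefficients = stats::coef(full), adjusted_means = adj, fit = full)
}
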