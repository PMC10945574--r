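# Group statistics mirroring the study's reporting conventions: one-way
# ANOVA with Tukey's HSD, two-way (Type II) ANOVA, mean +/- SEM summaries,
# and the figure-legend significance-star convention.

# Figure-legend significance cut-points. The legends print them as
# */**/***/**** = 0.05 / 0.0002 / 0.002 / 0.00002, whose middle two labels
# are not monotone as printed; stars are therefore assigned monotonically as
# the number of cut-points at or below which p falls.
STAR_THRESHOLDS <- c(0.05, 0.002, 0.0002, 0.00002)

#' Significance stars at the figure-legend cut-points
#'
#' @param p numeric vector of p-values.
#' @return character vector of `""` to `"****"` (`NA` p gives `""`).
#' @export
p_stars <- function(p) {
  vapply(p, function(pp) {
    if (is.na(pp)) return("")
    strrep("*", sum(pp <= STAR_THRESHOLDS))
  }, character(1))
}

#' Mean, SEM and n
#'
#' SEM is the sample standard deviation (n - 1 denominator) over `sqrt(n)`;
#' it is undefined (`NA`) for a single observation.
#'
#' @param values numeric vector, `n >= 1`.
#' @return list with `mean`, `sem`, `n`.
#' @examples
#' mean_sem(c(2, 4, 6))  # mean 4, sem 1.1547
#' @export
mean_sem <- function(values) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stopf("need at least one observation")
  list(mean = mean(values),
       sem = if (n >= 2L) stats::sd(values) / sqrt(n) else NA_real_,
       n = n)
}

#' One-way ANOVA with Tukey's HSD post hoc comparisons
#'
#' Standard one-way ANOVA F test across groups followed by Tukey honest
#' significant differences over all group pairs, with significance stars at
#' the figure-legend cut-points. With two groups the F statistic equals the
#' squared pooled-variance t statistic.
#'
#' @param values numeric response.
#' @param group group labels (coerced to factor); >= 2 groups, each with
#'   n >= 2.
#' @return list of class `group_stats`: `test`, `F`, `df`, `p`, `stars`,
#'   `group_summary` (mean/SEM/n per group), `tukey` (data frame `pair`,
#'   `diff`, `lwr`, `upr`, `p_adj`, `stars`).
#' @examples
#' one_way_anova_tukey(c(1, 2, 3, 5, 6, 7), rep(c("a", "b"), each = 3))
#' @export
one_way_anova_tukey <- function(values, group) {
  group <- factor(group)
  if (nlevels(group) < 2L) stopf("need >= 2 groups")
  n_by <- table(group)
  if (any(n_by < 2L))
    stopf("every group needs n >= 2 (got: %s)",
          paste(names(n_by), n_by, sep = "=", collapse = ", "))
  d <- data.frame(values = values, group = group)
  fit <- stats::aov(values ~ group, data = d)
  s <- summary(fit)[[1]]
  Fv <- s[["F value"]][1]
  p <- s[["Pr(>F)"]][1]
  tk <- stats::TukeyHSD(fit)$group
  tukey <- data.frame(pair = rownames(tk), diff = tk[, "diff"],
                      lwr = tk[, "lwr"], upr = tk[, "upr"],
                      p_adj = tk[, "p adj"], stars = p_stars(tk[, "p adj"]),
                      row.names = NULL, stringsAsFactors = FALSE)
  gs <- do.call(rbind, lapply(levels(group), function(g) {
    ms <- mean_sem(values[group == g])
    data.frame(group = g, mean = ms$mean, sem = ms$sem, n = ms$n)
  }))
  structure(list(test = "one-way ANOVA + Tukey HSD",
                 F = Fv, df = c(s$Df[1], s$Df[2]), p = p,
                 stars = p_stars(p), group_summary = gs, tukey = tukey),
            class = "group_stats")
}

#' Two-way ANOVA with Type II sums of squares
#'
#' Main effects and interaction for a two-factor layout, using Type II sums
#' of squares (via [car::Anova()]), appropriate for the unbalanced group
#' sizes typical of animal cohorts. A saturated design (no residual degrees
#' of freedom) is an error.
#'
#' @param values numeric response.
#' @param factor_a,factor_b factor labels.
#' @param factor_names names used for the two factors in the output table.
#' @return list of class `group_stats` with a `table` data frame (`term`,
#'   `sumsq`, `df`, `F`, `p`, `stars`).
#' @export
two_way_anova <- function(values, factor_a, factor_b,
                          factor_names = c("A", "B")) {
  fa <- factor(factor_a); fb <- factor(factor_b)
  if (nlevels(fa) < 2L || nlevels(fb) < 2L)
    stopf("both factors need >= 2 levels")
  d <- data.frame(values = values, A = fa, B = fb)
  with_int <- length(values) > nlevels(fa) * nlevels(fb) &&
    all(table(fa, fb) > 0)
  form <- if (with_int) values ~ A * B else values ~ A + B
  fit <- stats::lm(form, data = d)
  if (stats::df.residual(fit) < 1L)
    stopf("saturated design: no residual degrees of freedom")
  an <- tryCatch(car::Anova(fit, type = 2), error = function(e) {
    if (grepl("residual sum of squares is 0", conditionMessage(e)))
      stopf("saturated design: the model fits the data exactly (zero residual variance)")
    stop(e)
  })
  terms <- rownames(an)
  keep <- terms != "Residuals"
  relabel <- c(A = factor_names[1], B = factor_names[2])
  pretty <- vapply(terms[keep], function(tm) {
    parts <- strsplit(tm, ":", fixed = TRUE)[[1]]
    paste(ifelse(parts %in% names(relabel), relabel[parts], parts),
          collapse = ":")
  }, character(1))
  Fv <- an[keep, "F value"]
  # identical cells give zero effect SS; report F = 0 rather than NaN when
  # the residual variance is also zero
  ms_res <- an["Residuals", "Sum Sq"] / an["Residuals", "Df"]
  if (ms_res == 0) Fv <- ifelse(an[keep, "Sum Sq"] == 0, 0, Inf)
  p <- an[keep, "Pr(>F)"]
  p[ms_res == 0 & an[keep, "Sum Sq"] == 0] <- 1
  tab <- data.frame(term = pretty, sumsq = an[keep, "Sum Sq"],
                    df = an[keep, "Df"], F = Fv, p = p, stars = p_stars(p),
                    row.names = NULL, stringsAsFactors = FALSE)
  structure(list(test = "two-way ANOVA (Type II SS)", table = tab,
                 df_residual = an["Residuals", "Df"]),
            class = "group_stats")
}

#' Pairwise two-tailed unpaired t tests
#'
#' Welch t tests for all group pairs, uncorrected by default with an
#' optional Sidak correction across the pairs.
#'
#' @param values numeric response.
#' @param group group labels.
#' @param sidak apply a Sidak correction across the pairs.
#' @return data frame `pair`, `t`, `df`, `p`, (`p_adj`,) `stars`.
#' @export
pairwise_t_tests <- function(values, group, sidak = FALSE) {
  group <- factor(group)
  lv <- levels(group)
  pairs <- utils::combn(lv, 2, simplify = FALSE)
  out <- do.call(rbind, lapply(pairs, function(pr) {
    tt <- stats::t.test(values[group == pr[1]], values[group == pr[2]])
    data.frame(pair = paste(pr, collapse = "-"),
               t = unname(tt$statistic), df = unname(tt$parameter),
               p = tt$p.value, stringsAsFactors = FALSE)
  }))
  if (sidak) {
    out$p_adj <- 1 - (1 - out$p)^nrow(out)
    out$stars <- p_stars(out$p_adj)
  } else {
    out$stars <- p_stars(out$p)
  }
  out
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("<group_stats> %s\n", x$test))
  if (!is.null(x$table)) {
    print(x$table, row.names = FALSE, digits = 4)
  } else {
    cat(sprintf("  F(%d, %d) = %.4g, p = %.4g %s\n",
                x$df[1], x$df[2], x$F, x$p, x$stars))
    if (!is.null(x$tukey)) {
      cat("  Tukey HSD:\n")
      print(x$tukey, row.names = FALSE, digits = 4)
    }
  }
  invisible(x)
}
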