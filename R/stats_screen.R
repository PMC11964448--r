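#' Nested-culture ANOVA model comparison
#'
#' Measurements from neurons nested in independent cultures are analysed
#' with fixed-effect linear models: the null model `value ~ culture` is
#' compared with `value ~ group + culture` by an F-test on the residual sums
#' of squares. With a single culture this reduces exactly to the classical
#' one-way ANOVA. A culture perfectly aliased with a group (so the group
#' effect is not estimable) is an error.
#'
#' @param data Data.frame with columns `value`, `group`, `culture`.
#' @return An object of class `nested_anova`: `F`, `df1`, `df2`, `p`, plus
#'   the two fitted models.
#' @export
nested_anova <- function(data) {
  data <- validate_grouped(data)
  single_culture <- nlevels(data$culture) == 1
  m0 <- if (single_culture) {
    stats::lm(value ~ 1, data = data)
  } else {
    stats::lm(value ~ culture, data = data)
  }
  m1 <- if (single_culture) {
    stats::lm(value ~ group, data = data)
  } else {
    stats::lm(value ~ group + culture, data = data)
  }
  if (any(is.na(stats::coef(m1)))) {
    bad <- names(stats::coef(m1))[is.na(stats::coef(m1))]
    stop("singular design (culture aliased with group): ",
         paste(bad, collapse = ", "))
  }
  rss0 <- sum(stats::resid(m0)^2)
  rss1 <- sum(stats::resid(m1)^2)
  df1 <- m0$df.residual - m1$df.residual
  df2 <- m1$df.residual
  if (df2 <= 0) stop("no residual degrees of freedom")
  tss <- sum((data$value - mean(data$value))^2)
  tol <- 1e-12 * max(tss, 1)
  if (rss0 - rss1 <= tol && rss1 <= tol) {
    f <- 0; p <- 1          # degenerate zero-residual case: group adds nothing
  } else if (rss1 <= tol) {
    f <- Inf; p <- 0
  } else {
    f <- ((rss0 - rss1) / df1) / (rss1 / df2)
    p <- stats::pf(f, df1, df2, lower.tail = FALSE)
  }
  structure(
    list(F = f, df1 = df1, df2 = df2, p = p, null_model = m0,
         full_model = m1),
    class = "nested_anova"
  )
}

#' @export
print.nested_anova <- function(x, ...) {
  cat(sprintf("Nested-culture ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df1, x$df2, x$F, x$p))
  invisible(x)
}

#' @keywords internal
validate_grouped <- function(data, min_groups = 2) {
  if (!all(c("value", "group", "culture") %in% names(data))) {
    stop("data must have columns value, group, culture")
  }
  if (any(is.na(data$value)) || any(is.na(data$group)) ||
      any(is.na(data$culture))) {
    stop("missing values in value/group/culture")
  }
  data$group <- factor(data$group)
  data$culture <- factor(data$culture)
  if (nlevels(data$group) < min_groups) {
    stop(sprintf("need at least %d groups", min_groups))
  }
  data
}

#' Tukey-adjusted pairwise group contrasts
#'
#' Pairwise contrasts of culture-adjusted group means (estimated marginal
#' means of `value ~ group + culture`) with studentized-range (Tukey)
#' adjustment. With fewer than 3 groups use [nested_anova()] directly.
#'
#' @param data Data.frame with columns `value`, `group`, `culture`.
#' @param adjust Multiplicity adjustment, default `"tukey"`.
#' @return Data.frame of contrasts: `contrast`, `estimate`, `SE`, `df`,
#'   `t.ratio`, `p.value`.
#' @export
pairwise_contrasts <- function(data, adjust = "tukey") {
  data <- validate_grouped(data)
  if (nlevels(data$group) < 3) {
    stop("fewer than 3 groups: use nested_anova() for a two-group comparison")
  }
  m <- if (nlevels(data$culture) == 1) {
    stats::lm(value ~ group, data = data)
  } else {
    stats::lm(value ~ group + culture, data = data)
  }
  em <- emmeans::emmeans(m, "group")
  out <- as.data.frame(emmeans::contrast(em, method = "pairwise",
                                         adjust = adjust))
  out
}

#' Two-sided one-sample t-test
#'
#' Used e.g. for band intensities normalized to a 100% control.
#'
#' @param values Numeric sample, n >= 2, non-degenerate.
#' @param mu Null-hypothesis mean.
#' @return List with `t`, `p`, `mean`, `df`.
#' @export
one_sample_t <- function(values, mu) {
  if (length(values) < 2) stop("need at least 2 observations")
  if (stats::var(values) == 0) stop("zero variance: t statistic undefined")
  ht <- stats::t.test(values, mu = mu)
  list(t = unname(ht$statistic), p = ht$p.value,
       mean = unname(ht$estimate), df = unname(ht$parameter))
}

#' Robust FDR outlier screen
#'
#' A documented simplification of proprietary outlier screens: values are
#' studentized against the sample median and MAD, two-sided normal p-values
#' are Benjamini-Hochberg adjusted, and values with adjusted p below `q`
#' are flagged. Flags only — nothing is removed.
#'
#' @param values Numeric sample, n >= 5.
#' @param q FDR rate (default 0.01).
#' @return Logical vector of flags, same length as `values`.
#' @export
flag_outliers <- function(values, q = 0.01) {
  if (length(values) < 5) stop("need at least 5 observations")
  med <- stats::median(values)
  scale <- stats::mad(values)
  dev <- values - med
  if (scale == 0) {
    z <- ifelse(dev == 0, 0, Inf)
  } else {
    z <- dev / scale
  }
  p <- 2 * stats::pnorm(-abs(z))
  stats::p.adjust(p, method = "BH") < q
}

#' Filter a differential-expression table
#'
#' Keeps proteins with `|log2fc| > fc_thresh` AND `qvalue < q_thresh` (both
#' strict: a protein sitting exactly on a threshold is excluded). The
#' threshold is two-sided because both up- and downregulated proteins count
#' as significant.
#'
#' @param table Data.frame with columns `protein`, `log2fc`, `qvalue`
#'   (q in [0, 1], finite fold changes).
#' @param fc_thresh Absolute log2 fold-change threshold (default 0.56).
#' @param q_thresh q-value threshold (default 0.01).
#' @return List: `significant` (the kept rows), `n_up`, `n_down`, `pct_up`,
#'   `pct_down` (percent of the significant set), `pct_of_total` (percent of
#'   the whole table).
#' @export
filter_de_table <- function(table, fc_thresh = 0.56, q_thresh = 0.01) {
  if (!all(c("protein", "log2fc", "qvalue") %in% names(table))) {
    stop("table must have columns protein, log2fc, qvalue")
  }
  if (nrow(table) > 0) {
    if (any(!is.finite(table$log2fc))) stop("non-finite log2 fold changes")
    if (any(table$qvalue < 0 | table$qvalue > 1)) {
      stop("q-values must lie in [0, 1]")
    }
  }
  sig <- table[abs(table$log2fc) > fc_thresh & table$qvalue < q_thresh, ,
               drop = FALSE]
  rownames(sig) <- NULL
  n_up <- sum(sig$log2fc > 0)
  n_down <- sum(sig$log2fc < 0)
  n_sig <- nrow(sig)
  list(
    significant = sig,
    n_up = n_up,
    n_down = n_down,
    pct_up = if (n_sig > 0) 100 * n_up / n_sig else 0,
    pct_down = if (n_sig > 0) 100 * n_down / n_sig else 0,
    pct_of_total = if (nrow(table) > 0) 100 * n_sig / nrow(table) else 0
  )
}
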