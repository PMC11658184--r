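# Statistical comparisons performed on the derived tables. Raw P values are
# reported throughout -- no multiple-testing correction is applied, so
# downstream users comparing many families should adjust externally.

.as_grouped <- function(values, groups) {
  if (is.list(values) && is.null(groups)) {
    groups <- rep(names(values), lengths(values))
    values <- unlist(values, use.names = FALSE)
  }
  if (is.null(groups)) stop("supply 'groups' or a named list of values")
  keep <- is.finite(values)
  list(values = values[keep], groups = factor(groups[keep]))
}

#' Classical one-way fixed-effects ANOVA
#'
#' @param values Numeric vector of per-library or per-gene statistics, or a
#'   named list of group vectors.
#' @param groups Group labels (when `values` is a vector).
#' @return List with `F`, `p`, `df_between`, `df_within`, `group_sizes`.
#' @export
one_way_anova <- function(values, groups = NULL) {
  g <- .as_grouped(values, groups)
  sizes <- table(g$groups)
  if (length(sizes) < 2L || any(sizes < 2L))
    stop("one_way_anova needs >= 2 groups with >= 2 values each")
  within_var <- tapply(g$values, g$groups, stats::var)
  means <- tapply(g$values, g$groups, mean)
  if (all(within_var == 0)) {
    if (max(means) - min(means) == 0)
      stop("all values identical: within-group variance is zero and means are equal")
    return(list(F = Inf, p = 0, df_between = length(sizes) - 1L,
                df_within = sum(sizes) - length(sizes),
                group_sizes = as.integer(sizes)))
  }
  fit <- stats::anova(stats::lm(g$values ~ g$groups))
  list(F = fit$`F value`[1], p = fit$`Pr(>F)`[1],
       df_between = fit$Df[1], df_within = fit$Df[2],
       group_sizes = as.integer(sizes))
}

#' Two-sample t-test (Welch for unpaired)
#'
#' @param a,b Numeric vectors (equal length when paired).
#' @param paired Paired test.
#' @return List with `t`, `p`, `df`, `mean_diff`.
#' @export
two_sample_t <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("each sample needs >= 2 values")
  if (paired && length(a) != length(b)) stop("paired samples must have equal size")
  if (paired && stats::sd(a - b) == 0)
    stop("zero variance of paired differences")
  if (!paired && stats::sd(a) == 0 && stats::sd(b) == 0 && mean(a) == mean(b))
    stop("zero pooled variance")
  tt <- stats::t.test(a, b, paired = paired, var.equal = FALSE)
  list(t = unname(tt$statistic), p = tt$p.value, df = unname(tt$parameter),
       mean_diff = if (paired) mean(a - b) else mean(a) - mean(b))
}

#' Pearson correlation with two-sided P
#'
#' @param x,y Numeric vectors (n >= 3).
#' @param log_transform Log-transform both variables first (used for
#'   comparisons against half-life style covariates spanning decades).
#' @return List with `r`, `p`, `n`.
#' @export
pearson_corr <- function(x, y, log_transform = FALSE) {
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3L) stop("pearson_corr needs n >= 3 finite pairs")
  if (log_transform) {
    if (any(x <= 0) || any(y <= 0)) stop("log transform requires positive values")
    x <- log(x); y <- log(y)
  }
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance in x or y")
  ct <- stats::cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
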