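# Statistical layer applied to puncta endpoints: variance stabilization,
# Bartlett's test, one-way ANOVA on batch means, Dunnett comparisons against
# a control group, and Benjamini-Hochberg FDR adjustment.

#' Variance-stabilizing square-root transform
#'
#' Count-like puncta endpoints show severe inequality of variances across
#' treatment groups; the elementwise square root stabilizes them (for
#' Poisson-like counts the transformed variance is approximately 1/4,
#' independent of the mean).
#'
#' @param values nonnegative numeric vector.
#' @return `sqrt(values)`.
#' @export
stabilize <- function(values) {
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("`values` must be finite and nonnegative", call. = FALSE)
  }
  sqrt(values)
}

#' Bartlett's test of equal group variances
#'
#' Classical Bartlett statistic referenced to a chi-square distribution with
#' `k - 1` degrees of freedom. Groups with zero variance make the statistic
#' degenerate and are rejected.
#'
#' @param groups list of numeric vectors (>= 2 groups, each n >= 2).
#' @return list with `statistic`, `df`, `p.value`.
#' @export
bartlett_groups <- function(groups) {
  if (length(groups) < 2L || any(vapply(groups, length, 1L) < 2L)) {
    stop("need >= 2 groups with >= 2 observations each", call. = FALSE)
  }
  if (any(vapply(groups, var, numeric(1)) == 0)) {
    stop("degenerate zero-variance group", call. = FALSE)
  }
  bt <- bartlett.test(groups)
  list(statistic = unname(bt$statistic), df = unname(bt$parameter),
       p.value = bt$p.value)
}

#' One-way ANOVA
#'
#' Standard between/within variance decomposition with treatment as the only
#' factor. The intended analysis unit is the batch mean of
#' square-root-transformed per-cell endpoints (see [puncta_group_stats()]).
#'
#' @param groups list of numeric vectors, one per treatment.
#' @return list with `F`, `df_between`, `df_within`, `p.value`.
#' @export
anova_oneway <- function(groups) {
  k <- length(groups)
  n <- vapply(groups, length, 1L)
  if (k < 2L || sum(n) <= k) stop("need >= 2 groups and n > k", call. = FALSE)
  values <- unlist(groups, use.names = FALSE)
  grand <- mean(values)
  means <- vapply(groups, mean, numeric(1))
  ssb <- sum(n * (means - grand)^2)
  ssw <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1)))
  df_b <- k - 1L
  df_w <- sum(n) - k
  f <- if (ssb == 0) 0 else (ssb / df_b) / (ssw / df_w)
  list(F = f, df_between = df_b, df_within = df_w,
       p.value = stats::pf(f, df_b, df_w, lower.tail = FALSE))
}

#' Dunnett's many-to-one comparisons
#'
#' Two-sided comparisons of each treatment group against the control, with
#' familywise adjustment under the max-|t| null of the multivariate t
#' distribution sharing the pooled within-group variance. Tail probabilities
#' are computed by Monte-Carlo integration with a fixed internal seed, so
#' results are deterministic for given data.
#'
#' @param groups named list of numeric vectors.
#' @param control name of the control group in `groups`.
#' @param n_mc Monte-Carlo draws for the max-|t| null.
#' @param mc_seed internal RNG seed for the integration.
#' @return data.frame with one row per treatment-vs-control comparison:
#'   `comparison`, `estimate`, `t`, `df`, `p_raw` (unadjusted two-sided t),
#'   `p_adj` (Dunnett-adjusted).
#' @export
dunnett_test <- function(groups, control, n_mc = 1e5, mc_seed = 20260917L) {
  if (!control %in% names(groups)) stop("control group not found", call. = FALSE)
  trt <- setdiff(names(groups), control)
  if (length(trt) == 0L) stop("no treatment groups to compare", call. = FALSE)
  n <- vapply(groups, length, 1L)
  if (any(n < 2L)) stop("each group needs >= 2 observations", call. = FALSE)
  means <- vapply(groups, mean, numeric(1))
  df <- sum(n) - length(groups)
  s2 <- sum(vapply(groups, function(x) sum((x - mean(x))^2), numeric(1))) / df
  if (s2 <= 0) stop("pooled within-group variance is zero", call. = FALSE)
  se <- sqrt(s2 * (1 / n[trt] + 1 / n[control]))
  tstat <- (means[trt] - means[control]) / se
  # Monte-Carlo max-|t| null: group means ~ N(0, 1/n_j), shared s2 ~ chi2_df/df
  maxabs <- with_seed(mc_seed, {
    z0 <- rnorm(n_mc, 0, sqrt(1 / n[control]))
    s <- sqrt(stats::rchisq(n_mc, df) / df)
    m <- matrix(0, n_mc, length(trt))
    for (j in seq_along(trt)) {
      zj <- rnorm(n_mc, 0, sqrt(1 / n[trt[j]]))
      m[, j] <- abs(zj - z0) / (s * sqrt(1 / n[trt[j]] + 1 / n[control]))
    }
    apply(m, 1, max)
  })
  p_adj <- vapply(abs(tstat), function(t0) mean(maxabs >= t0), numeric(1))
  data.frame(
    comparison = paste(trt, "-", control),
    estimate = unname(means[trt] - means[control]),
    t = unname(tstat), df = df,
    p_raw = unname(2 * pt(-abs(tstat), df)),
    p_adj = unname(pmin(1, p_adj)),
    row.names = NULL
  )
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted p values, monotone and capped at 1.
#'
#' @param pvals numeric vector of p values in `[0, 1]`.
#' @return adjusted p values, same order as the input.
#' @export
bh_fdr <- function(pvals) {
  if (any(!is.finite(pvals)) || any(pvals < 0 | pvals > 1)) {
    stop("p values must lie in [0, 1]", call. = FALSE)
  }
  p.adjust(pvals, method = "BH")
}

#' Group statistics for puncta endpoints
#'
#' The full statistical recipe applied to per-cell endpoint values: square-root
#' variance stabilization, aggregation to batch means (the analysis unit, one
#' value per batch of cells recorded together), Bartlett's test of variance
#' homogeneity, one-way ANOVA with treatment as the factor, and two-sided
#' Dunnett comparisons against the control group.
#'
#' @param data data.frame with columns `treatment`, `batch`, `value`
#'   (per-cell endpoint, nonnegative).
#' @param control control treatment label.
#' @param n_mc Monte-Carlo draws for [dunnett_test()].
#' @return list of class `puncta_stats` with `batch_means` (data.frame),
#'   `bartlett`, `anova`, `dunnett`.
#' @export
puncta_group_stats <- function(data, control = "vehicle", n_mc = 1e5) {
  stopifnot(all(c("treatment", "batch", "value") %in% names(data)))
  data$z <- stabilize(data$value)
  agg <- aggregate(z ~ treatment + batch, data = data, FUN = mean)
  groups <- split(agg$z, agg$treatment)
  if (length(unique(agg$treatment)) < 2L) {
    stop("need at least two treatment groups", call. = FALSE)
  }
  structure(list(
    batch_means = agg,
    bartlett = bartlett_groups(split(data$z, data$treatment)),
    anova = anova_oneway(groups),
    dunnett = dunnett_test(groups, control, n_mc = n_mc)
  ), class = "puncta_stats")
}
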