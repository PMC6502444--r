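# Statistical harness for preparation-sensitivity studies: percent-difference
# distributions, triangle-count binning, group tests, discriminant
# classification, correlation screens, ln-ln scaling fits and convergence
# curves.

#' Percent difference between two preparations of the same surface
#'
#' Smoothing mode compares a smoothed to an unsmoothed value as
#' `(smoothed - unsmoothed) / smoothed * 100`; cropping mode compares the
#' entire-enamel-cap (EEC) to the basin-cut-off (BCO) value as
#' `(EEC - BCO) / EEC * 100`. Both are `(a - b) / a * 100` with the stated
#' argument roles; the mode names document which preparation goes where.
#' A zero denominator yields `Inf` ("infinite" difference); such records are
#' excluded from downstream summaries.
#'
#' @param a the smoothed (smoothing mode) or EEC (cropping mode) value.
#' @param b the unsmoothed (smoothing mode) or BCO (cropping mode) value.
#' @param mode `"smoothing"` or `"cropping"` (documentation of roles only).
#' @return percent difference; `Inf`/`-Inf` when `a == 0` and `b != a`.
#' @export
percent_difference <- function(a, b, mode = c("smoothing", "cropping")) {
  match.arg(mode)
  out <- (a - b) / a * 100
  out[a == 0 & b != 0] <- Inf
  out[a == 0 & b == 0] <- NaN
  out
}

#' Bin surfaces by triangle count
#'
#' The four standard triangle-count classes: low (< 210), medium-low
#' (210-1799), medium-high (1800-9999) and high (10000+).
#'
#' @param triangle_count integer vector.
#' @return factor with levels `L`, `ML`, `MH`, `H`.
#' @export
bin_by_triangle_count <- function(triangle_count) {
  cut(triangle_count, breaks = c(-Inf, 210, 1800, 10000, Inf),
      labels = c("L", "ML", "MH", "H"), right = FALSE)
}

#' Summarize a percent-difference distribution
#'
#' Reports n, the empirical fraction strictly greater than zero, mean, sd,
#' median and the 2.5%/97.5% quantiles (linear interpolation between order
#' statistics, R's default type-7 rule). `prob_gt_zero` is an empirical
#' fraction, not a frequentist p-value, and is labelled accordingly.
#'
#' @param values finite numeric vector (exclude infinite differences first).
#' @return one-row data frame of class `ct_distribution_summary`.
#' @export
summarize_distribution <- function(values) {
  if (!length(values)) ct_stop("no values to summarize", "ct_validation_error")
  if (any(!is.finite(values)))
    ct_stop("non-finite values; exclude infinite percent differences first",
            "ct_validation_error")
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  out <- data.frame(n = length(values),
                    prob_gt_zero = mean(values > 0),
                    mean = mean(values),
                    sd = stats::sd(values),
                    q025 = q[1L], median = q[2L], q975 = q[3L])
  class(out) <- c("ct_distribution_summary", "data.frame")
  out
}

.check_groups <- function(values, groups, min_per_group = 2L) {
  groups <- factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) < 2L)
    ct_stop("need at least two groups", "ct_validation_error")
  tab <- table(groups)
  small <- names(tab)[tab < min_per_group]
  if (length(small))
    ct_stop(sprintf("group(s) with fewer than %d observations: %s",
                    min_per_group, paste(small, collapse = ", ")),
            "ct_validation_error")
  groups
}

#' One-way fixed-effects ANOVA
#'
#' @param values numeric response.
#' @param groups group labels (e.g. dietary categories), each with at least
#'   two observations.
#' @return list with `f` and `p` (and the fitted `aov` object as `fit`).
#' @export
anova_oneway <- function(values, groups) {
  groups <- .check_groups(values, groups)
  fit <- stats::aov(values ~ groups)
  s <- summary(fit)[[1L]]
  list(f = s[["F value"]][1L], p = s[["Pr(>F)"]][1L], fit = fit)
}

#' Factorial fixed-effects ANOVA with all interactions
#'
#' Fits `response ~ f1 * f2 * ...` (all interaction terms up to the full
#' order) and returns the per-term F and p values. Sequential (type I) sums
#' of squares, which coincide with the usual decomposition on the balanced
#' designs the synthetic studies produce.
#'
#' @param records data frame containing the factor and response columns.
#' @param factors character vector of factor column names.
#' @param response name of the numeric response column.
#' @return data frame with term, df, f, p.
#' @export
anova_factorial <- function(records, factors, response) {
  stopifnot(all(c(factors, response) %in% names(records)))
  for (f in factors) records[[f]] <- factor(records[[f]])
  fml <- stats::as.formula(paste(response, "~", paste(factors, collapse = " * ")))
  fit <- stats::aov(fml, data = records)
  mm <- stats::model.matrix(fit)
  if (fit$rank < ncol(mm)) {
    piv <- fit$qr$pivot[seq_len(fit$rank)]
    dropped <- setdiff(seq_len(ncol(mm)), piv)
    labels <- attr(stats::terms(fit), "term.labels")
    bad <- unique(labels[attr(mm, "assign")[dropped]])
    ct_stop(paste("rank-deficient design; aliased terms:",
                  paste(bad, collapse = ", ")), "ct_validation_error")
  }
  s <- summary(fit)[[1L]]
  terms <- trimws(rownames(s))
  keep <- terms != "Residuals"
  data.frame(term = terms[keep], df = s$Df[keep],
             f = s[["F value"]][keep], p = s[["Pr(>F)"]][keep],
             stringsAsFactors = FALSE)
}

#' Tukey honest significant difference test
#'
#' Studentized-range-adjusted pairwise p-values following a one-way ANOVA.
#'
#' @inheritParams anova_oneway
#' @return list with `pairs` (the TukeyHSD table) and `p_matrix` (symmetric
#'   matrix of adjusted p-values with unit diagonal).
#' @export
tukey_hsd <- function(values, groups) {
  groups <- .check_groups(values, groups)
  fit <- stats::aov(values ~ groups)
  tk <- stats::TukeyHSD(fit)$groups
  lev <- levels(groups)
  pm <- matrix(1, nlevels(groups), nlevels(groups), dimnames = list(lev, lev))
  pairs <- strsplit(rownames(tk), "-", fixed = TRUE)
  for (i in seq_along(pairs)) {
    a <- pairs[[i]][1L]; b <- pairs[[i]][2L]
    pm[a, b] <- pm[b, a] <- tk[i, "p adj"]
  }
  list(pairs = as.data.frame(tk), p_matrix = pm)
}

#' Equal-prior leave-one-out discriminant classification
#'
#' Linear discriminant analysis with equal prior probabilities for every
#' class (mimicking diet prediction for fossils, where priors are unknown)
#' and leave-one-out cross-validation. Returns the percent of observations
#' whose class is correctly recovered.
#'
#' @param values numeric vector or matrix/data frame of predictor metrics.
#' @param groups class labels, at least two observations per class.
#' @return percent correctly classified in `[0, 100]`.
#' @export
dfa_loocv <- function(values, groups) {
  groups <- .check_groups(values, groups)
  x <- as.matrix(values)
  if (any(apply(x, 2L, stats::sd) == 0))
    ct_stop("constant predictor column; drop it or choose another metric subset",
            "ct_validation_error")
  k <- nlevels(groups)
  fit <- tryCatch(
    MASS::lda(x, grouping = groups, prior = rep(1 / k, k), CV = TRUE),
    error = function(e)
      ct_stop(paste("discriminant analysis failed (singular within-class",
                    "covariance?); try a smaller metric subset:",
                    conditionMessage(e)), "ct_validation_error"))
  100 * mean(fit$class == groups)
}

#' Pairwise Pearson correlation screen
#'
#' Pearson r and p for every pair of metric columns, flagged for significance
#' at the Bonferroni-corrected threshold `alpha / n_pairs` (0.05 / 15 =
#' 0.00333 for the six standard metrics).
#'
#' @param metric_table data frame or matrix of numeric metric columns
#'   (at least 3 complete rows).
#' @param alpha family-wise error rate before correction (default 0.05).
#' @return data frame with var1, var2, r, p, significant; the Bonferroni
#'   threshold is attached as `attr(, "threshold")`. Pairs involving a
#'   constant column get `NA` r and are never flagged.
#' @export
correlation_screen <- function(metric_table, alpha = 0.05) {
  x <- as.data.frame(metric_table)
  x <- x[stats::complete.cases(x), , drop = FALSE]
  if (nrow(x) < 3L)
    ct_stop("need at least 3 complete records", "ct_validation_error")
  nm <- names(x)
  combs <- utils::combn(length(nm), 2L)
  threshold <- alpha / ncol(combs)
  rows <- lapply(seq_len(ncol(combs)), function(i) {
    a <- combs[1L, i]; b <- combs[2L, i]
    if (stats::sd(x[[a]]) == 0 || stats::sd(x[[b]]) == 0)
      return(data.frame(var1 = nm[a], var2 = nm[b], r = NA_real_,
                        p = NA_real_, significant = FALSE))
    ct <- stats::cor.test(x[[a]], x[[b]], method = "pearson")
    data.frame(var1 = nm[a], var2 = nm[b],
               r = unname(ct$estimate), p = ct$p.value,
               significant = is.finite(ct$p.value) && ct$p.value < threshold)
  })
  out <- do.call(rbind, rows)
  attr(out, "threshold") <- threshold
  out
}

#' ln-ln scaling fit over the highest resampling levels
#'
#' Ordinary least squares of `ln(metric)` on `ln(level)` restricted to the
#' `n_levels` highest levels supplied (default 7: with a ten-step ladder the
#' three lowest levels are discarded, where oversimplification distorts the
#' surface).
#'
#' @param levels numeric resampling levels (triangle counts or resolutions).
#' @param metric metric values matching `levels`; must be positive and finite
#'   on the levels used.
#' @param n_levels how many of the highest levels enter the fit.
#' @return list with slope, intercept, r_squared, n_levels_used.
#' @export
loglog_fit <- function(levels, metric, n_levels = 7L) {
  stopifnot(length(levels) == length(metric))
  ok <- is.finite(levels) & is.finite(metric)
  levels <- levels[ok]
  metric <- metric[ok]
  if (length(levels) < n_levels)
    ct_stop(sprintf("need %d levels with finite metric values, have %d",
                    n_levels, length(levels)), "ct_validation_error")
  ord <- order(levels, decreasing = TRUE)
  use <- ord[seq_len(n_levels)]
  if (any(metric[use] <= 0))
    ct_stop("non-positive metric among the levels used; log undefined",
            "ct_validation_error")
  fit <- stats::lm(log(metric[use]) ~ log(levels[use]))
  co <- stats::coef(fit)
  ss <- suppressWarnings(summary(fit))  # r^2 = 1 on exact power laws is fine
  list(slope = unname(co[2L]), intercept = unname(co[1L]),
       r_squared = ss$r.squared, n_levels_used = n_levels)
}

#' Convergence curve against the highest-level reference
#'
#' Treats the metric value at the highest level as the best available
#' estimate and reports, per level, the absolute percent difference
#' `|(v - v_ref) / v_ref| * 100`.
#'
#' @param levels numeric resampling levels (at least 2).
#' @param metric metric values matching `levels`; the highest-level value
#'   must be nonzero.
#' @return data frame with `level` and `abs_pct_diff`, sorted by level.
#' @export
convergence_curve <- function(levels, metric) {
  stopifnot(length(levels) == length(metric))
  if (length(levels) < 2L)
    ct_stop("need at least two levels", "ct_validation_error")
  ord <- order(levels)
  levels <- levels[ord]
  metric <- metric[ord]
  ref <- metric[length(metric)]
  if (!is.finite(ref) || ref == 0)
    ct_stop("reference (highest-level) value is zero or missing",
            "ct_validation_error")
  data.frame(level = levels,
             abs_pct_diff = abs((metric - ref) / ref) * 100)
}
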