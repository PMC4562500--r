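#' Exponential growth rate from a density time series
#'
#' Log-linear regression of `log(density)` on time over the sliding window
#' (of at least `min_window` points) that maximizes R-squared, which picks
#' the exponential phase of a plate-reader curve and ignores lag and
#' saturation. Deterministic.
#'
#' @param time_h time in hours
#' @param density OD or cell count (> 0)
#' @param min_window minimum number of points in the regression window
#' @return list with `rate` (per hour), `window` (index range used),
#'   `r_squared`
#' @examples
#' tt <- seq(0, 72, by = 6)
#' growth_rate_from_curve(tt, 0.01 * exp(0.3 * tt))$rate  # 0.3
#' @export
growth_rate_from_curve <- function(time_h, density, min_window = 4L) {
  if (length(time_h) != length(density) || length(time_h) < min_window)
    stop("need >= ", min_window, " matching (time, density) points",
         call. = FALSE)
  if (any(!is.finite(density)) || any(density <= 0))
    stop("densities must be positive and finite", call. = FALSE)
  o <- order(time_h)
  time_h <- time_h[o]; density <- density[o]
  y <- log(density)
  n <- length(y)
  best <- list(rate = 0, window = c(1L, n), r_squared = -Inf)
  for (i in seq_len(n - min_window + 1L)) {
    for (j in seq.int(i + min_window - 1L, n)) {
      tt <- time_h[i:j]; yy <- y[i:j]
      sxx <- sum((tt - mean(tt))^2)
      if (sxx == 0) next
      sxy <- sum((tt - mean(tt)) * (yy - mean(yy)))
      syy <- sum((yy - mean(yy))^2)
      slope <- sxy / sxx
      r2 <- if (syy == 0) 1 else (sxy * sxy) / (sxx * syy)  # flat => rate 0
      if (syy == 0) slope <- 0
      if (r2 > best$r_squared + 1e-12) {
        best <- list(rate = slope, window = c(i, j), r_squared = r2)
      }
    }
  }
  best
}

log10_ratio <- function(a, b, what) {
  if (!is.numeric(a) || !is.numeric(b) || anyNA(a) || anyNA(b) ||
      any(a <= 0) || any(b <= 0))
    stop(what, " values must be positive (log-ratio undefined otherwise)",
         call. = FALSE)
  log10(a / b)
}

#' Fitness effect of doxycycline
#'
#' `log10(fitness with dox / fitness without dox)`. Zero means no effect;
#' negative values mean a doxycycline (squelching) cost.
#'
#' @param fit_withD,fit_noD fitness (per hour), both > 0
#' @return log10 ratio
#' @export
dox_fitness_effect <- function(fit_withD, fit_noD)
  log10_ratio(fit_withD, fit_noD, "fitness")

#' Fitness effect of zeocin
#'
#' `log10(fitness with zeocin / fitness without zeocin)`. Negative values
#' mean a zeocin cost (sensitivity); values near zero mean resistance.
#'
#' @param fit_withZ,fit_noZ fitness (per hour), both > 0
#' @return log10 ratio
#' @export
zeocin_fitness_effect <- function(fit_withZ, fit_noZ)
  log10_ratio(fit_withZ, fit_noZ, "fitness")

#' Expression change between two mean fluorescence values
#'
#' `log10(mean fluorescence A / mean fluorescence B)`, e.g. evolved clone vs
#' ancestor in the same condition, or with vs without inducer. An optional
#' constant background is subtracted from both before taking the ratio.
#'
#' @param mean_fluo_A,mean_fluo_B mean fluorescence values (> background)
#' @param background constant autofluorescence to subtract (default 0)
#' @return log10 ratio
#' @export
expression_effect <- function(mean_fluo_A, mean_fluo_B, background = 0) {
  log10_ratio(mean_fluo_A - background, mean_fluo_B - background,
              "fluorescence (after background subtraction)")
}

#' Compare two samples with a t-test and Bonferroni-adjusted significance
#'
#' Two-sided Student's t-test, independent or paired. The default is the
#' classical equal-variance flavor; Welch's unequal-variance version is
#' available via `var_equal = FALSE`. Significance is declared at
#' `alpha / n_comparisons` (Bonferroni).
#'
#' @param sample_A,sample_B numeric samples (paired: equal length >= 2)
#' @param paired logical
#' @param n_comparisons number of comparisons in the family (>= 1)
#' @param alpha family-wise significance level (default 0.05)
#' @param var_equal assume equal variances (default TRUE)
#' @return list with `statistic`, `df`, `p_value`, `alpha_adjusted`,
#'   `significant`
#' @export
compare_groups <- function(sample_A, sample_B, paired = FALSE,
                           n_comparisons = 1L, alpha = 0.05,
                           var_equal = TRUE) {
  if (paired && length(sample_A) != length(sample_B))
    stop("paired comparison needs equal-length samples", call. = FALSE)
  if (length(sample_A) < 2L || length(sample_B) < 2L)
    stop("need >= 2 observations per sample", call. = FALSE)
  if (n_comparisons < 1L)
    stop("'n_comparisons' must be >= 1", call. = FALSE)
  if (paired && stats::sd(sample_A - sample_B) == 0) {
    ## identical (or perfectly shifted) pairs: t statistic is 0 for a zero
    ## mean difference, infinite otherwise; stats::t.test errors here
    md <- mean(sample_A - sample_B)
    stat <- if (md == 0) 0 else sign(md) * Inf
    p <- if (md == 0) 1 else 0
    return(list(statistic = stat, df = length(sample_A) - 1L, p_value = p,
                alpha_adjusted = alpha / n_comparisons,
                significant = p < alpha / n_comparisons))
  }
  tt <- stats::t.test(sample_A, sample_B, paired = paired,
                      var.equal = var_equal, alternative = "two.sided")
  adj <- alpha / n_comparisons
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value, alpha_adjusted = adj,
       significant = tt$p.value < adj)
}
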