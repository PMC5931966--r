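# Agreement, diagnostic-performance and summary statistics.

#' Bland-Altman agreement analysis
#'
#' Differences are `measured - reference`; the bias is their mean, and the
#' limits of agreement are `bias +- 1.96 * SD` with the sample (n-1) SD.
#' The limits are exactly symmetric about the bias, so the bias is always
#' the midpoint of the limits.
#'
#' @param measured,reference numeric vectors of equal length >= 2 (percent).
#' @return An object of class `bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high`, `n`.
#' @examples
#' bland_altman(c(60, 70, 80), c(50, 50, 50)) # bias 20, limits (0.4, 39.6)
#' @export
bland_altman <- function(measured, reference) {
  if (length(measured) != length(reference))
    stop("`measured` and `reference` must have equal length")
  if (length(measured) < 2L) stop("need at least 2 paired measurements")
  d <- measured - reference
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d)),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("<bland_altman> bias %.1f, limits of agreement (%.1f, %.1f), n = %d\n",
              x$bias, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Clopper-Pearson exact binomial confidence interval
#'
#' Exact interval from beta-distribution quantiles; the lower bound is 0
#' when `k = 0` and the upper bound 100 when `k = n`.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `>= 1`.
#' @param conf confidence level.
#' @return `c(low, high)` in percent.
#' @examples
#' clopper_pearson(24, 24) # c(85.8, 100) -- lower = 100 * 0.025^(1/24)
#' @export
clopper_pearson <- function(k, n, conf = 0.95) {
  if (length(k) != 1L || length(n) != 1L || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("need integer counts with 0 <= k <= n and n >= 1")
  a <- (1 - conf) / 2
  low <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  high <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(low = 100 * low, high = 100 * high)
}

#' Diagnostic performance against a continuous reference
#'
#' Dichotomizes both the measured and the true stenosis at `threshold`
#' (inclusive `>=` on both sides, i.e. "detection of >= 50% stenosis") and
#' reports sensitivity, specificity, PPV and NPV with Clopper-Pearson
#' 95% intervals. Metrics with a zero denominator are flagged as undefined
#' rather than propagating NaN.
#'
#' @param measured,truth numeric vectors (percent) of equal length.
#' @param threshold percent in `(0, 100)`.
#' @param conf confidence level for the intervals.
#' @return An object of class `diagnostic_performance`: counts `tp`, `fp`,
#'   `tn`, `fn`; per metric a list with `value` (percent), `ci` and
#'   `undefined`.
#' @export
diagnostic_performance <- function(measured, truth, threshold, conf = 0.95) {
  if (length(measured) != length(truth) || length(measured) < 1L)
    stop("`measured` and `truth` must be non-empty and of equal length")
  if (threshold <= 0 || threshold >= 100) stop("threshold must be in (0, 100)")
  pred <- measured >= threshold
  cond <- truth >= threshold
  tp <- sum(pred & cond); fp <- sum(pred & !cond)
  tn <- sum(!pred & !cond); fn <- sum(!pred & cond)
  metric <- function(k, n) {
    if (n == 0)
      list(value = NA_real_, ci = c(low = NA_real_, high = NA_real_),
           undefined = TRUE)
    else
      list(value = 100 * k / n, ci = clopper_pearson(k, n, conf),
           undefined = FALSE)
  }
  structure(list(tp = tp, fp = fp, tn = tn, fn = fn,
                 sensitivity = metric(tp, tp + fn),
                 specificity = metric(tn, tn + fp),
                 ppv = metric(tp, tp + fp),
                 npv = metric(tn, tn + fn),
                 threshold = threshold, n = length(measured)),
            class = "diagnostic_performance")
}

#' @export
print.diagnostic_performance <- function(x, ...) {
  cat(sprintf("<diagnostic_performance> threshold >= %.0f%%: tp %d fp %d tn %d fn %d\n",
              x$threshold, x$tp, x$fp, x$tn, x$fn))
  for (m in c("sensitivity", "specificity", "ppv", "npv")) {
    v <- x[[m]]
    if (v$undefined) cat(sprintf("  %-12s undefined\n", m))
    else cat(sprintf("  %-12s %.1f%% (%.1f-%.1f)\n", m, v$value,
                     v$ci["low"], v$ci["high"]))
  }
  invisible(x)
}

#' Per-plaque quantification bundle
#'
#' @param calcium_volume mm^3.
#' @param diameter_stenosis_pct,area_stenosis_pct percent.
#' @return An object of class `plaque_quant`.
#' @export
plaque_quant <- function(calcium_volume, diameter_stenosis_pct,
                         area_stenosis_pct) {
  if (calcium_volume < 0) stop("calcium_volume must be >= 0")
  structure(list(calcium_volume = calcium_volume,
                 diameter_stenosis_pct = diameter_stenosis_pct,
                 area_stenosis_pct = area_stenosis_pct),
            class = "plaque_quant")
}

#' Fractional reduction of plaque measurements after de-blooming
#'
#' `RCV = (CV_before - CV_after) / CV_before` and likewise RDS (diameter
#' stenosis) and RAS (area stenosis), reported in percent. A metric whose
#' before-value is 0 is flagged undefined. Group-level summaries should be
#' the mean of per-plaque reductions, not the reduction of group means --
#' the two differ.
#'
#' @param before,after [plaque_quant()] objects (without / with
#'   de-blooming).
#' @return An object of class `plaque_change`: `rcv`, `rds`, `ras`
#'   (percent, `NA` when undefined) and `undefined` (named logical).
#' @export
plaque_change <- function(before, after) {
  red <- function(b, a) if (b > 0) 100 * (b - a) / b else NA_real_
  rcv <- red(before$calcium_volume, after$calcium_volume)
  rds <- red(before$diameter_stenosis_pct, after$diameter_stenosis_pct)
  ras <- red(before$area_stenosis_pct, after$area_stenosis_pct)
  structure(list(rcv = rcv, rds = rds, ras = ras,
                 undefined = c(rcv = is.na(rcv), rds = is.na(rds),
                               ras = is.na(ras))),
            class = "plaque_change")
}

#' Image-quality score summary
#'
#' Tallies 4-point image-quality scores (1 excellent ... 4 non-diagnostic)
#' and the proportion of diagnostic segments (scores 1-3).
#'
#' @param scores integer vector with values in 1--4.
#' @return An object of class `iq_summary`: `counts` (named, scores 1-4),
#'   `percents` (one decimal), `percent_diagnostic`, `n`.
#' @examples
#' s <- rep(1:4, times = c(100, 174, 74, 27))
#' iq_summary(s)$percent_diagnostic # 92.8
#' @export
iq_summary <- function(scores) {
  if (length(scores) == 0L) stop("`scores` must be non-empty")
  if (!all(scores %in% 1:4)) stop("all scores must be in 1..4")
  counts <- vapply(1:4, function(s) sum(scores == s), integer(1))
  names(counts) <- as.character(1:4)
  n <- length(scores)
  structure(list(counts = counts,
                 percents = round(100 * counts / n, 1),
                 percent_diagnostic = round(100 * sum(counts[1:3]) / n, 1),
                 n = n),
            class = "iq_summary")
}

#' Two-group comparison of a continuous image-quality metric
#'
#' Mean, SD and a two-sided two-sample t-test p-value, for comparing SNR or
#' noise between processing arms.
#'
#' @param x,y numeric vectors (length >= 2 each).
#' @return List with `mean_x`, `sd_x`, `mean_y`, `sd_y`, `p_value`.
#' @export
group_compare <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per group")
  list(mean_x = mean(x), sd_x = stats::sd(x),
       mean_y = mean(y), sd_y = stats::sd(y),
       p_value = stats::t.test(x, y)$p.value)
}
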