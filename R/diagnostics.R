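# GIST vs non-GIST classification by brightness cutoffs, and the
# accompanying diagnostic-test statistics.

#' Brightness cutoff rule
#'
#' The rule flags a lesion as GIST when its echogenicity and/or
#' heterogeneity reach fixed cutoffs. Defaults are the ROC-optimized
#' critical values T_mean >= 65 and T_SD >= 75 with the "either" (at least
#' one of the two findings) combination; comparisons are inclusive.
#'
#' @param t_mean_cut,t_sd_cut Cutoffs in \[0, 255\].
#' @param combination One of `"either"`, `"both"`, `"mean_only"`,
#'   `"sd_only"`.
#' @return An object of class `eus_rule`.
#' @export
eus_rule <- function(t_mean_cut = 65, t_sd_cut = 75,
                     combination = c("either", "both", "mean_only", "sd_only")) {
  combination <- match.arg(combination)
  if (t_mean_cut < 0 || t_mean_cut > 255 || t_sd_cut < 0 || t_sd_cut > 255) {
    stop_validation("cutoffs must lie in [0, 255]")
  }
  structure(list(t_mean_cut = t_mean_cut, t_sd_cut = t_sd_cut,
                 combination = combination), class = "eus_rule")
}

#' @export
print.eus_rule <- function(x, ...) {
  desc <- switch(x$combination,
    either = sprintf("T_mean >= %g OR T_SD >= %g", x$t_mean_cut, x$t_sd_cut),
    both = sprintf("T_mean >= %g AND T_SD >= %g", x$t_mean_cut, x$t_sd_cut),
    mean_only = sprintf("T_mean >= %g", x$t_mean_cut),
    sd_only = sprintf("T_SD >= %g", x$t_sd_cut))
  cat("GIST prediction rule:", desc, "\n")
  invisible(x)
}

#' Classify lesions with a cutoff rule
#'
#' @param records Data frame with columns `t_mean` and `t_sd` (e.g. from
#'   [generate_cohort()]).
#' @param rule An [eus_rule()].
#' @return `records` with a `predicted_label` column (`"GIST"` /
#'   `"non-GIST"`).
#' @examples
#' coh <- generate_cohort(cohort_spec(seed = 1))
#' table(classify(coh, eus_rule())$predicted_label)
#' @export
classify <- function(records, rule = eus_rule()) {
  if (!all(c("t_mean", "t_sd") %in% names(records))) {
    stop_validation("records must have t_mean and t_sd columns")
  }
  m <- records$t_mean >= rule$t_mean_cut
  s <- records$t_sd >= rule$t_sd_cut
  pos <- switch(rule$combination,
                either = m | s, both = m & s, mean_only = m, sd_only = s)
  records$predicted_label <- ifelse(pos, "GIST", "non-GIST")
  records
}

# Wilson score interval for a binomial proportion (no continuity
# correction), on the percent scale.
wilson_ci <- function(k, n, conf = 0.95) {
  if (n == 0) return(c(NA_real_, NA_real_))
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- k / n
  denom <- 1 + z^2 / n
  center <- (p + z^2 / (2 * n)) / denom
  half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
  100 * c(max(0, center - half), min(1, center + half))
}

#' Diagnostic-test metrics from labeled records
#'
#' Cross-tabulates truth against prediction (positive class `"GIST"`) and
#' reports sensitivity, specificity, PPV, NPV and accuracy as percentages
#' with 95% Wilson score confidence intervals. A rate whose denominator is
#' zero is reported as `NA` (undefined), not 0.
#'
#' @param records Data frame with `truth_label` and `predicted_label`
#'   columns, or use `counts`.
#' @param counts Optional named vector/list `c(tp=, fp=, fn=, tn=)`
#'   overriding `records`.
#' @return An object of class `eus_metrics`: counts, a `rates` data frame
#'   (estimate and CI bounds, percent), and the underlying fractions.
#' @examples
#' evaluate(counts = c(tp = 47, fp = 3, fn = 3, tn = 12))
#' @export
evaluate <- function(records = NULL, counts = NULL) {
  if (is.null(counts)) {
    if (!all(c("truth_label", "predicted_label") %in% names(records))) {
      stop_validation("records must have truth_label and predicted_label columns")
    }
    truth_pos <- records$truth_label == "GIST"
    pred_pos <- records$predicted_label == "GIST"
    counts <- c(tp = sum(truth_pos & pred_pos),
                fp = sum(!truth_pos & pred_pos),
                fn = sum(truth_pos & !pred_pos),
                tn = sum(!truth_pos & !pred_pos))
  }
  counts <- as.list(counts)
  tp <- counts$tp; fp <- counts$fp; fn <- counts$fn; tn <- counts$tn
  n <- tp + fp + fn + tn
  rate <- function(k, d) if (d > 0) 100 * k / d else NA_real_
  est <- c(sensitivity = rate(tp, tp + fn),
           specificity = rate(tn, tn + fp),
           ppv = rate(tp, tp + fp),
           npv = rate(tn, tn + fn),
           accuracy = rate(tp + tn, n))
  ci <- rbind(sensitivity = wilson_ci(tp, tp + fn),
              specificity = wilson_ci(tn, tn + fp),
              ppv = wilson_ci(tp, tp + fp),
              npv = wilson_ci(tn, tn + fn),
              accuracy = wilson_ci(tp + tn, n))
  rates <- data.frame(rate = names(est), estimate = unname(est),
                      ci_low = ci[, 1], ci_high = ci[, 2],
                      row.names = NULL)
  structure(list(tp = tp, fp = fp, fn = fn, tn = tn, n = n, rates = rates),
            class = "eus_metrics")
}

#' @export
print.eus_metrics <- function(x, digits = 1, ...) {
  cat(sprintf("Confusion counts: TP=%d FP=%d FN=%d TN=%d (n=%d)\n",
              x$tp, x$fp, x$fn, x$tn, x$n))
  r <- x$rates
  for (i in seq_len(nrow(r))) {
    if (is.na(r$estimate[i])) {
      cat(sprintf("  %-12s undefined (zero denominator)\n", r$rate[i]))
    } else {
      cat(sprintf("  %-12s %5.*f%% (95%% CI %.*f-%.*f)\n", r$rate[i],
                  digits, r$estimate[i], digits, r$ci_low[i],
                  digits, r$ci_high[i]))
    }
  }
  invisible(x)
}

#' Empirical ROC analysis over integer brightness cutoffs
#'
#' Sweeps cutoffs 0..255 with the inclusive `score >= cutoff` positive
#' rule, computes sensitivity/specificity at each, the trapezoidal AUC, and
#' the Youden-optimal cutoff (`J = sensitivity + specificity - 1`, ties
#' broken toward the lower cutoff).
#'
#' @param records Data frame with `truth_label` and the score column.
#' @param score `"t_mean"` or `"t_sd"`.
#' @return An object of class `eus_roc`: `points` (cutoff, sensitivity,
#'   specificity), `auc`, `optimal_cutoff`, `youden`.
#' @export
roc_analysis <- function(records, score = c("t_mean", "t_sd")) {
  score <- match.arg(score)
  truth_pos <- records$truth_label == "GIST"
  if (!any(truth_pos) || all(truth_pos)) {
    stop_validation("ROC analysis requires both classes present")
  }
  x <- records[[score]]
  cuts <- 0:255
  sens <- vapply(cuts, function(cc) mean(x[truth_pos] >= cc), numeric(1))
  spec <- vapply(cuts, function(cc) mean(x[!truth_pos] < cc), numeric(1))
  pts <- data.frame(cutoff = cuts, sensitivity = sens, specificity = spec)
  # staircase from (0,0) [cutoff above all scores] to (1,1) [cutoff 0]
  fpr <- c(1 - spec, 0)
  tpr <- c(sens, 0)
  ord <- order(fpr, tpr)
  fpr <- fpr[ord]; tpr <- tpr[ord]
  auc <- sum(diff(fpr) * (utils::head(tpr, -1) + utils::tail(tpr, -1)) / 2)
  j <- sens + spec - 1
  best <- which.max(j)  # first max -> lowest cutoff
  structure(list(points = pts, auc = auc, optimal_cutoff = cuts[best],
                 youden = j[best], score = score), class = "eus_roc")
}

#' @export
print.eus_roc <- function(x, ...) {
  cat(sprintf("ROC analysis of %s (GIST vs non-GIST)\n", x$score))
  cat(sprintf("  AUC (trapezoid):       %.3f\n", x$auc))
  cat(sprintf("  Youden-optimal cutoff: %d (J = %.3f)\n",
              x$optimal_cutoff, x$youden))
  invisible(x)
}

#' @export
plot.eus_roc <- function(x, ...) {
  graphics::plot(1 - x$points$specificity, x$points$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC: %s (AUC = %.3f)", x$score, x$auc), ...)
  graphics::abline(0, 1, lty = 3)
  invisible(x)
}

#' One-way ANOVA across histology groups
#'
#' Classical fixed-effects one-way analysis of variance
#' (`F = MS_between / MS_within` on `(k - 1, N - k)` degrees of freedom),
#' delegated to [stats::oneway.test()] with equal variances. Degenerate
#' inputs (zero between-group variability) return `F = 0, p = 1`.
#'
#' @param groups List of >= 2 numeric vectors, each of length >= 2.
#' @return List with `statistic` (F), `df` (numerator, denominator),
#'   `p_value`.
#' @export
one_way_anova <- function(groups) {
  if (length(groups) < 2 || any(vapply(groups, length, 0L) < 2)) {
    stop_validation("need >= 2 groups with >= 2 values each")
  }
  y <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, 0L)))
  k <- length(groups)
  df <- c(k - 1, length(y) - k)
  means <- vapply(groups, mean, numeric(1))
  ss_between <- sum(vapply(groups, length, 0L) * (means - mean(y))^2)
  ss_within <- sum(vapply(groups, function(v) sum((v - mean(v))^2), numeric(1)))
  if (ss_between == 0) return(list(statistic = 0, df = df, p_value = 1))
  if (ss_within == 0) {
    warning("zero within-group variance; p-value at machine floor", call. = FALSE)
    return(list(statistic = Inf, df = df, p_value = .Machine$double.xmin))
  }
  ft <- stats::oneway.test(y ~ g, var.equal = TRUE)
  list(statistic = unname(ft$statistic), df = unname(ft$parameter),
       p_value = ft$p.value)
}

#' Two-group comparison (pooled-variance t test)
#'
#' Used for the benign-vs-malignant GIST sub-analysis on simulated data.
#' Identical inputs return `t = 0, p = 1`; a zero pooled variance with
#' different means reports a machine-floor p-value with a warning instead
#' of erroring.
#'
#' @param a,b Numeric vectors, each of length >= 2.
#' @return List with `statistic` (t), `df`, `p_value`.
#' @export
compare_two_groups <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) {
    stop_validation("both groups need >= 2 values")
  }
  df <- length(a) + length(b) - 2
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) return(list(statistic = 0, df = df, p_value = 1))
    warning("zero within-group variance; p-value at machine floor", call. = FALSE)
    return(list(statistic = sign(mean(a) - mean(b)) * Inf, df = df,
                p_value = .Machine$double.xmin))
  }
  tt <- stats::t.test(a, b, var.equal = TRUE)
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value)
}
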