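# ROC analysis over gamma passing rates.
#
# Classification rule: at decision threshold tau, a delivery whose passing
# rate is BELOW tau is called positive (flagged as erroneous); a passing
# rate equal to tau is called negative. Low scores therefore indicate
# positives, the opposite of many ROC libraries' default orientation.

#' Build a ROC curve over passing-rate thresholds
#'
#' Candidate thresholds are the distinct observed passing rates plus
#' sentinels below the minimum and above the maximum. For each threshold
#' tau, sensitivity and specificity are computed under the rule "positive
#' iff passing rate < tau". The AUC is the trapezoidal area over
#' (FPR, TPR), which equals the Mann-Whitney probability that a random
#' positive scores below a random negative (ties counted half). The
#' optimal cutoff maximizes Youden's J = sensitivity + specificity - 1;
#' exact ties in J are broken toward higher specificity, then toward the
#' lower threshold (fewer false positives).
#'
#' @param passing_rate_pct numeric scores in `[0, 100]`.
#' @param label logical or 0/1: `TRUE`/1 = positive (the dosimetric
#'   deviation exceeds the studied magnitude).
#' @return object of class `roc_result`: `points` (data.frame with
#'   `threshold`, `sensitivity`, `specificity`, `fpr`), `auc`,
#'   `optimal_cutoff_pct`, `j_max`, `sens_at_opt`, `spec_at_opt`,
#'   `n_pos`, `n_neg`.
#' @export
build_roc <- function(passing_rate_pct, label) {
  if (length(passing_rate_pct) == 0L) stop("empty input: no scores")
  stopifnot(length(label) == length(passing_rate_pct),
            all(is.finite(passing_rate_pct)))
  label <- as.logical(label)
  n_pos <- sum(label); n_neg <- sum(!label)
  if (n_pos == 0L || n_neg == 0L)
    stop("undefined ROC: need at least one positive and one negative label")
  s <- sort(unique(passing_rate_pct))
  eps <- max(1, diff(range(s)))
  thresholds <- c(s[1] - eps, s, s[length(s)] + eps)
  pts <- do.call(rbind, lapply(thresholds, function(tau) {
    called_pos <- passing_rate_pct < tau
    data.frame(threshold = tau,
               sensitivity = sum(called_pos & label) / n_pos,
               specificity = sum(!called_pos & !label) / n_neg)
  }))
  pts$fpr <- 1 - pts$specificity
  pts <- pts[order(pts$fpr, pts$sensitivity), ]
  auc <- sum(diff(pts$fpr) * (utils::head(pts$sensitivity, -1) +
                              utils::tail(pts$sensitivity, -1)) / 2)
  j <- pts$sensitivity + pts$specificity - 1
  best <- which(j >= max(j) - 1e-12)
  best <- best[order(-pts$specificity[best], pts$threshold[best])][1]
  structure(list(points = pts, auc = auc,
                 optimal_cutoff_pct = pts$threshold[best],
                 j_max = j[best],
                 sens_at_opt = pts$sensitivity[best],
                 spec_at_opt = pts$specificity[best],
                 n_pos = n_pos, n_neg = n_neg),
            class = "roc_result")
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC over %d positives / %d negatives: AUC = %.2f\n",
              x$n_pos, x$n_neg, x$auc))
  cat(sprintf("  optimal passing-rate cutoff %.1f%% (J = %.2f, sens %.2f, spec %.2f)\n",
              x$optimal_cutoff_pct, x$j_max, x$sens_at_opt, x$spec_at_opt))
  invisible(x)
}

#' @export
plot.roc_result <- function(x, ...) {
  graphics::plot(x$points$fpr, x$points$sensitivity, type = "s",
                 xlab = "1 - specificity (FPR)", ylab = "sensitivity (TPR)",
                 xlim = c(0, 1), ylim = c(0, 1), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  graphics::points(1 - x$spec_at_opt, x$sens_at_opt, pch = 19)
  invisible(x)
}

#' Mann-Whitney AUC by direct pair counting
#'
#' Independent oracle for [build_roc()]'s trapezoidal AUC: the fraction of
#' (positive, negative) pairs with the positive scoring strictly below the
#' negative, plus half credit for ties.
#'
#' @inheritParams build_roc
#' @return probability in `[0, 1]`.
#' @export
auc_mann_whitney <- function(passing_rate_pct, label) {
  label <- as.logical(label)
  pos <- passing_rate_pct[label]; neg <- passing_rate_pct[!label]
  if (!length(pos) || !length(neg))
    stop("undefined ROC: need at least one positive and one negative label")
  total <- 0
  for (p in pos) total <- total + sum(p < neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

#' Mean AUC of a criteria group
#'
#' Arithmetic mean of the AUCs of the seven dose-difference / DTA pairs of
#' one normalization group, per deviation threshold, reported to two
#' decimals (the convention of the study's summary tables).
#'
#' @param auc_table data.frame with columns `metric` (or `dose_diff_pct` +
#'   `dta_mm`), `normalization`, one AUC column per deviation threshold
#'   (e.g. `auc_gt5`, `auc_gt10`, `auc_gt20`).
#' @param group `"global"` or `"local"`.
#' @param auc_cols names of the AUC columns to average; defaults to all
#'   columns starting with `"auc"`.
#' @return named numeric vector of rounded means, one per AUC column.
#' @export
summarize_group <- function(auc_table, group = c("global", "local"),
                            auc_cols = grep("^auc", names(auc_table), value = TRUE)) {
  group <- match.arg(group)
  rows <- auc_table[auc_table$normalization == group, , drop = FALSE]
  if (nrow(rows) != 7L)
    stop("expected the 7 criteria of the ", group, " group, got ", nrow(rows),
         if (nrow(rows) < 7L) " (missing criteria)" else "")
  vapply(auc_cols, function(cl) round(mean(rows[[cl]]), 2), numeric(1))
}

#' Fraction of deliveries failing the tolerance passing rate
#'
#' For each gamma metric, the fraction of scenarios whose passing rate is
#' strictly below the tolerance (a passing rate equal to the tolerance
#' passes).
#'
#' @param results long-format data.frame with columns `metric` and
#'   `passing_rate_pct` (one row per scenario x metric).
#' @param tolerance_pct tolerance passing rate in `(0, 100]` (default 95).
#' @return data.frame: `metric`, `n_fail`, `n`, `fraction_failing`.
#' @export
tolerance_failure_fraction <- function(results, tolerance_pct = 95) {
  stopifnot(tolerance_pct > 0, tolerance_pct <= 100)
  out <- do.call(rbind, lapply(split(results, results$metric), function(d) {
    data.frame(metric = d$metric[1], n_fail = sum(d$passing_rate_pct < tolerance_pct),
               n = nrow(d), stringsAsFactors = FALSE)
  }))
  out$fraction_failing <- out$n_fail / out$n
  rownames(out) <- NULL
  out
}
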