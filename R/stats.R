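# Diagnostic performance: 2x2 operating points with exact Clopper-Pearson
# intervals, prevalence-scenario PPV/accuracy, two-proportion chi-squared
# comparison, subgroup (forest-plot) sensitivity tables. Internal values are
# full precision; whole-percent rounding (half-up) is presentation only.

#' Round half-up to whole percent
#'
#' Presentation rounding used throughout reports: 0.5 always rounds up.
#' @param x numeric.
#' @param digits decimal places (default 0).
#' @return rounded numeric.
#' @export
percent_round <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

#' Exact binomial (Clopper-Pearson) confidence interval
#'
#' The exact interval from inversion of binomial tail probabilities via beta
#' quantiles, returned in percent at full precision.
#'
#' @param k number of successes, `0 <= k <= n`.
#' @param n number of trials, `n >= 1`.
#' @param conf_level confidence level. Default 0.95.
#' @return named vector `c(lower, upper)` in percent.
#' @export
binomial_ci <- function(k, n, conf_level = 0.95) {
  if (length(k) != 1 || length(n) != 1 || is.na(k) || is.na(n) ||
      n < 1 || k < 0 || k > n || k != round(k) || n != round(n))
    stop("binomial_ci needs integer counts with 0 <= k <= n, n >= 1",
         call. = FALSE)
  a <- (1 - conf_level) / 2
  lower <- if (k == 0) 0 else stats::qbeta(a, k, n - k + 1)
  upper <- if (k == n) 1 else stats::qbeta(1 - a, k + 1, n - k)
  c(lower = 100 * lower, upper = 100 * upper)
}

#' Diagnostic operating point from 2x2 counts
#'
#' @param tp,fn,fp,tn true/false positive/negative counts.
#' @param conf_level confidence level for the Clopper-Pearson intervals.
#' @return an object of class `operating_point` with counts, sensitivity and
#'   specificity (percent, full precision) and their exact 95% CIs.
#' @export
operating_point_from_counts <- function(tp, fn, fp, tn, conf_level = 0.95) {
  counts <- c(tp = tp, fn = fn, fp = fp, tn = tn)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  sens <- if (tp + fn > 0) 100 * tp / (tp + fn) else NA_real_
  spec <- if (fp + tn > 0) 100 * tn / (fp + tn) else NA_real_
  structure(list(
    tp = tp, fn = fn, fp = fp, tn = tn,
    sensitivity = sens,
    sensitivity_ci = if (tp + fn > 0) binomial_ci(tp, tp + fn, conf_level)
                     else c(lower = NA_real_, upper = NA_real_),
    specificity = spec,
    specificity_ci = if (fp + tn > 0) binomial_ci(tn, fp + tn, conf_level)
                     else c(lower = NA_real_, upper = NA_real_),
    adjusted_specificity = NULL
  ), class = "operating_point")
}

#' Diagnostic operating point from calls and truth
#'
#' Crosses panel calls with true disease status into a 2x2 table and
#' computes sensitivity and specificity with exact binomial intervals.
#'
#' @param calls an `aab_calls` data.frame (see [call_panel()]), or any
#'   data.frame with `subject_id` and logical `panel_positive`.
#' @param truth a data.frame with `subject_id` and logical `true_cancer`
#'   (e.g. [truth_table()]), or a logical vector named by subject id.
#' @param conf_level confidence level. Default 0.95.
#' @return an `operating_point`.
#' @export
operating_point <- function(calls, truth, conf_level = 0.95) {
  tr <- truth_lookup(truth, calls$subject_id)
  pos <- calls$panel_positive
  operating_point_from_counts(tp = sum(pos & tr), fn = sum(!pos & tr),
                              fp = sum(pos & !tr), tn = sum(!pos & !tr),
                              conf_level = conf_level)
}

truth_lookup <- function(truth, ids) {
  if (is.data.frame(truth)) {
    i <- match(ids, truth$subject_id)
    if (anyNA(i))
      stop("subject without truth label: ", ids[is.na(i)][1], call. = FALSE)
    as.logical(truth$true_cancer[i])
  } else {
    if (!all(ids %in% names(truth)))
      stop("subject without truth label: ",
           setdiff(ids, names(truth))[1], call. = FALSE)
    as.logical(truth[ids])
  }
}

#' @export
print.operating_point <- function(x, ...) {
  fmt <- function(v, ci) sprintf("%s%% (95%% CI %s-%s%%)  [n = %d]",
                                 percent_round(v), percent_round(ci[1]),
                                 percent_round(ci[2]), NA)
  cat(sprintf("Operating point (tp=%d fn=%d fp=%d tn=%d)\n",
              x$tp, x$fn, x$fp, x$tn))
  cat(sprintf("  sensitivity %g%% (95%% CI %g-%g%%)\n",
              percent_round(x$sensitivity),
              percent_round(x$sensitivity_ci[1]),
              percent_round(x$sensitivity_ci[2])))
  cat(sprintf("  specificity %g%% (95%% CI %g-%g%%)\n",
              percent_round(x$specificity),
              percent_round(x$specificity_ci[1]),
              percent_round(x$specificity_ci[2])))
  if (!is.null(x$adjusted_specificity))
    cat(sprintf("  occult-adjusted specificity %g%%\n",
                percent_round(x$adjusted_specificity)))
  invisible(x)
}

check_scenario <- function(sensitivity, specificity, prevalence) {
  if (any(c(sensitivity, specificity, prevalence) < 0) ||
      any(c(sensitivity, specificity) > 1) ||
      prevalence <= 0 || prevalence >= 1)
    stop("sensitivity/specificity must lie in [0,1] and prevalence in (0,1); ",
         "pass fractions, not percentages", call. = FALSE)
}

#' Positive predictive value under a prevalence scenario
#'
#' `PPV = s*pi / (s*pi + (1-sp)*(1-pi))` by Bayes' rule, in percent.
#'
#' @param sensitivity,specificity fractions in `[0, 1]`.
#' @param prevalence disease prevalence, fraction in `(0, 1)`.
#' @return PPV in percent, full precision.
#' @export
ppv <- function(sensitivity, specificity, prevalence) {
  check_scenario(sensitivity, specificity, prevalence)
  100 * sensitivity * prevalence /
    (sensitivity * prevalence + (1 - specificity) * (1 - prevalence))
}

#' Express a PPV as "one positive in N"
#'
#' @param ppv_percent PPV in percent.
#' @return integer N = 100/PPV rounded half-up.
#' @export
one_in_n <- function(ppv_percent) {
  if (any(ppv_percent <= 0)) stop("one_in_n undefined for PPV <= 0", call. = FALSE)
  as.integer(floor(100 / ppv_percent + 0.5))
}

#' Overall accuracy under a prevalence scenario
#'
#' Prevalence-weighted fraction correctly classified,
#' `100*(s*pi + sp*(1-pi))`.
#'
#' @inheritParams ppv
#' @return accuracy in percent, full precision.
#' @export
accuracy <- function(sensitivity, specificity, prevalence) {
  check_scenario(sensitivity, specificity, prevalence)
  100 * (sensitivity * prevalence + specificity * (1 - prevalence))
}

#' Compare two proportions by Pearson chi-squared
#'
#' Two-sided Pearson chi-squared test on the 2x2 table, without continuity
#' correction.
#'
#' @param k1,n1,k2,n2 successes and trials in the two groups.
#' @return list with `chi2` and `p`.
#' @export
compare_proportions <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1 || k1 < 0 || k2 < 0 || k1 > n1 || k2 > n2)
    stop("invalid counts", call. = FALSE)
  if ((k1 + k2) == 0 || (k1 + k2) == (n1 + n2))
    stop("degenerate table: a margin is empty", call. = FALSE)
  ht <- suppressWarnings(stats::prop.test(c(k1, k2), c(n1, n2),
                                          correct = FALSE))
  list(chi2 = unname(ht$statistic), p = ht$p.value)
}

#' Reduction in false positives between two specificities
#'
#' The relative drop in the false-positive rate when specificity moves from
#' `spec_old` to `spec_new` (both in percent):
#' `100 * ((100-spec_old) - (100-spec_new)) / (100-spec_old)`.
#'
#' @param spec_old,spec_new specificities in percent.
#' @return percent reduction (negative if false positives increased).
#' @export
reduction_in_false_positives <- function(spec_old, spec_new) {
  if (spec_old < 0 || spec_old > 100 || spec_new < 0 || spec_new > 100)
    stop("specificities must lie in [0, 100]", call. = FALSE)
  if (spec_old == 100)
    stop("reduction undefined: old specificity has no false positives",
         call. = FALSE)
  100 * ((100 - spec_old) - (100 - spec_new)) / (100 - spec_old)
}

#' Subgroup sensitivity table (forest-plot data)
#'
#' Per-subgroup sensitivity with exact binomial intervals among the truly
#' diseased subjects, plus an overall row — the data behind a forest plot of
#' sensitivity by tumor characteristics.
#'
#' @param calls an `aab_calls` data.frame.
#' @param truth truth labels as in [operating_point()].
#' @param groups factor or character vector of subgroup labels named by
#'   subject id (subjects absent from `groups` are excluded); only truly
#'   diseased subjects enter the rows.
#' @return a data.frame of class `aab_subgroups`: `group`, `n`, `k`,
#'   `sensitivity`, `lower`, `upper` (percent; CI is `NA` for empty groups).
#' @export
subgroup_table <- function(calls, truth, groups) {
  tr <- truth_lookup(truth, calls$subject_id)
  pos <- calls$panel_positive
  ids <- calls$subject_id
  keep <- tr & ids %in% names(groups)
  g <- as.character(groups[ids[keep]])
  p <- pos[keep]
  levs <- unique(as.character(groups))
  rows <- lapply(c("overall", levs), function(lv) {
    sel <- if (lv == "overall") rep(TRUE, length(g)) else g == lv
    n <- sum(sel); k <- sum(p[sel])
    if (n == 0)
      return(data.frame(group = lv, n = 0L, k = 0L, sensitivity = NA_real_,
                        lower = NA_real_, upper = NA_real_))
    ci <- binomial_ci(k, n)
    data.frame(group = lv, n = n, k = k, sensitivity = 100 * k / n,
               lower = ci[["lower"]], upper = ci[["upper"]])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("aab_subgroups", "data.frame")
  out
}

#' Forest plot of subgroup sensitivities
#'
#' @param x an `aab_subgroups` table.
#' @param ref_line vertical reference line, percent (default: the overall
#'   sensitivity).
#' @param ... ignored.
#' @export
plot.aab_subgroups <- function(x, ref_line = NULL, ...) {
  d <- x[!is.na(x$sensitivity), , drop = FALSE]
  m <- nrow(d)
  ys <- rev(seq_len(m))
  graphics::plot(NULL, xlim = c(0, 100), ylim = c(0.5, m + 0.5),
                 yaxt = "n", xlab = "Sensitivity (%)", ylab = "",
                 main = "Panel sensitivity by subgroup")
  graphics::axis(2, at = ys, labels = sprintf("%s (%d)", d$group, d$n),
                 las = 1, cex.axis = 0.8)
  graphics::segments(d$lower, ys, d$upper, ys)
  graphics::points(d$sensitivity, ys, pch = 15)
  graphics::abline(v = ref_line %||% d$sensitivity[d$group == "overall"],
                   lty = 2, col = "grey40")
  invisible(x)
}
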