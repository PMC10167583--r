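# Diagnostic-accuracy statistics for a binary detector scored against a
# manual reference standard: the 2x2 table, the full metric set with 95%
# intervals, and the interval machinery (exact and score intervals for
# proportions, log-method and bootstrap intervals for likelihood ratios,
# large-sample interval for Cohen's kappa).

#' Build a confusion matrix from raw counts
#'
#' @param tp,fp,fn,tn Non-negative integer counts (true positive, false
#'   positive, false negative, true negative); their sum must be positive.
#' @return An object of class `vte_cm`.
#' @export
#' @examples
#' vte_confusion(563, 55, 63, 29471)
vte_confusion <- function(tp, fp, fn, tn) {
  counts <- c(tp = tp, fp = fp, fn = fn, tn = tn)
  if (any(is.na(counts)) || any(counts < 0) || any(counts != round(counts))) {
    stop("confusion-matrix cells must be non-negative integers", call. = FALSE)
  }
  if (sum(counts) <= 0) stop("confusion matrix must have n > 0", call. = FALSE)
  structure(as.list(counts), class = "vte_cm")
}

#' @export
print.vte_cm <- function(x, ...) {
  n <- x$tp + x$fp + x$fn + x$tn
  cat(sprintf("<2x2 confusion matrix, n = %d>\n", n))
  m <- matrix(c(x$tp, x$fn, x$fp, x$tn), 2, 2,
              dimnames = list(c("detector +", "detector -"),
                              c("reference +", "reference -")))
  print(m)
  invisible(x)
}

#' Cross-tabulate predictions against reference labels
#'
#' Aligns the two tables on `patient_id` (the id sets must coincide) and
#' counts the 2x2 cells for the chosen outcome column.
#'
#' @param predictions Data frame with `patient_id` and a logical outcome
#'   column (e.g. the output of [detect_corpus()]).
#' @param reference Data frame with `patient_id` and the same outcome
#'   column (e.g. [read_reference_labels()]).
#' @param outcome Outcome column name; default `"vte_any"`.
#' @return An object of class `vte_cm`.
#' @export
confusion_matrix <- function(predictions, reference, outcome = "vte_any") {
  missing_ref <- setdiff(predictions$patient_id, reference$patient_id)
  missing_pred <- setdiff(reference$patient_id, predictions$patient_id)
  if (length(missing_ref) || length(missing_pred)) {
    stop("patient_id mismatch; missing from reference: ",
         paste(utils::head(missing_ref, 5), collapse = ", "),
         "; missing from predictions: ",
         paste(utils::head(missing_pred, 5), collapse = ", "), call. = FALSE)
  }
  pred <- predictions[[outcome]][match(reference$patient_id, predictions$patient_id)]
  ref <- reference[[outcome]]
  if (anyNA(pred) || anyNA(ref)) {
    stop("NA outcome values; resolve per-record errors before evaluation",
         call. = FALSE)
  }
  vte_confusion(sum(pred & ref), sum(pred & !ref), sum(!pred & ref),
                sum(!pred & !ref))
}

#' Confidence interval for a binomial proportion
#'
#' The default is the exact Clopper-Pearson interval, which reproduces
#' printed clinical-report intervals such as a sensitivity of 563/626 =
#' 89.9% (95% CI 87.3%-92.2%); the Wilson score interval is available as an
#' alternative.
#'
#' @param k Number of successes, `0 <= k <= n`.
#' @param n Number of trials, `n > 0`.
#' @param level Confidence level, default 0.95.
#' @param method `"clopper-pearson"` (default) or `"wilson"`.
#' @return Numeric vector `c(lower, upper)` with
#'   `0 <= lower <= k/n <= upper <= 1`.
#' @export
#' @examples
#' proportion_ci(563, 626)
proportion_ci <- function(k, n, level = 0.95,
                          method = c("clopper-pearson", "wilson")) {
  method <- match.arg(method)
  if (is.na(n) || n <= 0) stop("n must be positive", call. = FALSE)
  if (is.na(k) || k < 0 || k > n) stop("k must satisfy 0 <= k <= n", call. = FALSE)
  alpha <- 1 - level
  if (method == "clopper-pearson") {
    lower <- if (k == 0) 0 else stats::qbeta(alpha / 2, k, n - k + 1)
    upper <- if (k == n) 1 else stats::qbeta(1 - alpha / 2, k + 1, n - k)
  } else {
    z <- stats::qnorm(1 - alpha / 2)
    p <- k / n
    denom <- 1 + z^2 / n
    centre <- (p + z^2 / (2 * n)) / denom
    half <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / denom
    lower <- max(0, centre - half)
    upper <- min(1, centre + half)
  }
  c(lower = lower, upper = upper)
}

# run expr under a fixed RNG seed, restoring the caller's RNG state
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_seed) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

lr_point <- function(cm, which) {
  sens <- cm$tp / (cm$tp + cm$fn)
  spec <- cm$tn / (cm$tn + cm$fp)
  if (which == "pos") sens / (1 - spec) else (1 - sens) / spec
}

# delta-method variance of log LR (Simel-style): each LR is a ratio of two
# independent binomial proportions
lr_log_var <- function(cm, which) {
  if (which == "pos") {
    (1 / cm$tp - 1 / (cm$tp + cm$fn)) + (1 / cm$fp - 1 / (cm$fp + cm$tn))
  } else {
    (1 / cm$fn - 1 / (cm$tp + cm$fn)) + (1 / cm$tn - 1 / (cm$fp + cm$tn))
  }
}

#' Log-method confidence interval for a likelihood ratio
#'
#' Delta-method interval on the log scale for the positive
#' (`sens / (1 - spec)`) or negative (`(1 - sens) / spec`) likelihood
#' ratio. Requires the LR's defining cells to be non-zero: with a zero cell
#' the log-variance is undefined and [bootstrap_lr_ci()] must be used (this
#' function then raises a condition saying so).
#'
#' @param cm A `vte_cm` confusion matrix.
#' @param which `"pos"` or `"neg"`.
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)` containing the point estimate.
#' @export
#' @examples
#' lr_ci(vte_confusion(563, 55, 63, 29471), "pos")  # ~ (370, 629)
lr_ci <- function(cm, which = c("pos", "neg"), level = 0.95) {
  which <- match.arg(which)
  cells <- if (which == "pos") c(cm$tp, cm$fp) else c(cm$fn, cm$tn)
  if (any(cells == 0)) {
    stop("zero cell in the likelihood ratio's defining cells; ",
         "use bootstrap_lr_ci()", call. = FALSE)
  }
  est <- lr_point(cm, which)
  z <- stats::qnorm(1 - (1 - level) / 2)
  half <- z * sqrt(lr_log_var(cm, which))
  c(lower = est * exp(-half), upper = est * exp(half))
}

#' Bootstrap percentile interval for a likelihood ratio
#'
#' Resamples the two margins of the 2x2 (disease-positive and
#' disease-negative rows) independently and takes percentile bounds of the
#' resampled likelihood ratios. The margins are drawn from their Jeffreys
#' posteriors (Beta(k + 1/2, n - k + 1/2)), a smoothed parametric
#' bootstrap, so the interval is defined even when a cell is zero - in
#' particular for the negative LR of a detector with 100% sensitivity,
#' where the lower bound is 0 at the reported precision and the upper
#' bound stays positive.
#'
#' @param cm A `vte_cm` confusion matrix.
#' @param which `"pos"` or `"neg"`.
#' @param reps Number of bootstrap replicates (at least 1000); default 2000.
#' @param seed Integer seed; the interval is reproducible given the seed.
#' @param level Confidence level, default 0.95.
#' @return Numeric vector `c(lower, upper)`.
#' @export
bootstrap_lr_ci <- function(cm, which = c("pos", "neg"), reps = 2000,
                            seed = 1, level = 0.95) {
  which <- match.arg(which)
  if (reps < 1000) stop("reps must be at least 1000", call. = FALSE)
  npos <- cm$tp + cm$fn
  nneg <- cm$fp + cm$tn
  if (npos == 0 || nneg == 0) {
    stop("both margins must be non-empty for the bootstrap", call. = FALSE)
  }
  with_seed(seed, {
    sens_b <- stats::rbeta(reps, cm$tp + 0.5, cm$fn + 0.5)
    fpr_b <- stats::rbeta(reps, cm$fp + 0.5, cm$tn + 0.5)
    lr_b <- if (which == "pos") sens_b / fpr_b else (1 - sens_b) / (1 - fpr_b)
    qs <- stats::quantile(lr_b, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    c(lower = qs[1], upper = qs[2])
  })
}

#' Cohen's kappa with a large-sample confidence interval
#'
#' Chance-corrected agreement on the 2x2 between detector and reference,
#' with the large-sample standard error
#' `sqrt(po (1 - po) / n) / (1 - pe)` and a normal interval truncated to
#' `[-1, 1]`. Degenerate margins (all observations in one class for either
#' rater) leave kappa undefined.
#'
#' @param cm A `vte_cm` confusion matrix.
#' @param level Confidence level, default 0.95.
#' @return List with `kappa`, `lower`, `upper`, `se`, and `note` (empty
#'   string, or the reason kappa is undefined).
#' @export
#' @examples
#' kappa_ci(vte_confusion(563, 55, 63, 29471))  # kappa ~ 0.90
kappa_ci <- function(cm, level = 0.95) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  row_pos <- cm$tp + cm$fp   # detector positive
  col_pos <- cm$tp + cm$fn   # reference positive
  if (row_pos %in% c(0, n) && col_pos %in% c(0, n)) {
    return(list(kappa = NA_real_, lower = NA_real_, upper = NA_real_,
                se = NA_real_, note = "undefined: degenerate margins"))
  }
  po <- (cm$tp + cm$tn) / n
  pe <- (row_pos * col_pos + (n - row_pos) * (n - col_pos)) / n^2
  if (pe == 1) {
    return(list(kappa = NA_real_, lower = NA_real_, upper = NA_real_,
                se = NA_real_, note = "undefined: expected agreement is 1"))
  }
  kappa <- (po - pe) / (1 - pe)
  se <- sqrt(po * (1 - po) / n) / (1 - pe)
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(kappa = kappa,
       lower = max(-1, kappa - z * se),
       upper = min(1, kappa + z * se),
       se = se, note = "")
}

f1_from_cells <- function(tp, fp, fn) {
  denom <- 2 * tp + fp + fn
  if (denom == 0) return(NA_real_)
  2 * tp / denom
}

# percentile bootstrap CI for F1 by multinomial resampling of the 2x2
f1_boot_ci <- function(cm, reps = 2000, seed = 1, level = 0.95) {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  probs <- c(cm$tp, cm$fp, cm$fn, cm$tn) / n
  with_seed(seed, {
    draws <- stats::rmultinom(reps, n, probs)
    f1_b <- 2 * draws[1, ] / (2 * draws[1, ] + draws[2, ] + draws[3, ])
    qs <- stats::quantile(f1_b, c((1 - level) / 2, 1 - (1 - level) / 2),
                          na.rm = TRUE, names = FALSE)
    c(lower = qs[1], upper = qs[2])
  })
}

#' Full diagnostic report for a 2x2 confusion matrix
#'
#' Computes sensitivity, specificity, PPV, NPV, the positive and negative
#' likelihood ratios, AUC, F1-score, Cohen's kappa, and prevalence, each
#' with a 95% confidence interval:
#' \itemize{
#'   \item proportions: [proportion_ci()] (exact by default);
#'   \item likelihood ratios: log-method [lr_ci()], falling back to
#'     [bootstrap_lr_ci()] when a defining cell is zero (flagged);
#'   \item AUC: for a binary detector the ROC curve has a single operating
#'     point, so AUC = (sensitivity + specificity) / 2, with a delta-method
#'     interval from the two independent binomial variances;
#'   \item F1: percentile bootstrap over multinomial resamples of the table;
#'   \item kappa: [kappa_ci()].
#' }
#' Metrics with a zero denominator are reported as undefined (`NA` with a
#' note), never dropped and never an exception.
#'
#' @param cm A `vte_cm` confusion matrix.
#' @param level Confidence level, default 0.95.
#' @param boot_reps Bootstrap replicates for the F1 interval (and LR
#'   fallback); default 2000.
#' @param seed Seed for the bootstrap components; default 1.
#' @param ci_method Proportion CI method, see [proportion_ci()].
#' @return An object of class `vte_report`: a data frame with columns
#'   `metric`, `estimate`, `lower`, `upper`, `note`, plus the confusion
#'   matrix in attribute `"cm"`.
#' @export
#' @examples
#' diagnostic_metrics(vte_confusion(563, 55, 63, 29471))
diagnostic_metrics <- function(cm, level = 0.95, boot_reps = 2000, seed = 1,
                               ci_method = "clopper-pearson") {
  n <- cm$tp + cm$fp + cm$fn + cm$tn
  rows <- list()
  add <- function(metric, estimate, lower, upper, note = "") {
    rows[[length(rows) + 1L]] <<- data.frame(
      metric = metric, estimate = estimate, lower = lower, upper = upper,
      note = note, stringsAsFactors = FALSE)
  }
  prop_row <- function(metric, k, nn) {
    if (nn == 0) {
      add(metric, NA_real_, NA_real_, NA_real_, "undefined: zero denominator")
    } else {
      ci <- proportion_ci(k, nn, level, ci_method)
      add(metric, k / nn, ci[["lower"]], ci[["upper"]])
    }
  }
  prop_row("sensitivity", cm$tp, cm$tp + cm$fn)
  prop_row("specificity", cm$tn, cm$tn + cm$fp)
  prop_row("ppv", cm$tp, cm$tp + cm$fp)
  prop_row("npv", cm$tn, cm$tn + cm$fn)

  lr_row <- function(metric, which) {
    est <- lr_point(cm, which)
    if (!is.finite(est)) {
      add(metric, NA_real_, NA_real_, NA_real_,
          "undefined: zero denominator (perfect separation)")
      return(invisible())
    }
    cells <- if (which == "pos") c(cm$tp, cm$fp) else c(cm$fn, cm$tn)
    if (any(cells == 0)) {
      ci <- bootstrap_lr_ci(cm, which, reps = boot_reps, seed = seed,
                            level = level)
      add(metric, est, ci[["lower"]], ci[["upper"]], "bootstrap CI (zero cell)")
    } else {
      ci <- lr_ci(cm, which, level)
      add(metric, est, ci[["lower"]], ci[["upper"]])
    }
  }
  lr_row("lr_pos", "pos")
  lr_row("lr_neg", "neg")

  npos <- cm$tp + cm$fn
  nneg <- cm$fp + cm$tn
  if (npos == 0 || nneg == 0) {
    add("auc", NA_real_, NA_real_, NA_real_, "undefined: one-class reference")
  } else {
    sens <- cm$tp / npos
    spec <- cm$tn / nneg
    auc <- (sens + spec) / 2
    se <- sqrt(sens * (1 - sens) / npos + spec * (1 - spec) / nneg) / 2
    z <- stats::qnorm(1 - (1 - level) / 2)
    add("auc", auc, max(0, auc - z * se), min(1, auc + z * se))
  }

  f1 <- f1_from_cells(cm$tp, cm$fp, cm$fn)
  if (is.na(f1)) {
    add("f1", NA_real_, NA_real_, NA_real_, "undefined: no positives anywhere")
  } else {
    ci <- f1_boot_ci(cm, reps = boot_reps, seed = seed, level = level)
    add("f1", f1, ci[["lower"]], ci[["upper"]], "bootstrap CI")
  }

  kp <- kappa_ci(cm, level)
  add("kappa", kp$kappa, kp$lower, kp$upper, kp$note)
  prop_row("prevalence", cm$tp + cm$fn, n)

  out <- do.call(rbind, rows)
  attr(out, "cm") <- cm
  attr(out, "n") <- n
  class(out) <- c("vte_report", "data.frame")
  out
}

#' Look up one metric from a diagnostic report
#'
#' @param report A `vte_report`.
#' @param metric Metric name, e.g. `"sensitivity"`.
#' @return Named numeric vector `c(estimate, lower, upper)`.
#' @export
report_metric <- function(report, metric) {
  i <- match(metric, report$metric)
  if (is.na(i)) stop("unknown metric '", metric, "'", call. = FALSE)
  c(estimate = report$estimate[i], lower = report$lower[i],
    upper = report$upper[i])
}

#' @export
print.vte_report <- function(x, digits = 3, ...) {
  cm <- attr(x, "cm")
  cat(sprintf("Diagnostic report (n = %d; TP %d, FP %d, FN %d, TN %d)\n",
              attr(x, "n"), cm$tp, cm$fp, cm$fn, cm$tn))
  pct <- c("sensitivity", "specificity", "ppv", "npv", "prevalence")
  for (i in seq_len(nrow(x))) {
    if (is.na(x$estimate[i])) {
      cat(sprintf("  %-11s %s\n", x$metric[i], x$note[i]))
    } else if (x$metric[i] %in% pct) {
      cat(sprintf("  %-11s %5.1f%% (95%% CI %.1f%%-%.1f%%)\n", x$metric[i],
                  100 * x$estimate[i], 100 * x$lower[i], 100 * x$upper[i]))
    } else {
      cat(sprintf("  %-11s %s (95%% CI %s-%s)\n", x$metric[i],
                  signif(x$estimate[i], digits), signif(x$lower[i], digits),
                  signif(x$upper[i], digits)))
    }
  }
  invisible(x)
}
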