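# Hypothesis tests for comparing detectors and strata: the DeLong test on
# AUCs (fast placement-value implementation), a bootstrap-SE z test on F1
# differences, the relative diagnostic likelihood ratio test for comparing
# the LRs of two independent strata, chi-square / Fisher selection for
# categorical tables, and Bonferroni adjustment.

# placement values and AUC for one score vector (rank-based, tie-aware)
delong_placements <- function(scores, ref) {
  pos <- scores[ref]
  neg <- scores[!ref]
  m <- length(pos)
  n <- length(neg)
  r_all <- rank(c(pos, neg), ties.method = "average")
  r_pos <- rank(pos, ties.method = "average")
  r_neg <- rank(neg, ties.method = "average")
  v10 <- (r_all[seq_len(m)] - r_pos) / n
  v01 <- 1 - (r_all[m + seq_len(n)] - r_neg) / m
  list(auc = mean(v10), v10 = v10, v01 = v01, m = m, n = n)
}

#' DeLong test for comparing two AUCs
#'
#' Nonparametric comparison of the areas under two ROC curves via the
#' placement-value (structural components) covariance estimate. With a
#' single reference (`reference_b = NULL`) the predictions are paired on
#' the same patients and the covariance between the two AUCs is used; with
#' a second reference the strata are treated as independent and the
#' variances are summed with zero covariance. Binary predictions are
#' handled as two-point scores (ties contribute 1/2).
#'
#' @param pred_a,pred_b Numeric or logical prediction vectors.
#' @param reference Logical reference labels for `pred_a` (and for
#'   `pred_b` when paired).
#' @param reference_b Optional logical reference for `pred_b` (unpaired
#'   comparison of two strata).
#' @return List with `auc_a`, `auc_b`, `z`, `p` (two-sided).
#' @export
#' @examples
#' set.seed(1)
#' ref <- c(rep(TRUE, 20), rep(FALSE, 80))
#' delong_test(ref, ref, ref)$p  # identical classifiers: p = 1
delong_test <- function(pred_a, pred_b, reference, reference_b = NULL) {
  # a single positive (or negative) contributes no variance information
  safe_var <- function(x) if (length(x) < 2L) 0 else stats::var(x)
  safe_cov <- function(m) if (nrow(m) < 2L) matrix(0, 2, 2) else stats::cov(m)
  reference <- as.logical(reference)
  check_ref <- function(ref) {
    if (!any(ref) || all(ref)) {
      stop("reference must contain both classes", call. = FALSE)
    }
  }
  check_ref(reference)
  a <- delong_placements(as.numeric(pred_a), reference)
  if (is.null(reference_b)) {
    if (length(pred_b) != length(pred_a)) {
      stop("paired predictions must have equal length", call. = FALSE)
    }
    b <- delong_placements(as.numeric(pred_b), reference)
    s10 <- safe_cov(cbind(a$v10, b$v10))
    s01 <- safe_cov(cbind(a$v01, b$v01))
    var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / a$m +
      (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / a$n
  } else {
    reference_b <- as.logical(reference_b)
    check_ref(reference_b)
    b <- delong_placements(as.numeric(pred_b), reference_b)
    var_a <- safe_var(a$v10) / a$m + safe_var(a$v01) / a$n
    var_b <- safe_var(b$v10) / b$m + safe_var(b$v01) / b$n
    var_diff <- var_a + var_b
  }
  diff <- a$auc - b$auc
  z <- if (var_diff <= 0) {
    if (diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / sqrt(var_diff)
  }
  list(auc_a = a$auc, auc_b = b$auc, z = z, p = 2 * stats::pnorm(-abs(z)))
}

f1_score <- function(pred, ref) {
  f1_from_cells(sum(pred & ref), sum(pred & !ref), sum(!pred & ref))
}

#' Bootstrap z test for comparing two F1-scores
#'
#' Two-sided z test on the F1 difference, with the standard error estimated
#' by bootstrap. Paired (`reference_b = NULL`): patients are resampled
#' jointly and the SE of the within-replicate F1 differences is used.
#' Unpaired: each stratum is resampled separately and the variances summed.
#'
#' @param pred_a,pred_b Logical prediction vectors.
#' @param reference Logical reference for `pred_a` (and `pred_b` if paired).
#' @param reference_b Optional logical reference for `pred_b` (unpaired).
#' @param reps Bootstrap replicates (at least 1000); default 2000.
#' @param seed Integer seed; the p-value is reproducible given the seed.
#' @return List with `f1_a`, `f1_b`, `z`, `p` (two-sided).
#' @export
f1_z_test <- function(pred_a, pred_b, reference, reference_b = NULL,
                      reps = 2000, seed = 1) {
  if (reps < 1000) stop("reps must be at least 1000", call. = FALSE)
  pred_a <- as.logical(pred_a)
  pred_b <- as.logical(pred_b)
  reference <- as.logical(reference)
  f1_a <- f1_score(pred_a, reference)
  paired <- is.null(reference_b)
  f1_b <- if (paired) f1_score(pred_b, reference) else {
    f1_score(pred_b, as.logical(reference_b))
  }
  diff <- f1_a - f1_b
  se <- with_seed(seed, {
    if (paired) {
      n <- length(reference)
      diffs <- vapply(seq_len(reps), function(r) {
        idx <- sample.int(n, n, replace = TRUE)
        f1_score(pred_a[idx], reference[idx]) -
          f1_score(pred_b[idx], reference[idx])
      }, numeric(1))
      stats::sd(diffs, na.rm = TRUE)
    } else {
      ref_b <- as.logical(reference_b)
      boot_one <- function(pred, ref) {
        n <- length(ref)
        vapply(seq_len(reps), function(r) {
          idx <- sample.int(n, n, replace = TRUE)
          f1_score(pred[idx], ref[idx])
        }, numeric(1))
      }
      sqrt(stats::var(boot_one(pred_a, reference), na.rm = TRUE) +
             stats::var(boot_one(pred_b, ref_b), na.rm = TRUE))
    }
  })
  z <- if (is.na(se) || se == 0) {
    if (isTRUE(all.equal(diff, 0)) || diff == 0) 0 else sign(diff) * Inf
  } else {
    diff / se
  }
  list(f1_a = f1_a, f1_b = f1_b, z = z, p = 2 * stats::pnorm(-abs(z)))
}

#' Relative diagnostic likelihood ratio test
#'
#' Compares the positive or negative likelihood ratios of two diagnostic
#' 2x2 tables from independent strata: the ratio of LRs with a delta-method
#' confidence interval on the log scale and a two-sided z test of
#' `ratio = 1`. When a defining cell of either table is zero the
#' delta-method variance is undefined and a bootstrap of both tables'
#' binomial margins is used instead (flagged in `method`).
#'
#' @param cm_a,cm_b `vte_cm` confusion matrices of two independent strata.
#' @param which `"pos"` or `"neg"`.
#' @param level Confidence level, default 0.95.
#' @param reps,seed Bootstrap parameters for the zero-cell fallback.
#' @return List with `ratio`, `lower`, `upper`, `z`, `p`, `method`.
#' @export
relative_dlr_test <- function(cm_a, cm_b, which = c("pos", "neg"),
                              level = 0.95, reps = 2000, seed = 1) {
  which <- match.arg(which)
  cells <- function(cm) if (which == "pos") c(cm$tp, cm$fp) else c(cm$fn, cm$tn)
  z_crit <- stats::qnorm(1 - (1 - level) / 2)
  if (any(cells(cm_a) == 0) || any(cells(cm_b) == 0)) {
    # Jeffreys-smoothed margin resampling keeps the ratio finite even when a
    # point LR is 0 or infinite; the p-value comes from the percentile
    # position of ratio = 1 in the bootstrap distribution
    boot_lr <- function(cm) {
      sens_b <- stats::rbeta(reps, cm$tp + 0.5, cm$fn + 0.5)
      fpr_b <- stats::rbeta(reps, cm$fp + 0.5, cm$tn + 0.5)
      if (which == "pos") sens_b / fpr_b else (1 - sens_b) / (1 - fpr_b)
    }
    res <- with_seed(seed, {
      r_b <- boot_lr(cm_a) / boot_lr(cm_b)
      r_b <- r_b[is.finite(r_b) & r_b > 0]
      tail_p <- min(mean(r_b <= 1), mean(r_b >= 1))
      p <- min(1, 2 * max(tail_p, 1 / (length(r_b) + 1)))
      list(p = p, med = stats::median(r_b),
           qs = stats::quantile(r_b, c((1 - level) / 2, 1 - (1 - level) / 2),
                                names = FALSE))
    })
    ratio <- lr_point(cm_a, which) / lr_point(cm_b, which)
    if (!is.finite(ratio) || is.nan(ratio)) ratio <- res$med
    z <- sign(log(res$med)) * stats::qnorm(1 - res$p / 2)
    return(list(ratio = ratio, lower = res$qs[1], upper = res$qs[2], z = z,
                p = res$p, method = "bootstrap (zero cell)"))
  }
  log_ratio <- log(lr_point(cm_a, which)) - log(lr_point(cm_b, which))
  se <- sqrt(lr_log_var(cm_a, which) + lr_log_var(cm_b, which))
  z <- if (se == 0) {
    if (log_ratio == 0) 0 else sign(log_ratio) * Inf
  } else {
    log_ratio / se
  }
  list(ratio = exp(log_ratio),
       lower = exp(log_ratio - z_crit * se),
       upper = exp(log_ratio + z_crit * se),
       z = z, p = 2 * stats::pnorm(-abs(z)), method = "delta")
}

#' Chi-square or Fisher exact test for a contingency table
#'
#' Applies the Pearson chi-square test (no continuity correction, the
#' convention of clinical baseline-characteristics tables) unless any
#' expected cell count is below 5, in which case the Fisher exact test is
#' selected. The method actually used is reported.
#'
#' @param table An r x c matrix of non-negative counts.
#' @return List with `statistic` (`NA` for Fisher), `p`, `method`.
#' @export
#' @examples
#' categorical_test(matrix(c(286, 13961, 340, 15565), 2))
categorical_test <- function(table) {
  table <- as.matrix(table)
  if (length(table) == 0 || sum(table) == 0) {
    stop("empty contingency table", call. = FALSE)
  }
  if (any(table < 0)) stop("counts must be non-negative", call. = FALSE)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5)) {
    res <- stats::fisher.test(table)
    list(statistic = NA_real_, p = res$p.value, method = "fisher")
  } else {
    res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
    list(statistic = unname(res$statistic), p = res$p.value,
         method = "chi-square")
  }
}

#' Bonferroni threshold and p-value adjustment
#'
#' `bonferroni()` returns the per-comparison significance threshold
#' `alpha / m`; `bonferroni_adjust()` returns `min(1, p * m)` per p-value.
#'
#' @param alpha Family-wise significance level.
#' @param m Number of comparisons, at least 1.
#' @return `bonferroni()`: a single threshold.
#' @export
#' @examples
#' bonferroni(0.01, 3)  # 0.00333..., printed as .003
bonferroni <- function(alpha, m) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  alpha / m
}

#' @param pvalues Numeric vector of p-values.
#' @rdname bonferroni
#' @return `bonferroni_adjust()`: adjusted p-values, capped at 1.
#' @export
bonferroni_adjust <- function(pvalues, m = length(pvalues)) {
  if (m < 1) stop("m must be at least 1", call. = FALSE)
  pmin(1, pvalues * m)
}

#' Format a p-value in clinical-report style
#'
#' No leading zero; two decimals at or above 0.01, three decimals below
#' that, and `<.001` below 0.001.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector, e.g. `".43"`, `".003"`, `"<.001"`.
#' @export
format_pvalue <- function(p) {
  out <- ifelse(p < 0.001, "<.001",
                ifelse(p < 0.01, sub("^0", "", sprintf("%.3f", p)),
                       sub("^0", "", sprintf("%.2f", p))))
  out[is.na(p)] <- NA_character_
  out
}
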