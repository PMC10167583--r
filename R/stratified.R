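# Subgroup evaluation: one diagnostic report per stratum of a grouping
# (age band, sex, department class, VTE-risk tier, or study quarter), plus
# pairwise between-stratum comparisons - relative DLR tests for the
# likelihood ratios, unpaired DeLong for AUC, bootstrap z for F1 - with
# Bonferroni adjustment across the pairs of each metric family.

STRATA_GROUPINGS <- c("none", "age", "sex", "department", "risk", "quarter")

record_stratum <- function(rec, grouping) {
  switch(grouping,
    none = "overall",
    age = if (rec$age > 65) "age >65" else "age <=65",
    sex = rec$sex,
    department = rec$department_class,
    risk = paste0(rec$vte_risk_tier, " risk"),
    quarter = {
      t <- parse_timestamp(rec$admission_time)
      paste0("Q", (as.integer(format(t, "%m")) - 1) %/% 3 + 1)
    },
    stop("unknown grouping '", grouping, "'; use one of: ",
         paste(STRATA_GROUPINGS, collapse = ", "), call. = FALSE)
  )
}

#' Stratified diagnostic evaluation with pairwise comparisons
#'
#' Splits the cohort by the requested grouping, computes a full
#' [diagnostic_metrics()] report per stratum, and compares every pair of
#' usable strata: positive and negative likelihood ratios with
#' [relative_dlr_test()], AUC with the unpaired [delong_test()], and F1
#' with the unpaired [f1_z_test()]. P-values are Bonferroni-adjusted across
#' the pairs within each metric. Strata whose 2x2 lacks a reference class
#' (no positives or no negatives) are reported but flagged and excluded
#' from comparisons.
#'
#' @param records List of `vte_record` objects (defines the strata).
#' @param predictions Prediction table from [detect_corpus()].
#' @param reference Reference labels from [read_reference_labels()].
#' @param grouping One of `"none"`, `"age"` (over/under 65), `"sex"`,
#'   `"department"` (class), `"risk"` (VTE-risk tier), `"quarter"`.
#' @param outcome Outcome column, default `"vte_any"`.
#' @param boot_reps,seed Bootstrap parameters for F1 comparisons and
#'   zero-cell fallbacks.
#' @return An object of class `vte_strat_eval`: list with `grouping`,
#'   `strata` (one metrics row per stratum), `comparisons` (pairwise tests
#'   with raw, adjusted, and formatted p-values), and `reports` (the named
#'   list of per-stratum `vte_report` objects).
#' @export
stratified_evaluate <- function(records, predictions, reference,
                                grouping = "none", outcome = "vte_any",
                                boot_reps = 1000, seed = 1) {
  grouping <- match.arg(grouping, STRATA_GROUPINGS)
  ids <- vapply(records, `[[`, character(1), "patient_id")
  strata <- vapply(records, record_stratum, character(1), grouping = grouping)
  pred <- predictions[[outcome]][match(ids, predictions$patient_id)]
  ref <- reference[[outcome]][match(ids, reference$patient_id)]
  if (anyNA(pred) || anyNA(ref)) {
    stop("records, predictions and reference must cover the same patients",
         call. = FALSE)
  }

  levels_order <- sort(unique(strata))
  reports <- list()
  rows <- list()
  usable <- character(0)
  for (s in levels_order) {
    in_s <- strata == s
    cm <- vte_confusion(sum(pred[in_s] & ref[in_s]),
                        sum(pred[in_s] & !ref[in_s]),
                        sum(!pred[in_s] & ref[in_s]),
                        sum(!pred[in_s] & !ref[in_s]))
    rep_s <- diagnostic_metrics(cm, boot_reps = boot_reps, seed = seed)
    reports[[s]] <- rep_s
    ok <- (cm$tp + cm$fn) > 0 && (cm$fp + cm$tn) > 0
    if (ok) usable <- c(usable, s)
    row <- data.frame(stratum = s, n = sum(in_s), tp = cm$tp, fp = cm$fp,
                      fn = cm$fn, tn = cm$tn, comparable = ok,
                      stringsAsFactors = FALSE)
    for (i in seq_len(nrow(rep_s))) {
      row[[rep_s$metric[i]]] <- rep_s$estimate[i]
      row[[paste0(rep_s$metric[i], "_lower")]] <- rep_s$lower[i]
      row[[paste0(rep_s$metric[i], "_upper")]] <- rep_s$upper[i]
    }
    rows[[length(rows) + 1L]] <- row
  }
  strata_df <- do.call(rbind, rows)

  comparisons <- list()
  if (length(usable) >= 2L) {
    pairs <- utils::combn(usable, 2, simplify = FALSE)
    m <- length(pairs)
    for (pair in pairs) {
      a <- pair[1]; b <- pair[2]
      in_a <- strata == a; in_b <- strata == b
      cm_of <- function(in_s) {
        vte_confusion(sum(pred[in_s] & ref[in_s]), sum(pred[in_s] & !ref[in_s]),
                      sum(!pred[in_s] & ref[in_s]), sum(!pred[in_s] & !ref[in_s]))
      }
      cm_a <- cm_of(in_a); cm_b <- cm_of(in_b)
      add_cmp <- function(metric, est_a, est_b, statistic, p) {
        comparisons[[length(comparisons) + 1L]] <<- data.frame(
          metric = metric, stratum_a = a, stratum_b = b,
          estimate_a = est_a, estimate_b = est_b,
          statistic = statistic, p = p, m = m, stringsAsFactors = FALSE)
      }
      for (which in c("pos", "neg")) {
        res <- tryCatch(relative_dlr_test(cm_a, cm_b, which,
                                          reps = max(boot_reps, 1000),
                                          seed = seed),
                        error = function(e) NULL)
        if (!is.null(res)) {
          add_cmp(paste0("lr_", which), lr_point(cm_a, which),
                  lr_point(cm_b, which), res$ratio, res$p)
        }
      }
      dl <- delong_test(pred[in_a], pred[in_b], ref[in_a], ref[in_b])
      add_cmp("auc", dl$auc_a, dl$auc_b, dl$z, dl$p)
      fz <- f1_z_test(pred[in_a], pred[in_b], ref[in_a], ref[in_b],
                      reps = max(boot_reps, 1000), seed = seed)
      add_cmp("f1", fz$f1_a, fz$f1_b, fz$z, fz$p)
    }
  }
  comparisons_df <- if (length(comparisons)) {
    df <- do.call(rbind, comparisons)
    df$p_adjusted <- bonferroni_adjust(df$p, m = df$m[1])
    df$p_formatted <- format_pvalue(df$p_adjusted)
    df$m <- NULL
    df
  } else {
    data.frame(metric = character(0), stratum_a = character(0),
               stratum_b = character(0), estimate_a = numeric(0),
               estimate_b = numeric(0), statistic = numeric(0),
               p = numeric(0), p_adjusted = numeric(0),
               p_formatted = character(0), stringsAsFactors = FALSE)
  }

  structure(
    list(grouping = grouping, strata = strata_df,
         comparisons = comparisons_df, reports = reports),
    class = "vte_strat_eval"
  )
}

#' @export
print.vte_strat_eval <- function(x, ...) {
  cat(sprintf("Stratified evaluation by '%s' (%d stratum/strata)\n",
              x$grouping, nrow(x$strata)))
  show <- c("stratum", "n", "sensitivity", "specificity", "lr_pos", "lr_neg",
            "auc", "f1", "kappa")
  print(format(x$strata[, intersect(show, names(x$strata))], digits = 3),
        row.names = FALSE)
  if (nrow(x$comparisons)) {
    cat("\nPairwise comparisons (Bonferroni-adjusted):\n")
    print(format(x$comparisons[, c("metric", "stratum_a", "stratum_b",
                                   "p_formatted")]),
          row.names = FALSE)
  }
  invisible(x)
}

#' Write a stratified evaluation report to disk
#'
#' Writes the per-stratum metric table (and, when present, the pairwise
#' comparison table) as tab-separated values, plus a machine-readable JSON
#' twin of the whole object.
#'
#' @param eval A `vte_strat_eval` from [stratified_evaluate()].
#' @param tsv_path Output TSV path.
#' @param json_path Optional JSON path (default: `tsv_path` with a `.json`
#'   extension).
#' @return `tsv_path`, invisibly.
#' @export
write_evaluation_report <- function(eval, tsv_path, json_path = NULL) {
  if (is.null(json_path)) json_path <- sub("\\.tsv$", ".json", tsv_path)
  if (identical(json_path, tsv_path)) json_path <- paste0(tsv_path, ".json")
  con <- file(tsv_path, "w", encoding = "UTF-8")
  utils::write.table(eval$strata, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  if (nrow(eval$comparisons)) {
    writeLines("", con)
    utils::write.table(eval$comparisons, con, sep = "\t", row.names = FALSE,
                       quote = FALSE)
  }
  close(con)
  jsonlite::write_json(
    list(grouping = eval$grouping, strata = eval$strata,
         comparisons = eval$comparisons),
    json_path, auto_unbox = TRUE, digits = NA, na = "null")
  invisible(tsv_path)
}
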