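# records for stratified tests are built directly (no NLP involved):
# stratified_evaluate only needs stratum metadata and id alignment
mock_cohort <- function(n, dept, sens, spec, prev, seed, quarter_month = 3,
                        age = 60) {
  set.seed(seed)
  ids <- sprintf("%s-%04d", dept, seq_len(n))
  truth <- stats::runif(n) < prev
  pred <- ifelse(truth, stats::runif(n) < sens, stats::runif(n) > spec)
  records <- lapply(seq_len(n), function(i) {
    vtenlp:::new_record(
      ids[i],
      sprintf("2021-%02d-10T08:00:00", quarter_month),
      sprintf("2021-%02d-20T08:00:00", quarter_month),
      department = dept, department_class = dept,
      vte_risk_tier = switch(dept, surgery = "low", icu = "high",
                             "intermediate"),
      age = age, sex = if (i %% 2 == 0) "female" else "male",
      documents = list())
  })
  list(records = records,
       predictions = data.frame(patient_id = ids, vte_any = pred,
                                stringsAsFactors = FALSE),
       reference = data.frame(patient_id = ids, vte_any = truth,
                              stringsAsFactors = FALSE))
}

bind_cohorts <- function(...) {
  parts <- list(...)
  list(records = do.call(c, lapply(parts, `[[`, "records")),
       predictions = do.call(rbind, lapply(parts, `[[`, "predictions")),
       reference = do.call(rbind, lapply(parts, `[[`, "reference")))
}

test_that("strata are formed per grouping and reports cover each stratum", {
  co <- bind_cohorts(
    mock_cohort(800, "surgery", 0.95, 0.999, 0.02, 51, quarter_month = 2),
    mock_cohort(900, "internal_medicine", 0.88, 0.995, 0.03, 52,
                quarter_month = 5),
    mock_cohort(300, "icu", 0.9, 0.99, 0.14, 53, quarter_month = 11))
  res <- stratified_evaluate(co$records, co$predictions, co$reference,
                             grouping = "department")
  expect_s3_class(res, "vte_strat_eval")
  expect_equal(nrow(res$strata), 3)
  expect_equal(sum(res$strata$n), 2000)
  # 3 usable strata -> 3 pairs x 4 metric families
  expect_equal(nrow(res$comparisons), 12)
  expect_true(all(res$comparisons$p_adjusted >= res$comparisons$p - 1e-12))

  by_quarter <- stratified_evaluate(co$records, co$predictions, co$reference,
                                    grouping = "quarter")
  expect_setequal(by_quarter$strata$stratum, c("Q1", "Q2", "Q4"))

  overall <- stratified_evaluate(co$records, co$predictions, co$reference,
                                 grouping = "none")
  expect_equal(nrow(overall$strata), 1)
  expect_equal(nrow(overall$comparisons), 0)
})

test_that("a stratum without reference positives is flagged and not compared", {
  co <- bind_cohorts(
    mock_cohort(400, "surgery", 0.95, 0.999, 0, 61),     # no events at all
    mock_cohort(400, "internal_medicine", 0.9, 0.99, 0.05, 62),
    mock_cohort(200, "icu", 0.9, 0.99, 0.1, 63))
  res <- stratified_evaluate(co$records, co$predictions, co$reference,
                             grouping = "department")
  expect_false(res$strata$comparable[res$strata$stratum == "surgery"])
  expect_false("surgery" %in% c(res$comparisons$stratum_a,
                                res$comparisons$stratum_b))
  # one usable pair remains: internal_medicine vs icu
  expect_equal(nrow(res$comparisons), 4)
})

test_that("an engineered specificity gap is declared significant", {
  # surgery-like stratum with perfect specificity vs an ICU-like stratum
  # with clearly lower specificity: LR+ must differ after adjustment
  co <- bind_cohorts(
    mock_cohort(6000, "surgery", 0.95, 1.0, 0.01, 71),
    mock_cohort(2000, "icu", 0.95, 0.96, 0.10, 72))
  res <- stratified_evaluate(co$records, co$predictions, co$reference,
                             grouping = "department", seed = 5)
  lr_cmp <- res$comparisons[res$comparisons$metric == "lr_pos", ]
  expect_equal(nrow(lr_cmp), 1)
  expect_lt(lr_cmp$p_adjusted, 0.01)
  ests <- stats::setNames(c(lr_cmp$estimate_a, lr_cmp$estimate_b),
                          c(lr_cmp$stratum_a, lr_cmp$stratum_b))
  expect_gt(ests[["surgery"]], ests[["icu"]])  # surgery LR+ higher
})

test_that("identical performance across strata yields no significant pairs", {
  co <- bind_cohorts(
    mock_cohort(1500, "surgery", 0.9, 0.99, 0.05, 81),
    mock_cohort(1500, "internal_medicine", 0.9, 0.99, 0.05, 82),
    mock_cohort(1500, "icu", 0.9, 0.99, 0.05, 83))
  res <- stratified_evaluate(co$records, co$predictions, co$reference,
                             grouping = "department", seed = 6)
  expect_true(all(res$comparisons$p_adjusted > bonferroni(0.01, 1),
                  na.rm = TRUE))
})

test_that("report files are written as TSV with a JSON twin", {
  co <- bind_cohorts(
    mock_cohort(400, "surgery", 0.9, 0.99, 0.05, 91),
    mock_cohort(400, "icu", 0.9, 0.99, 0.08, 92))
  res <- stratified_evaluate(co$records, co$predictions, co$reference,
                             grouping = "department")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_evaluation_report(res, tsv)
  expect_true(file.exists(tsv))
  json_path <- sub("\\.tsv$", ".json", tsv)
  expect_true(file.exists(json_path))
  twin <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  expect_equal(twin$grouping, "department")
  expect_equal(nrow(twin$strata), 2)
  header <- readLines(tsv, n = 1)
  expect_match(header, "stratum\tn\ttp")
})
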