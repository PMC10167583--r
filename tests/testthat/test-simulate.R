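test_that("generation is byte-deterministic under a seed", {
  cfg <- sim_config(n_patients = 150, seed = 5, language = "mixed")
  c1 <- generate_corpus(cfg)
  c2 <- generate_corpus(cfg)
  expect_identical(c1, c2)
  c3 <- generate_corpus(sim_config(n_patients = 150, seed = 6,
                                   language = "mixed"))
  expect_false(identical(c1$records, c3$records))
})

test_that("degenerate configurations behave sensibly", {
  empty <- generate_corpus(sim_config(n_patients = 0))
  expect_length(empty$records, 0)
  expect_equal(nrow(empty$labels), 0)

  none <- generate_corpus(sim_config(
    n_patients = 300, seed = 2,
    prevalence_by_department = c(surgery = 0, internal_medicine = 0, icu = 0)))
  expect_false(any(none$labels$vte_any))

  expect_error(sim_config(department_mix = c(surgery = 0.5,
                                             internal_medicine = 0.5,
                                             icu = 0.5)), "sum to 1")
  expect_error(sim_config(on_admission_fraction = 1.2), "proportions")
  expect_error(sim_config(error_mode_rates = c(bogus = 0.1)), "error_mode_rates")
})

test_that("realized prevalence tracks the configured strata", {
  corpus <- generate_corpus(sim_config(n_patients = 20000, seed = 3,
                                       error_mode_rates = no_error_rates()))
  dept <- vapply(corpus$records, `[[`, character(1), "department_class")
  expected <- c(surgery = 0.006, internal_medicine = 0.027, icu = 0.145)
  for (cl in names(expected)) {
    n_cl <- sum(dept == cl)
    p_hat <- mean(corpus$labels$vte_any[dept == cl])
    tol <- 3 * sqrt(expected[[cl]] * (1 - expected[[cl]]) / n_cl)
    expect_lt(abs(p_hat - expected[[cl]]), tol)
  }
  # overall event fraction ~2.1%
  p_all <- mean(corpus$labels$vte_any)
  expect_lt(abs(p_all - 0.021), 3 * sqrt(0.021 * 0.979 / 20000))
  # department mix ~45/52/3
  expect_lt(abs(mean(dept == "surgery") - 0.451), 0.02)
})

test_that("rendered notes carry exactly the requested assertion", {
  kb <- load_kb()
  status_of <- function(doc, concept) {
    res <- vtenlp:::conclude_document(doc, kb)
    res$conclusion$status[res$conclusion$concept == concept]
  }
  aff <- render_note("PE", "imaging_report", "affirmed", "en")
  expect_match(aff$text, "pulmonary embolism")
  expect_equal(status_of(aff, "PE"), "positive")

  hist <- render_note("DVT", "admission_note", "historical", "en")
  expect_match(hist$text, "History of deep vein thrombosis")
  expect_equal(status_of(hist, "DVT"), "negative")

  # excluded-site wording matches the lexicon but stays negative
  excl <- render_note("DVT", "discharge_summary", "excluded_site", "zh")
  expect_equal(status_of(excl, "DVT"), "negative")

  susp <- render_note("PE", "admission_note", "suspected", "zh")
  expect_equal(status_of(susp, "PE"), "positive")  # default option asserts it

  expect_equal(status_of(render_note("DVT", "progress_note", "negated", "en"),
                         "DVT"), "negative")
  expect_error(render_note("PE", "imaging_report", "vague", "en"),
               "unknown style")
  expect_error(render_note("PE", "imaging_report", "excluded_site", "en"),
               "no template")
})

test_that("error-mode injection: identity at zero rates, forced misses at 1", {
  cfg <- sim_config(n_patients = 250, seed = 13,
                    error_mode_rates = no_error_rates())
  corpus <- generate_corpus(cfg)
  expect_identical(inject_error_modes(corpus, no_error_rates(), seed = 1),
                   corpus)

  # calf_vein_omitted at rate 1: every positive becomes a pipeline FN
  rates <- no_error_rates()
  rates["calf_vein_omitted"] <- 1
  broken <- inject_error_modes(corpus, rates, seed = 2)
  expect_identical(broken$labels, corpus$labels)  # labels untouched
  pred <- detect_corpus(broken$records, load_kb())
  expect_false(any(pred$vte_any[broken$labels$vte_any]))
  expect_true(all(broken$tags$error_mode[broken$labels$vte_any] ==
                    "calf_vein_omitted"))

  # false-positive modes flip only label-negative patients
  rates_fp <- no_error_rates()
  rates_fp["prior_vte_history"] <- 1
  fp <- inject_error_modes(corpus, rates_fp, seed = 3)
  pred_fp <- detect_corpus(fp$records, load_kb())
  neg <- !fp$labels$vte_any
  expect_true(all(pred_fp$vte_any[neg]))
  expect_equal(pred_fp$onset[neg], rep("on_admission", sum(neg)))
})

test_that("a corpus written to disk round-trips through the readers", {
  corpus <- generate_corpus(sim_config(n_patients = 40, seed = 19,
                                       language = "mixed"))
  dir <- withr::local_tempdir()
  paths <- write_corpus(corpus, dir)
  back <- read_records(paths[["records"]])
  expect_equal(nrow(attr(back, "errors")), 0)
  expect_length(back, 40)
  expect_equal(vapply(back, `[[`, character(1), "patient_id"),
               corpus$labels$patient_id)
  labels <- read_reference_labels(paths[["labels"]])
  expect_equal(labels, corpus$labels)
})
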