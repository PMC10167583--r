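kb <- load_kb()

test_that("sentence rule matches its enumeration oracle for every flag combo", {
  combos <- expand.grid(site_valid = c(TRUE, FALSE),
                        polarity = c("affirmed", "negated"),
                        temporality = c("present", "historical"),
                        certainty = c("confirmed", "suspected"),
                        stringsAsFactors = FALSE)
  kb_strict <- kb
  kb_strict$options$suspected_counts_as_positive <- FALSE
  for (i in seq_len(nrow(combos))) {
    m <- data.frame(concept = "DVT", matched_term = "DVT", start = 0L,
                    end = 3L, site_valid = combos$site_valid[i],
                    polarity = combos$polarity[i],
                    temporality = combos$temporality[i],
                    certainty = combos$certainty[i], stringsAsFactors = FALSE)
    for (opt in c(TRUE, FALSE)) {
      got <- infer_sentence(m, if (opt) kb else kb_strict)
      want <- oracle_sentence_status(
        negated = combos$polarity[i] == "negated",
        historical = combos$temporality[i] == "historical",
        suspected = combos$certainty[i] == "suspected",
        site_invalid = !combos$site_valid[i],
        suspected_ok = opt)
      expect_equal(got$status, want, info = paste(unlist(combos[i, ]),
                                                  "opt =", opt))
    }
  }
})

test_that("one qualifying mention outweighs disqualified ones in a sentence", {
  text <- "History of DVT. Now CTPA confirmed acute pulmonary embolism and deep vein thrombosis."
  sents <- segment_sentences(text)
  res <- lapply(seq_len(nrow(sents)), function(i) {
    infer_sentence(detect_context(sents$text[i],
                                  recognize_entities(sents$text[i], kb), kb), kb)
  })
  expect_equal(res[[1]]$status[res[[1]]$concept == "DVT"], "negative")
  expect_setequal(res[[2]]$status, c("positive", "positive"))
})

test_that("document rule is any-positive, else any-mention negative", {
  cases <- expand.grid(s1 = c("positive", "negative", "not_mentioned"),
                       s2 = c("positive", "negative", "not_mentioned"),
                       stringsAsFactors = FALSE)
  for (i in seq_len(nrow(cases))) {
    st <- c(cases$s1[i], cases$s2[i])
    kept <- st[st != "not_mentioned"]
    conclusions <- data.frame(concept = rep("PE", length(kept)),
                              status = kept, stringsAsFactors = FALSE)
    got <- infer_document(conclusions)
    expect_equal(got$status[got$concept == "PE"], oracle_document_status(st),
                 info = paste(st, collapse = "+"))
  }
  none <- infer_document(data.frame(concept = character(0),
                                    status = character(0)))
  expect_equal(none$status, c("not_mentioned", "not_mentioned"))
})

test_that("location detector routes document types per target", {
  adm <- make_doc("x", "admission_note", "adm")
  img <- make_doc("y", "imaging_report", "img")
  rec <- make_record(list(adm, img))
  expect_equal(vapply(detect_locations(rec, "admission_with_vte", kb),
                      `[[`, character(1), "doc_id"), "adm")
  expect_equal(vapply(detect_locations(rec, "discharged_with_vte", kb),
                      `[[`, character(1), "doc_id"), "img")
  rec2 <- make_record(list(make_doc("z", "surgical_note")))
  expect_length(detect_locations(rec2, "admission_with_vte", kb), 0)
  expect_error(detect_locations(rec, "somewhere_else", kb), "unknown")
})

test_that("patient inference separates on-admission from in-hospital VTE", {
  # prior VTE wording with a trigger on admission, affirmed at discharge:
  # admission conclusion stays negative, the event counts as in-hospital
  rec <- make_record(list(
    make_doc("History of DVT two years ago.", "admission_note", "adm"),
    make_doc("Doppler ultrasound showed deep vein thrombosis.",
             "discharge_summary", "dis")))
  f <- infer_patient(rec, kb)$flags
  expect_false(f[["admission_with_dvt"]])
  expect_true(f[["discharged_with_dvt"]])
  expect_true(f[["in_hospital_dvt"]])

  # affirmed on admission and at discharge: on-admission, not in-hospital
  rec2 <- make_record(list(
    make_doc("CTPA confirmed acute pulmonary embolism.", "admission_note", "adm"),
    make_doc("CTPA confirmed acute pulmonary embolism.", "imaging_report", "img")))
  f2 <- infer_patient(rec2, kb)$flags
  expect_true(f2[["admission_with_pe"]])
  expect_false(f2[["in_hospital_pe"]])

  # no mentions anywhere: every flag false
  rec3 <- make_record(list(make_doc("Stable course.", "admission_note", "adm")))
  expect_false(any(infer_patient(rec3, kb)$flags))
})

test_that("provenance records the contributing spans", {
  rec <- make_record(list(
    make_doc("Routine check. CTPA confirmed acute pulmonary embolism.",
             "imaging_report", "img")))
  concl <- infer_patient(rec, kb)
  expect_equal(nrow(concl$provenance), 1)
  expect_equal(concl$provenance$doc_id, "img")
  expect_equal(concl$provenance$concept, "PE")
  txt <- rec$documents[[1]]$text
  expect_match(substring(txt, concl$provenance$start + 1, concl$provenance$end),
               "pulmonary embolism")
})

test_that("structured fields are scanned with default context", {
  rec <- make_record(list(
    make_doc("", "discharge_summary", "dis",
             fields = list(discharge_diagnosis = c("deep vein thrombosis",
                                                   "pneumonia")))))
  f <- infer_patient(rec, kb)$flags
  expect_true(f[["discharged_with_dvt"]])
  expect_false(f[["discharged_with_pe"]])
})

test_that("the in-hospital identity holds across a random corpus", {
  corpus <- generate_corpus(sim_config(n_patients = 150, seed = 31,
                                       language = "mixed"))
  for (rec in corpus$records) {
    f <- infer_patient(rec, kb)$flags
    expect_equal(f[["in_hospital_vte"]],
                 f[["discharged_with_vte"]] && !f[["admission_with_vte"]])
    expect_equal(f[["admission_with_vte"]],
                 f[["admission_with_dvt"]] || f[["admission_with_pe"]])
  }
})

test_that("adding an all-not-mentioned document never changes the conclusion", {
  corpus <- generate_corpus(sim_config(n_patients = 60, seed = 17))
  filler <- make_doc("Vitals stable; plan unchanged.", "progress_note",
                     "extra-filler")
  for (rec in corpus$records[1:40]) {
    before <- infer_patient(rec, kb)$flags
    rec$documents <- c(rec$documents, list(filler))
    after <- infer_patient(rec, kb)$flags
    expect_identical(before, after)
  }
})

test_that("detect_corpus is deterministic and labels onset correctly", {
  corpus <- generate_corpus(sim_config(n_patients = 120, seed = 43,
                                       error_mode_rates = no_error_rates()))
  p1 <- detect_corpus(corpus$records, kb)
  p2 <- detect_corpus(corpus$records, kb)
  expect_identical(p1, p2)
  expect_equal(p1$onset, corpus$labels$onset)
  expect_equal(p1$vte_any, corpus$labels$vte_any)
  expect_equal(nrow(detect_corpus(list(), kb)), 0)
})
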