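# Shared fixture builders. Everything is constructed in code; no data files.

make_doc <- function(text, type = "imaging_report", id = "d1",
                     ts = "2021-03-05T09:00:00", fields = NULL) {
  ehr_document(id, type, ts, text, fields)
}

make_record <- function(docs = list(), id = "p1",
                        adm = "2021-03-01T08:00:00",
                        dis = "2021-03-10T10:00:00",
                        dept = "internal_medicine", tier = "intermediate",
                        age = 60, sex = "female") {
  patient_record(id, adm, dis, department = dept, department_class = dept,
                 vte_risk_tier = tier, age = age, sex = sex, documents = docs)
}

# the reconstructed headline 2x2: 626 events, 563 detected, 55 FP, N = 30,152
printed_cm <- function() vte_confusion(563, 55, 63, 29471)

# one sentence per assertion-flag combination; NA flags mean "no mention".
# Forward triggers stack left of the term, the excluded-site qualifier sits
# right of it, so each flag is controlled independently.
flag_sentence <- function(negated, historical, suspected, site_invalid) {
  paste0(
    if (negated) "No evidence of " else "There is ",
    if (suspected) "suspected " else "",
    if (historical) "prior " else "",
    "deep vein thrombosis",
    if (site_invalid) " of the internal jugular vein" else "",
    "."
  )
}

all_flag_combos <- function() {
  combos <- expand.grid(negated = c(FALSE, TRUE), historical = c(FALSE, TRUE),
                        suspected = c(FALSE, TRUE), site_invalid = c(FALSE, TRUE))
  combos$text <- mapply(flag_sentence, combos$negated, combos$historical,
                        combos$suspected, combos$site_invalid)
  combos
}

# independent statement of the sentence rule (the oracle the pipeline is
# checked against): positive iff site-valid, affirmed, present, and
# confirmed-or-suspected-allowed
oracle_sentence_status <- function(negated, historical, suspected,
                                   site_invalid, suspected_ok = TRUE) {
  qualifies <- !site_invalid && !negated && !historical &&
    (!suspected || suspected_ok)
  if (qualifies) "positive" else "negative"
}

# document rule oracle: any positive wins, else any mention is negative
oracle_document_status <- function(statuses) {
  if (any(statuses == "positive")) "positive"
  else if (any(statuses %in% c("positive", "negative"))) "negative"
  else "not_mentioned"
}
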