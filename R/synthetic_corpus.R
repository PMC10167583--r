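# Seeded generator of synthetic inpatient cohorts with ground-truth labels.
# The defaults emulate the validation cohort the detector is meant for:
# department mix 45.1/52/2.9% (surgery / internal medicine / ICU) with
# per-department VTE prevalence 0.6/2.7/14.5%, PE in 28.3% and DVT in 85.0%
# of events, 47.3% female, age median 56 (IQR 41-67). Assertion error modes
# mirror the observed failure taxonomy of deployed rule systems: suspected
# events later disproved, undetected prior-VTE wording (false positives);
# undocumented calf-vein events, modified admission diagnoses, unrecognised
# iliac-vein wording (false negatives).

ERROR_MODES <- c("suspected_then_disproved", "prior_vte_history",
                 "calf_vein_omitted", "modified_admission_dx",
                 "iliac_unrecognized")

#' Default error-mode rates
#'
#' Per-patient probabilities calibrated so that, at the reference cohort
#' scale (about 30,000 patients, 626 events), the expected counts match the
#' observed error taxonomy: 29 suspected-then-disproved and 23 prior-VTE
#' false positives among ~29,526 negatives; 44 calf-vein, 12
#' modified-diagnosis, and 7 iliac false negatives among 626 positives
#' (a 70/19/11 percent split of false negatives).
#'
#' @return Named numeric vector over the five error modes. False-positive
#'   modes are probabilities per label-negative patient; false-negative
#'   modes per label-positive patient.
#' @export
default_error_rates <- function() {
  c(suspected_then_disproved = 29 / 29526,
    prior_vte_history = 23 / 29526,
    calf_vein_omitted = 44 / 626,
    modified_admission_dx = 12 / 626,
    iliac_unrecognized = 7 / 626)
}

#' All-zero error-mode rates (a clean corpus)
#' @return Named numeric vector of zeros over the five error modes.
#' @export
no_error_rates <- function() {
  stats::setNames(rep(0, length(ERROR_MODES)), ERROR_MODES)
}

#' Simulation configuration for a synthetic cohort
#'
#' @param n_patients Number of patients to generate.
#' @param seed Integer seed; the full (records, labels, tags) triple is
#'   reproducible given the seed.
#' @param department_mix Named proportions over `surgery`,
#'   `internal_medicine`, `icu`; must sum to 1.
#' @param prevalence_by_department Named per-department VTE probabilities.
#' @param pe_fraction,dvt_fraction Fractions of events that involve PE and
#'   DVT respectively (they may overlap; the excess over 1 is the fraction
#'   with both).
#' @param on_admission_fraction Fraction of events already present on
#'   admission (the remainder are new-onset in-hospital events).
#' @param age_meanlog,age_sdlog Log-normal age parameters (years), matched
#'   to median 56, IQR 41-67, truncated to 18-100.
#' @param female_fraction Proportion of female patients.
#' @param negated_mention_fraction Fraction of label-negative patients whose
#'   notes carry a negated, historical, or excluded-site mention rather
#'   than no mention at all.
#' @param error_mode_rates Named vector over [ERROR_MODES][default_error_rates];
#'   see [default_error_rates()]. Use [no_error_rates()] for a clean corpus.
#' @param language `"en"`, `"zh"`, or `"mixed"` (each document drawn at
#'   random).
#' @return A validated list of class `vte_sim_config`.
#' @export
sim_config <- function(n_patients = 1000,
                       seed = 1,
                       department_mix = c(surgery = 0.451,
                                          internal_medicine = 0.520,
                                          icu = 0.029),
                       prevalence_by_department = c(surgery = 0.006,
                                                    internal_medicine = 0.027,
                                                    icu = 0.145),
                       pe_fraction = 177 / 626,
                       dvt_fraction = 532 / 626,
                       on_admission_fraction = 0.8,
                       age_meanlog = log(56),
                       age_sdlog = 0.364,
                       female_fraction = 0.473,
                       negated_mention_fraction = 0.15,
                       error_mode_rates = default_error_rates(),
                       language = c("en", "zh", "mixed")) {
  language <- match.arg(language)
  if (n_patients < 0 || n_patients != round(n_patients)) {
    stop("n_patients must be a non-negative integer", call. = FALSE)
  }
  classes <- c("surgery", "internal_medicine", "icu")
  if (!setequal(names(department_mix), classes)) {
    stop("department_mix must be named over: ", paste(classes, collapse = ", "),
         call. = FALSE)
  }
  if (abs(sum(department_mix) - 1) > 1e-8) {
    stop("department_mix must sum to 1", call. = FALSE)
  }
  props <- c(prevalence_by_department, pe_fraction, dvt_fraction,
             on_admission_fraction, female_fraction, negated_mention_fraction)
  if (any(props < 0 | props > 1)) {
    stop("all proportions must lie in [0, 1]", call. = FALSE)
  }
  if (!setequal(names(prevalence_by_department), classes)) {
    stop("prevalence_by_department must be named over: ",
         paste(classes, collapse = ", "), call. = FALSE)
  }
  rates <- error_mode_rates[ERROR_MODES]
  if (anyNA(rates) || any(rates < 0 | rates > 1)) {
    stop("error_mode_rates must cover all of: ",
         paste(ERROR_MODES, collapse = ", "), " with values in [0, 1]",
         call. = FALSE)
  }
  names(rates) <- ERROR_MODES
  structure(
    list(n_patients = n_patients, seed = seed,
         department_mix = department_mix[classes],
         prevalence_by_department = prevalence_by_department[classes],
         pe_fraction = pe_fraction, dvt_fraction = dvt_fraction,
         on_admission_fraction = on_admission_fraction,
         age_meanlog = age_meanlog, age_sdlog = age_sdlog,
         female_fraction = female_fraction,
         negated_mention_fraction = negated_mention_fraction,
         error_mode_rates = rates, language = language),
    class = "vte_sim_config"
  )
}

NOTE_TEMPLATES <- list(
  en = list(
    admission_intro = "Admission note. Present illness: admitted for further evaluation and management.",
    imaging_intro = "Imaging report. D-dimer 1.5 mg/L elevated.",
    discharge_intro = "Discharge summary. Hospital course reviewed.",
    absent = "Patient stable. Vital signs within normal limits. Plan: continue current management.",
    affirmed = c(PE = "CTPA showed acute pulmonary embolism in the right lower lobe.",
                 DVT = "Doppler ultrasound showed deep vein thrombosis of the left popliteal vein."),
    negated = c(PE = "CTPA showed no evidence of pulmonary embolism.",
                DVT = "Ultrasound showed no evidence of deep vein thrombosis."),
    historical = c(PE = "History of pulmonary embolism two years ago.",
                   DVT = "History of deep vein thrombosis two years ago."),
    suspected = c(PE = "Suspected pulmonary embolism; CTPA pending.",
                  DVT = "Suspected deep vein thrombosis; ultrasound pending."),
    excluded_site = c(DVT = "Ultrasound showed deep vein thrombosis of the internal jugular vein."),
    prior_untriggered = c(PE = "Known pulmonary embolism since 2015, on long-term anticoagulation.",
                          DVT = "Known DVT since 2015, on long-term anticoagulation."),
    calf_omitted = "Screening ultrasound of the lower limbs performed; report filed separately. Recovering well.",
    modified_dx = "Admission diagnosis revised after review; see updated problem list.",
    iliac = "Ultrasound showed thrombosis of the left iliac vein."
  ),
  zh = list(
    admission_intro = "入院记录。现病史：患者为求进一步诊治入院。",
    imaging_intro = "影像学报告。D-二聚体1.5mg/L，升高。",
    discharge_intro = "出院小结。住院经过已回顾。",
    absent = "患者一般情况可，生命体征平稳，继续目前治疗。",
    affirmed = c(PE = "CT肺动脉造影示急性肺栓塞。",
                 DVT = "下肢静脉超声示左侧腘静脉深静脉血栓形成。"),
    negated = c(PE = "CT肺动脉造影未见肺栓塞。",
                DVT = "下肢静脉超声未见深静脉血栓。"),
    historical = c(PE = "既往肺栓塞病史。",
                   DVT = "既往深静脉血栓病史。"),
    suspected = c(PE = "肺栓塞待排，建议CT肺动脉造影检查。",
                  DVT = "疑似深静脉血栓，建议超声检查。"),
    excluded_site = c(DVT = "超声示上肢深静脉血栓形成。"),
    prior_untriggered = c(PE = "2015年曾患肺栓塞，长期抗凝治疗。",
                          DVT = "2015年曾患深静脉血栓，长期抗凝治疗。"),
    calf_omitted = "已行双下肢静脉超声筛查，报告另附。恢复良好。",
    modified_dx = "入院诊断经复核后修订，见更新后的问题列表。",
    iliac = "超声示左侧髂静脉血栓形成。"
  )
)

NOTE_STYLES <- c("affirmed", "negated", "historical", "suspected",
                 "excluded_site", "absent")

doc_intro <- function(tpl, doc_type) {
  switch(doc_type,
    admission_note = tpl$admission_intro,
    imaging_report = tpl$imaging_intro,
    progress_note = tpl$discharge_intro,
    surgical_note = tpl$discharge_intro,
    discharge_summary = tpl$discharge_intro
  )
}

#' Render a templated clinical note
#'
#' Produces a short document whose text contains exactly one templated
#' mention region consistent with the requested assertion style, parseable
#' by the bundled default knowledge base. `concepts` may name one or both
#' target concepts; with style `"absent"` no mention is rendered.
#'
#' @param concepts Character vector over `c("PE", "DVT")` (ignored for
#'   style `"absent"`).
#' @param doc_type One of [DOC_TYPES].
#' @param style One of `affirmed`, `negated`, `historical`, `suspected`,
#'   `excluded_site` (DVT only), `absent`.
#' @param language `"en"` or `"zh"`.
#' @param doc_id,timestamp Passed through to [ehr_document()].
#' @return A `vte_document`.
#' @export
#' @examples
#' render_note("PE", "imaging_report", "affirmed", "en",
#'             doc_id = "d1", timestamp = "2021-03-05T09:00:00")
render_note <- function(concepts, doc_type, style, language = "en",
                        doc_id = "doc1", timestamp = "2021-01-01T08:00:00") {
  if (!style %in% NOTE_STYLES) stop("unknown style '", style, "'", call. = FALSE)
  if (!language %in% c("en", "zh")) {
    stop("language must be 'en' or 'zh'", call. = FALSE)
  }
  tpl <- NOTE_TEMPLATES[[language]]
  if (!doc_type %in% DOC_TYPES) {
    stop("doc_type must be one of: ", paste(DOC_TYPES, collapse = ", "),
         call. = FALSE)
  }
  if (!grepl("^\\d{4}-\\d{2}-\\d{2}(T\\d{2}:\\d{2}:\\d{2})?$", timestamp)) {
    stop("timestamp '", timestamp, "' is not ISO-8601", call. = FALSE)
  }
  body <- if (style == "absent") {
    tpl$absent
  } else {
    bank <- tpl[[style]]
    missing <- setdiff(concepts, names(bank))
    if (length(missing)) {
      stop("style '", style, "' has no template for concept ",
           paste(missing, collapse = ", "), call. = FALSE)
    }
    paste(bank[concepts], collapse = " ")
  }
  new_document(doc_id, doc_type, timestamp,
               paste(doc_intro(tpl, doc_type), body, tpl$absent))
}

sample_language <- function(config) {
  if (config$language == "mixed") sample(c("en", "zh"), 1L) else config$language
}

#' Generate a synthetic cohort with ground-truth labels
#'
#' Draws each patient's department, demographics and VTE status from the
#' configured distributions; renders location-appropriate documents
#' (on-admission events appear in the admission note and the discharge-side
#' documents, in-hospital events only in the imaging report and discharge
#' summary; label-negative patients carry no mention or a
#' negated/historical/excluded-site one); and finally injects the
#' configured error modes via [inject_error_modes()].
#'
#' @param config A [sim_config()] object.
#' @return List with `records` (list of `vte_record`), `labels` (reference
#'   data frame: `patient_id`, `vte_any`, `pe`, `dvt`, `onset`) and `tags`
#'   (data frame `patient_id`, `error_mode`; `""` when untouched).
#' @export
generate_corpus <- function(config = sim_config()) {
  if (!inherits(config, "vte_sim_config")) config <- do.call(sim_config, config)
  n <- config$n_patients
  empty_labels <- data.frame(patient_id = character(0), vte_any = logical(0),
                             pe = logical(0), dvt = logical(0),
                             onset = character(0), stringsAsFactors = FALSE)
  empty_tags <- data.frame(patient_id = character(0), error_mode = character(0),
                           stringsAsFactors = FALSE)
  if (n == 0L) {
    return(list(records = list(), labels = empty_labels, tags = empty_tags))
  }
  corpus <- with_seed(config$seed, {
    classes <- names(config$department_mix)
    dept <- sample(classes, n, replace = TRUE, prob = config$department_mix)
    tier <- c(surgery = "low", internal_medicine = "intermediate",
              icu = "high")[dept]
    age <- round(pmin(100, pmax(18, stats::rlnorm(n, config$age_meanlog,
                                                  config$age_sdlog))))
    sex <- ifelse(stats::runif(n) < config$female_fraction, "female", "male")
    vte <- stats::rbinom(n, 1L, config$prevalence_by_department[dept]) == 1L

    p_both <- max(0, config$pe_fraction + config$dvt_fraction - 1)
    p_pe_only <- config$pe_fraction - p_both
    p_dvt_only <- config$dvt_fraction - p_both
    type <- rep(NA_character_, n)
    type[vte] <- sample(c("pe", "dvt", "both"), sum(vte), replace = TRUE,
                        prob = c(p_pe_only, p_dvt_only, p_both))
    on_adm <- vte & stats::runif(n) < config$on_admission_fraction

    adm_day <- stats::runif(n, 0, 364)
    los_days <- pmax(2, round(stats::rlnorm(n, log(8), 0.649)))
    origin <- as.POSIXct("2021-01-01 00:00:00", tz = "UTC")
    adm_time <- origin + adm_day * 86400
    dis_time <- adm_time + los_days * 86400
    iso <- function(t) format(t, "%Y-%m-%dT%H:%M:%S")

    records <- vector("list", n)
    for (i in seq_len(n)) {
      pid <- sprintf("P%06d", i)
      concepts <- switch(if (vte[i]) type[i] else "none",
                         pe = "PE", dvt = "DVT", both = c("PE", "DVT"),
                         none = character(0))
      mid_time <- iso(adm_time[i] + los_days[i] * 86400 / 2)
      docs <- list()
      if (vte[i]) {
        adm_style <- if (on_adm[i]) "affirmed" else "absent"
        docs[[1]] <- render_note(concepts, "admission_note", adm_style,
                                 sample_language(config),
                                 paste0(pid, "-adm"), iso(adm_time[i]))
        docs[[2]] <- render_note(concepts, "imaging_report", "affirmed",
                                 sample_language(config),
                                 paste0(pid, "-img"), mid_time)
        docs[[3]] <- render_note(concepts, "discharge_summary", "affirmed",
                                 sample_language(config),
                                 paste0(pid, "-dis"), iso(dis_time[i]))
      } else {
        docs[[1]] <- render_note(character(0), "admission_note", "absent",
                                 sample_language(config),
                                 paste0(pid, "-adm"), iso(adm_time[i]))
        docs[[2]] <- render_note(character(0), "discharge_summary", "absent",
                                 sample_language(config),
                                 paste0(pid, "-dis"), iso(dis_time[i]))
        if (stats::runif(1) < config$negated_mention_fraction) {
          style <- sample(c("negated", "historical", "excluded_site"), 1L,
                          prob = c(0.6, 0.3, 0.1))
          cpt <- if (style == "excluded_site") "DVT" else sample(c("PE", "DVT"), 1L)
          docs[[3]] <- render_note(cpt, "imaging_report", style,
                                   sample_language(config),
                                   paste0(pid, "-img"), mid_time)
        }
      }
      records[[i]] <- new_record(
        pid, iso(adm_time[i]), iso(dis_time[i]),
        department = dept[i], department_class = dept[i],
        vte_risk_tier = unname(tier[i]), age = age[i], sex = sex[i],
        documents = docs)
    }
    labels <- data.frame(
      patient_id = vapply(records, `[[`, character(1), "patient_id"),
      vte_any = vte,
      pe = vte & type %in% c("pe", "both"),
      dvt = vte & type %in% c("dvt", "both"),
      onset = ifelse(!vte, "none", ifelse(on_adm, "on_admission", "in_hospital")),
      stringsAsFactors = FALSE
    )
    tags <- data.frame(patient_id = labels$patient_id,
                       error_mode = "", stringsAsFactors = FALSE)
    list(records = records, labels = labels, tags = tags)
  })
  if (any(config$error_mode_rates > 0)) {
    corpus <- inject_error_modes(corpus, config$error_mode_rates,
                                 seed = config$seed + 1L,
                                 language = config$language)
  }
  corpus
}

replace_documents <- function(record, new_docs) {
  record$documents <- new_docs
  record
}

# rewrite a positive patient's documents so no parseable mention remains,
# using the narrative fragment for the given error mode
strip_mentions <- function(record, fragment_key, language) {
  record$documents <- lapply(record$documents, function(d) {
    lang <- if (language == "mixed") sample(c("en", "zh"), 1L) else language
    tpl <- NOTE_TEMPLATES[[lang]]
    d$text <- paste(doc_intro(tpl, d$doc_type), tpl[[fragment_key]], tpl$absent)
    d
  })
  record
}

#' Inject assertion error modes into a synthetic corpus
#'
#' Each mode rewrites the narrative while leaving the ground-truth label
#' untouched, so the discrepancy it creates is deliberate and tagged:
#' \describe{
#'   \item{suspected_then_disproved}{label-negative patient; the admission
#'     note gains a suspected mention, which the detector (with the default
#'     `suspected_counts_as_positive`) asserts - a candidate false positive.}
#'   \item{prior_vte_history}{label-negative patient; the admission note
#'     gains prior-VTE wording phrased without any configured temporality
#'     trigger - a candidate false positive.}
#'   \item{calf_vein_omitted}{label-positive patient; all documents lose
#'     their mention (an asymptomatic isolated calf-vein event absent from
#'     the discharge diagnosis) - a forced false negative.}
#'   \item{modified_admission_dx}{label-positive patient; the admission
#'     diagnosis was revised and the final wording carries no mention - a
#'     forced false negative.}
#'   \item{iliac_unrecognized}{label-positive patient; the event is
#'     documented as iliac-vein thrombosis, wording outside the lexicon - a
#'     forced false negative.}
#' }
#' False-positive modes are drawn per label-negative patient, false-negative
#' modes per label-positive patient; at most one mode per patient.
#'
#' @param corpus List `(records, labels, tags)` from [generate_corpus()].
#' @param rates Named vector over [ERROR_MODES][default_error_rates].
#' @param seed Integer seed.
#' @param language `"en"`, `"zh"`, or `"mixed"`.
#' @return The corpus with rewritten records and updated `tags`.
#' @export
inject_error_modes <- function(corpus, rates = default_error_rates(), seed = 1,
                               language = "en") {
  rates <- rates[ERROR_MODES]
  if (anyNA(rates) || any(rates < 0 | rates > 1)) {
    stop("rates must cover all error modes with values in [0, 1]", call. = FALSE)
  }
  if (all(rates == 0)) return(corpus)
  with_seed(seed, {
    labels <- corpus$labels
    pick_mode <- function(u, mode_rates) {
      cum <- cumsum(mode_rates)
      if (sum(mode_rates) > 1) cum <- cum / sum(mode_rates)
      i <- which(u < cum)
      if (length(i)) names(mode_rates)[i[1]] else ""
    }
    fp_rates <- rates[c("suspected_then_disproved", "prior_vte_history")]
    fn_rates <- rates[c("calf_vein_omitted", "modified_admission_dx",
                        "iliac_unrecognized")]
    for (i in seq_along(corpus$records)) {
      u <- stats::runif(1)
      mode <- if (labels$vte_any[i]) pick_mode(u, fn_rates) else pick_mode(u, fp_rates)
      if (!nzchar(mode)) next
      rec <- corpus$records[[i]]
      lang <- if (language == "mixed") sample(c("en", "zh"), 1L) else language
      if (mode == "suspected_then_disproved") {
        cpt <- sample(c("PE", "DVT"), 1L)
        adm <- which(vapply(rec$documents, `[[`, character(1), "doc_type") ==
                       "admission_note")[1]
        old <- rec$documents[[adm]]
        rec$documents[[adm]] <- render_note(cpt, "admission_note", "suspected",
                                            lang, old$doc_id, old$timestamp)
      } else if (mode == "prior_vte_history") {
        cpt <- sample(c("PE", "DVT"), 1L)
        adm <- which(vapply(rec$documents, `[[`, character(1), "doc_type") ==
                       "admission_note")[1]
        old <- rec$documents[[adm]]
        tpl <- NOTE_TEMPLATES[[lang]]
        rec$documents[[adm]] <- ehr_document(
          old$doc_id, "admission_note", old$timestamp,
          paste(doc_intro(tpl, "admission_note"),
                tpl$prior_untriggered[[cpt]], tpl$absent))
      } else if (mode == "calf_vein_omitted") {
        rec <- strip_mentions(rec, "calf_omitted", lang)
      } else if (mode == "modified_admission_dx") {
        rec <- strip_mentions(rec, "modified_dx", lang)
      } else if (mode == "iliac_unrecognized") {
        rec <- strip_mentions(rec, "iliac", lang)
      }
      corpus$records[[i]] <- rec
      corpus$tags$error_mode[i] <- mode
    }
    corpus
  })
}

#' Write a synthetic corpus to disk
#'
#' Writes the records as JSON Lines ([write_records()]) plus the labels and
#' error-mode tags as CSV.
#'
#' @param corpus List from [generate_corpus()].
#' @param dir Output directory (created if absent).
#' @return Named character vector of the three paths, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(records = file.path(dir, "records.jsonl"),
             labels = file.path(dir, "labels.csv"),
             tags = file.path(dir, "tags.csv"))
  write_records(corpus$records, paths[["records"]])
  write_reference_labels(corpus$labels, paths[["labels"]])
  utils::write.csv(corpus$tags, paths[["tags"]], row.names = FALSE,
                   quote = FALSE, fileEncoding = "UTF-8")
  invisible(paths)
}
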