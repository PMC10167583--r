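# The inference pipeline, from raw documents to a patient-level conclusion:
#   location detection -> sentence segmentation -> entity recognition ->
#   context (assertion) detection -> sentence inference -> document
#   inference -> patient inference via knowledge-base expressions.
# All character offsets are 0-based, half-open, in character units.

SENTENCE_TERMINATORS <- "[.!?;\n。！？；]"

# tokens before a period that never end a sentence
ABBREVIATIONS <- c("e.g", "i.e", "etc", "vs", "dr", "mr", "mrs", "ms",
                   "fig", "st", "approx", "resp")

#' Split document text into sentences
#'
#' Boundaries are `.` `!` `?` `;`, newline, and their full-width
#' counterparts. A period between two digits (a decimal number) or ending a
#' known abbreviation (`e.g.`, `Dr.`, single initials, ...) is not a
#' boundary. Sentence spans are substrings of the input, so concatenating
#' the spans with the inter-sentence whitespace gaps reconstructs the text.
#'
#' @param text A single string (possibly empty; any script).
#' @return Data frame with columns `start`, `end` (0-based, half-open
#'   character offsets into `text`) and `text` (the sentence substring);
#'   sentences are ordered and non-overlapping.
#' @export
#' @examples
#' segment_sentences("No DVT. CTPA negative.")
#' segment_sentences("D-dimer 1.5 mg/L elevated.")  # one sentence
segment_sentences <- function(text) {
  empty <- data.frame(start = integer(0), end = integer(0), text = character(0),
                      stringsAsFactors = FALSE)
  if (length(text) != 1L || is.na(text) || !nzchar(text)) return(empty)
  n <- nchar(text)
  m <- gregexpr(SENTENCE_TERMINATORS, text, perl = TRUE)[[1]]
  bpos <- if (m[1] == -1L) integer(0) else as.integer(m)
  if (length(bpos)) {
    ch <- substring(text, bpos, bpos)
    keep <- rep(TRUE, length(bpos))
    for (j in which(ch == ".")) {
      i <- bpos[j]
      prev <- if (i > 1L) substring(text, i - 1L, i - 1L) else ""
      nxt <- if (i < n) substring(text, i + 1L, i + 1L) else ""
      if (grepl("[0-9]", prev) && grepl("[0-9]", nxt)) {
        keep[j] <- FALSE
        next
      }
      head_txt <- substring(text, max(1L, i - 8L), i - 1L)
      tok <- regmatches(head_txt, regexpr("[A-Za-z.]+$", head_txt))
      if (length(tok)) {
        tok <- tolower(tok)
        after_dot <- sub("^.*\\.", "", tok)
        if (tok %in% ABBREVIATIONS || nchar(after_dot) == 1L) keep[j] <- FALSE
      }
    }
    bpos <- bpos[keep]
  }
  ends <- unique(c(bpos, n))
  starts <- c(1L, ends[-length(ends)] + 1L)
  out <- vector("list", length(ends))
  for (k in seq_along(ends)) {
    s <- starts[k]
    e <- ends[k]
    while (s <= e && grepl("^\\s$", substring(text, s, s))) s <- s + 1L
    while (e >= s && grepl("^\\s$", substring(text, e, e))) e <- e - 1L
    if (s > e) next
    out[[k]] <- data.frame(start = s - 1L, end = e, text = substring(text, s, e),
                           stringsAsFactors = FALSE)
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (!length(out)) return(empty)
  do.call(rbind, out)
}

sentence_text <- function(sentence) {
  if (is.character(sentence)) sentence else sentence$text
}

concept_pattern <- function(kb) {
  paste(unlist(lapply(kb$concepts, `[[`, "terms")), collapse = "|")
}

# shared constants for the fast path (most documents mention no concept)
NOT_MENTIONED_DF <- data.frame(
  concept = c("DVT", "PE"), status = c("not_mentioned", "not_mentioned"),
  stringsAsFactors = FALSE)
EMPTY_PROVENANCE_DF <- data.frame(
  doc_id = character(0), concept = character(0), start = integer(0),
  end = integer(0), section = character(0), stringsAsFactors = FALSE)

#' Recognise DVT/PE concept mentions in one sentence
#'
#' Matches the knowledge-base lexicon (case-insensitive regular expressions)
#' against the sentence text and returns all non-overlapping matches,
#' preferring the longest match at each position. A mention is marked
#' `site_valid = FALSE` when one of its concept's excluded-site terms (upper
#' extremity, internal jugular, vena cava, ...) also occurs in the sentence,
#' because thrombosis at those sites does not count as valid VTE.
#'
#' @param sentence A sentence string, or one row of [segment_sentences()].
#' @param kb A `vte_kb` knowledge base.
#' @return Data frame with columns `concept`, `matched_term`, `start`, `end`
#'   (0-based, half-open offsets within the sentence), `site_valid`.
#' @export
#' @examples
#' kb <- load_kb()
#' recognize_entities("Acute pulmonary embolism on CTPA.", kb)
#' recognize_entities("internal jugular deep vein thrombosis", kb)$site_valid
recognize_entities <- function(sentence, kb) {
  text <- sentence_text(sentence)
  empty <- data.frame(concept = character(0), matched_term = character(0),
                      start = integer(0), end = integer(0),
                      site_valid = logical(0), stringsAsFactors = FALSE)
  if (!nzchar(text)) return(empty)
  hits <- list()
  for (cname in names(kb$concepts)) {
    for (pat in kb$concepts[[cname]]$terms) {
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1L) next
      len <- attr(m, "match.length")
      hits[[length(hits) + 1L]] <- data.frame(
        concept = cname, start1 = as.integer(m), len = as.integer(len),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) return(empty)
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$start1, -hits$len), , drop = FALSE]
  keep <- logical(nrow(hits))
  last_end <- 0L
  for (i in seq_len(nrow(hits))) {
    if (hits$start1[i] > last_end) {
      keep[i] <- TRUE
      last_end <- hits$start1[i] + hits$len[i] - 1L
    }
  }
  hits <- hits[keep, , drop = FALSE]
  site_ok <- vapply(hits$concept, function(cname) {
    excl <- kb$concepts[[cname]]$excluded_site_terms
    !length(excl) || !any(vapply(excl, function(p) {
      grepl(p, text, perl = TRUE, ignore.case = TRUE)
    }, logical(1)))
  }, logical(1))
  data.frame(
    concept = hits$concept,
    matched_term = substring(text, hits$start1, hits$start1 + hits$len - 1L),
    start = hits$start1 - 1L,
    end = hits$start1 + hits$len - 1L,
    site_valid = unname(site_ok),
    stringsAsFactors = FALSE
  )
}

#' Attach assertion context to concept mentions
#'
#' For each mention, every trigger whose directional scope window reaches
#' the mention sets its dimension (polarity, temporality, or certainty);
#' when several triggers of one dimension reach a mention, the nearest wins.
#' Scope windows are counted in characters between the trigger match and the
#' mention. Mentions with no trigger in range keep the defaults
#' affirmed / present / confirmed.
#'
#' @param sentence A sentence string or one row of [segment_sentences()].
#' @param mentions Data frame from [recognize_entities()].
#' @param kb A `vte_kb` knowledge base.
#' @return `mentions` with added character columns `polarity`
#'   (`affirmed`/`negated`), `temporality` (`present`/`historical`) and
#'   `certainty` (`confirmed`/`suspected`).
#' @export
#' @examples
#' kb <- load_kb()
#' s <- "no evidence of pulmonary embolism"
#' detect_context(s, recognize_entities(s, kb), kb)$polarity
detect_context <- function(sentence, mentions, kb) {
  text <- sentence_text(sentence)
  defaults <- c(polarity = "affirmed", temporality = "present",
                certainty = "confirmed")
  for (dim in names(defaults)) mentions[[dim]] <- rep(defaults[[dim]], nrow(mentions))
  if (!nrow(mentions)) return(mentions)
  best_gap <- matrix(Inf, nrow(mentions), length(CONTEXT_DIMENSIONS),
                     dimnames = list(NULL, CONTEXT_DIMENSIONS))
  tr <- kb$triggers
  for (i in seq_len(nrow(tr))) {
    m <- gregexpr(tr$trigger_text[i], text, perl = TRUE, ignore.case = TRUE)[[1]]
    if (m[1] == -1L) next
    tstarts <- as.integer(m) - 1L
    tends <- tstarts + attr(m, "match.length")
    for (k in seq_along(tstarts)) {
      for (j in seq_len(nrow(mentions))) {
        gap <- Inf
        fwd <- tends[k] <= mentions$start[j] &&
          (mentions$start[j] - tends[k]) <= tr$scope_window[i]
        bwd <- tstarts[k] >= mentions$end[j] &&
          (tstarts[k] - mentions$end[j]) <= tr$scope_window[i]
        if (tr$direction[i] %in% c("forward", "bidirectional") && fwd) {
          gap <- min(gap, mentions$start[j] - tends[k])
        }
        if (tr$direction[i] %in% c("backward", "bidirectional") && bwd) {
          gap <- min(gap, tstarts[k] - mentions$end[j])
        }
        dim <- tr$dimension[i]
        if (gap < best_gap[j, dim]) {
          best_gap[j, dim] <- gap
          mentions[[dim]][j] <- tr$value[i]
        }
      }
    }
  }
  mentions
}

#' Derive sentence-level conclusions from contextualised mentions
#'
#' Per concept: `positive` when at least one mention is site-valid,
#' affirmed, present, and either confirmed or (with the
#' `suspected_counts_as_positive` option, the default) suspected;
#' `negative` when mentions of the concept exist but none qualifies.
#' Concepts without mentions are not mentioned and yield no row.
#'
#' @param mentions Data frame from [detect_context()].
#' @param kb A `vte_kb` knowledge base.
#' @return Data frame with columns `concept` and `status`
#'   (`positive`/`negative`), one row per mentioned concept.
#' @export
infer_sentence <- function(mentions, kb) {
  empty <- data.frame(concept = character(0), status = character(0),
                      stringsAsFactors = FALSE)
  if (!nrow(mentions)) return(empty)
  allow_suspected <- isTRUE(kb$options$suspected_counts_as_positive)
  qualifies <- mentions$site_valid &
    mentions$polarity == "affirmed" &
    mentions$temporality == "present" &
    (mentions$certainty == "confirmed" | allow_suspected)
  concepts <- unique(mentions$concept)
  data.frame(
    concept = concepts,
    status = vapply(concepts, function(cname) {
      if (any(qualifies[mentions$concept == cname])) "positive" else "negative"
    }, character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Aggregate sentence conclusions into a document conclusion
#'
#' Per concept: `positive` if any sentence is positive, else `negative` if
#' any sentence mentions the concept (all non-qualifying), else
#' `not_mentioned`. The any-positive rule means an affirmed sentence
#' dominates a negated one elsewhere in the same document.
#'
#' @param sentence_conclusions Data frame of stacked [infer_sentence()]
#'   rows for one document (columns `concept`, `status`).
#' @return Data frame with one row per concept in `c("DVT", "PE")` and a
#'   `status` column (`positive`/`negative`/`not_mentioned`).
#' @export
infer_document <- function(sentence_conclusions) {
  data.frame(
    concept = CONCEPTS,
    status = vapply(CONCEPTS, function(cname) {
      st <- sentence_conclusions$status[sentence_conclusions$concept == cname]
      if (any(st == "positive")) "positive"
      else if (length(st)) "negative"
      else "not_mentioned"
    }, character(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Select the documents read for one extraction target
#'
#' The admission-with-VTE conclusion is extracted from admission notes only;
#' the discharged-with-VTE conclusion from imaging reports, discharge
#' summaries, progress notes and surgical notes, per the knowledge base's
#' location map. Original document order is preserved.
#'
#' @param record A `vte_record`.
#' @param target `"admission_with_vte"` or `"discharged_with_vte"`.
#' @param kb A `vte_kb` knowledge base.
#' @return List of the record's matching documents (possibly empty).
#' @export
detect_locations <- function(record, target, kb) {
  if (!target %in% names(kb$locations)) {
    stop("unknown extraction target '", target, "'", call. = FALSE)
  }
  types <- kb$locations[[target]]
  Filter(function(d) d$doc_type %in% types, record$documents)
}

# clinical section headers used to annotate provenance; mentions in a
# past-history section still need a temporality trigger to become historical
SECTION_HEADERS <- list(
  chief_complaint = c("chief complaint", "主诉"),
  present_history = c("history of present illness", "present illness",
                      "现病史"),
  past_history = c("past medical history", "既往史")
)

section_spans <- function(text) {
  hits <- list()
  for (nm in names(SECTION_HEADERS)) {
    for (pat in SECTION_HEADERS[[nm]]) {
      m <- gregexpr(pat, text, perl = TRUE, ignore.case = TRUE)[[1]]
      if (m[1] == -1L) next
      hits[[length(hits) + 1L]] <- data.frame(
        section = nm, start = as.integer(m) - 1L, stringsAsFactors = FALSE)
    }
  }
  if (!length(hits)) {
    return(data.frame(section = character(0), start = integer(0),
                      end = integer(0), stringsAsFactors = FALSE))
  }
  hits <- do.call(rbind, hits)
  hits <- hits[order(hits$start), , drop = FALSE]
  hits$end <- c(hits$start[-1], nchar(text))
  hits
}

# full per-document inference: sentences -> mentions -> context -> sentence
# conclusions -> document conclusion, plus provenance of positive sentences.
# Structured fields are scanned with the same lexicon; their mentions carry
# default (affirmed/present/confirmed) context.
conclude_document <- function(doc, kb, combined = NULL) {
  if (is.null(combined)) combined <- concept_pattern(kb)
  has_text_hit <- nzchar(doc$text) &&
    grepl(combined, doc$text, perl = TRUE, ignore.case = TRUE)
  if (!has_text_hit && is.null(doc$structured_fields)) {
    return(list(conclusion = NOT_MENTIONED_DF, provenance = EMPTY_PROVENANCE_DF))
  }
  provenance <- list()
  sentence_conclusions <- list()

  if (has_text_hit) {
    sentences <- segment_sentences(doc$text)
    sections <- section_spans(doc$text)
    for (i in seq_len(nrow(sentences))) {
      mentions <- recognize_entities(sentences$text[i], kb)
      if (!nrow(mentions)) next
      mentions <- detect_context(sentences$text[i], mentions, kb)
      concl <- infer_sentence(mentions, kb)
      sentence_conclusions[[length(sentence_conclusions) + 1L]] <- concl
      pos <- concl$concept[concl$status == "positive"]
      for (cname in pos) {
        sec <- NA_character_
        if (nrow(sections)) {
          in_sec <- sections$start <= sentences$start[i] &
            sentences$start[i] < sections$end
          if (any(in_sec)) sec <- sections$section[which(in_sec)[1]]
        }
        provenance[[length(provenance) + 1L]] <- data.frame(
          doc_id = doc$doc_id, concept = cname,
          start = sentences$start[i], end = sentences$end[i],
          section = sec, stringsAsFactors = FALSE)
      }
    }
  }

  for (field in names(doc$structured_fields)) {
    for (value in doc$structured_fields[[field]]) {
      mentions <- recognize_entities(value, kb)
      if (!nrow(mentions)) next
      mentions$polarity <- "affirmed"
      mentions$temporality <- "present"
      mentions$certainty <- "confirmed"
      concl <- infer_sentence(mentions, kb)
      sentence_conclusions[[length(sentence_conclusions) + 1L]] <- concl
      for (cname in concl$concept[concl$status == "positive"]) {
        provenance[[length(provenance) + 1L]] <- data.frame(
          doc_id = doc$doc_id, concept = cname,
          start = NA_integer_, end = NA_integer_,
          section = field, stringsAsFactors = FALSE)
      }
    }
  }

  stacked <- if (length(sentence_conclusions)) {
    do.call(rbind, sentence_conclusions)
  } else {
    data.frame(concept = character(0), status = character(0),
               stringsAsFactors = FALSE)
  }
  list(
    conclusion = infer_document(stacked),
    provenance = if (length(provenance)) do.call(rbind, provenance) else
      EMPTY_PROVENANCE_DF
  )
}

#' Run the full pipeline on one patient record
#'
#' Applies location detection, sentence segmentation, entity recognition,
#' context detection, and sentence/document inference per extraction
#' target, then computes the patient-level derived variables with the
#' knowledge-base expressions. The defining identity of new-onset
#' in-hospital VTE is `in_hospital = discharged AND NOT admission`,
#' per concept and overall.
#'
#' @param record A `vte_record`.
#' @param kb A `vte_kb` knowledge base.
#' @return An object of class `vte_conclusion`: a list with `patient_id`,
#'   `flags` (named logical vector: the four document-level aggregates
#'   `admission_with_dvt`, `admission_with_pe`, `discharged_with_dvt`,
#'   `discharged_with_pe` plus every knowledge-base expression, e.g.
#'   `in_hospital_vte`), and `provenance` (data frame of contributing
#'   positive sentences: `doc_id`, `concept`, `start`, `end`, `section`).
#' @param .combined Internal: precompiled combined lexicon pattern, used by
#'   [detect_corpus()] to avoid rebuilding it per record.
#' @export
infer_patient <- function(record, kb, .combined = NULL) {
  rt <- kb_runtime(kb)
  if (is.null(.combined)) .combined <- rt$combined
  adm_docs <- detect_locations(record, "admission_with_vte", kb)
  dis_docs <- detect_locations(record, "discharged_with_vte", kb)

  conclude_many <- function(docs) lapply(docs, conclude_document, kb = kb,
                                         combined = .combined)
  adm <- conclude_many(adm_docs)
  dis <- conclude_many(dis_docs)

  any_positive <- function(conclusions, cname) {
    any(vapply(conclusions, function(x) {
      x$conclusion$status[x$conclusion$concept == cname] == "positive"
    }, logical(1)))
  }
  bindings <- list(
    admission_with_dvt = any_positive(adm, "DVT"),
    admission_with_pe = any_positive(adm, "PE"),
    discharged_with_dvt = any_positive(dis, "DVT"),
    discharged_with_pe = any_positive(dis, "PE")
  )
  for (nm in rt$order) {
    bindings[[nm]] <- eval_node(rt$asts[[nm]], bindings)
  }
  prov <- c(lapply(adm, `[[`, "provenance"), lapply(dis, `[[`, "provenance"))
  prov <- prov[vapply(prov, nrow, integer(1)) > 0L]
  structure(
    list(
      patient_id = record$patient_id,
      flags = vapply(bindings, isTRUE, logical(1)),
      provenance = if (length(prov)) do.call(rbind, prov) else EMPTY_PROVENANCE_DF
    ),
    class = "vte_conclusion"
  )
}

#' @export
print.vte_conclusion <- function(x, ...) {
  cat(sprintf("<patient %s conclusion>\n", x$patient_id))
  on <- names(x$flags)[x$flags]
  cat("  flags set:", if (length(on)) paste(on, collapse = ", ") else "(none)", "\n")
  cat(sprintf("  provenance: %d contributing span(s)\n", nrow(x$provenance)))
  invisible(x)
}

conclusion_flag <- function(concl, name, fallback) {
  if (name %in% names(concl$flags)) unname(concl$flags[name]) else fallback
}

#' Run the detector over a corpus of records
#'
#' One prediction row per record, in input order. A patient is positive for
#' a concept when it is concluded either on admission or at discharge;
#' `onset` is `on_admission` when the admission notes conclude VTE,
#' otherwise `in_hospital` when new-onset in-hospital VTE is concluded,
#' otherwise `none`. Records that fail inference yield a row of `NA`s and
#' are listed in the `"errors"` attribute.
#'
#' @param records List of `vte_record` objects (already cohort-filtered).
#' @param kb A `vte_kb` knowledge base; default bundled KB when `NULL`.
#' @param provenance Collect per-patient provenance? Default `FALSE`.
#' @return Data frame with columns `patient_id`, `pe`, `dvt`, `vte_any`,
#'   `onset`; attribute `"errors"` (data frame `patient_id`, `message`),
#'   and, when requested, attribute `"provenance"` (named list).
#' @export
detect_corpus <- function(records, kb = NULL, provenance = FALSE) {
  if (is.null(kb)) kb <- load_kb()
  kb <- prepare_kb(kb)
  combined <- kb_runtime(kb)$combined
  n <- length(records)
  out <- data.frame(
    patient_id = character(n), pe = rep(NA, n), dvt = rep(NA, n),
    vte_any = rep(NA, n), onset = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  errors <- list()
  prov <- if (provenance) vector("list", n) else NULL
  for (i in seq_len(n)) {
    rec <- records[[i]]
    out$patient_id[i] <- rec$patient_id
    concl <- tryCatch(infer_patient(rec, kb, .combined = combined),
                      error = function(e) e)
    if (inherits(concl, "error")) {
      errors[[length(errors) + 1L]] <- list(patient_id = rec$patient_id,
                                            message = conditionMessage(concl))
      next
    }
    adm_pe <- conclusion_flag(concl, "admission_with_pe", FALSE)
    adm_dvt <- conclusion_flag(concl, "admission_with_dvt", FALSE)
    dis_pe <- conclusion_flag(concl, "discharged_with_pe", FALSE)
    dis_dvt <- conclusion_flag(concl, "discharged_with_dvt", FALSE)
    adm_any <- conclusion_flag(concl, "admission_with_vte", adm_pe || adm_dvt)
    in_hosp <- conclusion_flag(concl, "in_hospital_vte",
                               (dis_pe || dis_dvt) && !adm_any)
    out$pe[i] <- adm_pe || dis_pe
    out$dvt[i] <- adm_dvt || dis_dvt
    out$vte_any[i] <- out$pe[i] || out$dvt[i]
    out$onset[i] <- if (adm_any) "on_admission" else if (in_hosp) "in_hospital" else "none"
    if (provenance) prov[[i]] <- concl$provenance
  }
  attr(out, "errors") <- if (length(errors)) {
    data.frame(patient_id = vapply(errors, `[[`, character(1), "patient_id"),
               message = vapply(errors, `[[`, character(1), "message"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(patient_id = character(0), message = character(0))
  }
  if (provenance) {
    names(prov) <- out$patient_id
    attr(out, "provenance") <- prov
  }
  out
}
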