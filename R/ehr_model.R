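#' Document types recognised by the pipeline
#'
#' The five clinical document types the extraction-location detector knows
#' about. Every [ehr_document()] carries exactly one of these.
#'
#' @format Character vector of length 5.
#' @export
DOC_TYPES <- c(
  "admission_note", "progress_note", "surgical_note",
  "discharge_summary", "imaging_report"
)

#' Construct a clinical document
#'
#' A single timestamped document belonging to one hospitalization: free text
#' (any script, including unsegmented Chinese) plus optional structured
#' fields such as a coded diagnosis list. Text may be empty only when at
#' least one structured field is present.
#'
#' @param doc_id Character identifier, unique within a patient record.
#' @param doc_type One of [DOC_TYPES].
#' @param timestamp ISO-8601 datetime string (timezone optional).
#' @param text Free text of the note (default `""`).
#' @param structured_fields Optional named list of character vectors,
#'   e.g. `list(discharge_diagnosis = c("..."))`.
#' @return An object of class `vte_document`.
#' @export
#' @examples
#' ehr_document("d1", "imaging_report", "2021-03-05T09:00:00",
#'              "CTPA: acute pulmonary embolism.")
ehr_document <- function(doc_id, doc_type, timestamp, text = "",
                         structured_fields = NULL) {
  doc <- structure(
    list(
      doc_id = as.character(doc_id),
      doc_type = as.character(doc_type),
      timestamp = as.character(timestamp),
      text = as.character(text),
      structured_fields = canonical_fields(structured_fields)
    ),
    class = "vte_document"
  )
  problems <- validate_document(doc)
  if (length(problems)) {
    stop("invalid document '", doc_id, "': ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  doc
}

# unvalidated constructors for code paths that build records from values
# already known to be well-formed (the synthetic generator); user-facing
# input always goes through ehr_document()/patient_record()/read_records()
new_document <- function(doc_id, doc_type, timestamp, text,
                         structured_fields = NULL) {
  structure(
    list(doc_id = doc_id, doc_type = doc_type, timestamp = timestamp,
         text = text, structured_fields = structured_fields),
    class = "vte_document"
  )
}

new_record <- function(patient_id, admission_time, discharge_time, department,
                       department_class, vte_risk_tier, age, sex, documents) {
  structure(
    list(patient_id = patient_id, admission_time = admission_time,
         discharge_time = discharge_time, department = department,
         department_class = department_class, vte_risk_tier = vte_risk_tier,
         age = age, sex = sex, documents = documents),
    class = "vte_record"
  )
}

canonical_fields <- function(fields) {
  if (is.null(fields) || length(fields) == 0L) return(NULL)
  if (is.null(names(fields)) || any(!nzchar(names(fields)))) {
    stop("structured_fields must be a named list", call. = FALSE)
  }
  lapply(fields, function(v) as.character(unlist(v, use.names = FALSE)))
}

validate_document <- function(doc) {
  problems <- character(0)
  if (!is.character(doc$doc_id) || length(doc$doc_id) != 1L || !nzchar(doc$doc_id)) {
    problems <- c(problems, "doc_id must be a non-empty string")
  }
  if (!doc$doc_type %in% DOC_TYPES) {
    problems <- c(problems,
                  sprintf("doc_type '%s' is not one of: %s", doc$doc_type,
                          paste(DOC_TYPES, collapse = ", ")))
  }
  if (is.na(parse_timestamp(doc$timestamp))) {
    problems <- c(problems, sprintf("timestamp '%s' is not ISO-8601", doc$timestamp))
  }
  if (!nzchar(doc$text) && is.null(doc$structured_fields)) {
    problems <- c(problems, "text may be empty only if structured_fields is non-empty")
  }
  problems
}

#' Parse an ISO-8601 timestamp
#'
#' Accepts `YYYY-MM-DDTHH:MM:SS` with optional fractional seconds and an
#' optional `Z`/numeric offset, or a bare date. Naive timestamps are ordered
#' as if UTC.
#'
#' @param x Character vector of timestamps.
#' @return `POSIXct` vector (UTC); `NA` where unparseable.
#' @export
parse_timestamp <- function(x) {
  x <- as.character(x)
  x <- sub("Z$", "+0000", x)
  x <- sub("([+-][0-9]{2}):([0-9]{2})$", "\\1\\2", x)
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = "UTC")
  for (fmt in c("%Y-%m-%dT%H:%M:%OS%z", "%Y-%m-%dT%H:%M:%OS",
                "%Y-%m-%d %H:%M:%OS", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(x[miss], format = fmt, tz = "UTC")
  }
  out
}

#' Construct a patient record
#'
#' One hospitalization: identifiers, admission/discharge timestamps,
#' department metadata (including the administratively assigned department
#' class and VTE-risk tier), demographics, and the list of typed clinical
#' documents. This is the unit of inference for the pipeline.
#'
#' @param patient_id Character identifier.
#' @param admission_time,discharge_time ISO-8601 datetime strings;
#'   `discharge_time` must not precede `admission_time`.
#' @param department Free-text department label.
#' @param department_class One of `"surgery"`, `"internal_medicine"`, `"icu"`.
#' @param vte_risk_tier One of `"low"`, `"intermediate"`, `"high"` (assigned
#'   from the department's historical VTE-related death rate: fewer than 1,
#'   1 to 5, or more than 5 deaths per year).
#' @param age Age in years.
#' @param sex `"female"` or `"male"`.
#' @param documents List of [ehr_document()] objects with unique `doc_id`s.
#' @return An object of class `vte_record`.
#' @export
patient_record <- function(patient_id, admission_time, discharge_time,
                           department, department_class, vte_risk_tier,
                           age, sex, documents = list()) {
  rec <- structure(
    list(
      patient_id = as.character(patient_id),
      admission_time = as.character(admission_time),
      discharge_time = as.character(discharge_time),
      department = as.character(department),
      department_class = as.character(department_class),
      vte_risk_tier = as.character(vte_risk_tier),
      age = as.numeric(age),
      sex = as.character(sex),
      documents = documents
    ),
    class = "vte_record"
  )
  problems <- validate_record(rec, eligibility = FALSE)
  if (length(problems)) {
    stop("invalid record '", patient_id, "': ", paste(problems, collapse = "; "),
         call. = FALSE)
  }
  rec
}

#' Validate a patient record
#'
#' Checks structural invariants (field types, enumerations, unique document
#' ids, timestamp ordering) and, when `eligibility = TRUE`, the cohort
#' eligibility rules as well (age at least 18 years and a hospital stay
#' longer than 24 hours).
#'
#' @param rec A `vte_record`.
#' @param eligibility Also report eligibility violations? Default `TRUE`.
#' @return Character vector of problems; empty when the record is valid.
#' @export
validate_record <- function(rec, eligibility = TRUE) {
  problems <- character(0)
  need <- c("patient_id", "admission_time", "discharge_time", "department",
            "department_class", "vte_risk_tier", "age", "sex", "documents")
  missing <- setdiff(need, names(rec))
  if (length(missing)) {
    return(sprintf("missing field '%s'", missing))
  }
  if (!nzchar(rec$patient_id)) problems <- c(problems, "patient_id must be non-empty")
  adm <- parse_timestamp(rec$admission_time)
  dis <- parse_timestamp(rec$discharge_time)
  if (is.na(adm)) problems <- c(problems, "admission_time is not ISO-8601")
  if (is.na(dis)) problems <- c(problems, "discharge_time is not ISO-8601")
  if (!is.na(adm) && !is.na(dis) && dis < adm) {
    problems <- c(problems, "discharge_time precedes admission_time")
  }
  if (!rec$department_class %in% c("surgery", "internal_medicine", "icu")) {
    problems <- c(problems, sprintf("department_class '%s' invalid", rec$department_class))
  }
  if (!rec$vte_risk_tier %in% c("low", "intermediate", "high")) {
    problems <- c(problems, sprintf("vte_risk_tier '%s' invalid", rec$vte_risk_tier))
  }
  if (is.na(rec$age) || rec$age < 0) problems <- c(problems, "age must be non-negative")
  if (!rec$sex %in% c("female", "male")) {
    problems <- c(problems, sprintf("sex '%s' invalid", rec$sex))
  }
  ids <- vapply(rec$documents, function(d) d$doc_id, character(1))
  if (anyDuplicated(ids)) {
    problems <- c(problems, sprintf("duplicate doc_id '%s'", ids[duplicated(ids)][1]))
  }
  for (d in rec$documents) problems <- c(problems, validate_document(d))
  if (eligibility && !length(problems)) {
    if (rec$age < 18) problems <- c(problems, "age below 18 years")
    if (as.numeric(difftime(dis, adm, units = "hours")) <= 24) {
      problems <- c(problems, "hospital stay of 24 hours or less (exclusion rule)")
    }
  }
  problems
}

record_from_list <- function(x) {
  docs <- lapply(x$documents, function(d) {
    ehr_document(d$doc_id, d$doc_type, d$timestamp,
                 if (is.null(d$text)) "" else d$text,
                 d$structured_fields)
  })
  patient_record(x$patient_id, x$admission_time, x$discharge_time,
                 x$department, x$department_class, x$vte_risk_tier,
                 x$age, x$sex, docs)
}

record_to_list <- function(rec) {
  out <- unclass(rec)
  out$documents <- lapply(rec$documents, function(d) {
    dl <- unclass(d)
    if (is.null(dl$structured_fields)) dl$structured_fields <- NULL
    dl
  })
  out
}

#' Read patient records from a JSON-Lines file
#'
#' One JSON object per line, UTF-8. Lines that fail to parse or violate the
#' record schema (including the eligibility rules: age at least 18 and stay
#' over 24 hours) are collected, with their line numbers and messages, in
#' the `"errors"` attribute of the result rather than aborting the read.
#'
#' @param path Path to a `.jsonl` file.
#' @param strict Abort on the first invalid line instead? Default `FALSE`.
#' @return List of `vte_record` objects; attribute `"errors"` is a data frame
#'   with columns `line` and `message` (zero rows when everything parsed).
#' @seealso [write_records()], [filter_cohort()]
#' @export
read_records <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  records <- vector("list", length(lines))
  errors <- list()
  keep <- logical(length(lines))
  for (i in seq_along(lines)) {
    if (!nzchar(trimws(lines[i]))) next
    parsed <- tryCatch(jsonlite::fromJSON(lines[i], simplifyVector = FALSE),
                       error = function(e) e)
    if (inherits(parsed, "error")) {
      msg <- sprintf("line %d: malformed JSON (%s)", i, conditionMessage(parsed))
      if (strict) stop(msg, call. = FALSE)
      errors[[length(errors) + 1L]] <- list(line = i, message = msg)
      next
    }
    rec <- tryCatch(record_from_list(parsed), error = function(e) e)
    problems <- if (inherits(rec, "error")) conditionMessage(rec) else {
      validate_record(rec, eligibility = TRUE)
    }
    if (length(problems)) {
      msg <- sprintf("line %d: %s", i, paste(problems, collapse = "; "))
      if (strict) stop(msg, call. = FALSE)
      errors[[length(errors) + 1L]] <- list(line = i, message = msg)
      next
    }
    records[[i]] <- rec
    keep[i] <- TRUE
  }
  out <- records[keep]
  attr(out, "errors") <- if (length(errors)) {
    data.frame(line = vapply(errors, `[[`, integer(1), "line"),
               message = vapply(errors, `[[`, character(1), "message"),
               stringsAsFactors = FALSE)
  } else {
    data.frame(line = integer(0), message = character(0))
  }
  out
}

#' Write patient records as JSON Lines
#'
#' Inverse of [read_records()]: `read_records(write_records(x, path))`
#' reproduces `x` field for field, including non-ASCII text.
#'
#' @param records List of `vte_record` objects.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_records <- function(records, path) {
  lines <- vapply(records, function(rec) {
    as.character(jsonlite::toJSON(record_to_list(rec), auto_unbox = TRUE,
                                  null = "null", digits = NA))
  }, character(1))
  con <- file(path, open = "wb")
  on.exit(close(con))
  if (length(lines)) writeLines(lines, con, useBytes = TRUE, sep = "\n")
  invisible(path)
}

#' Partition records into the analysis cohort and exclusions
#'
#' Applies the cohort rules: adults only (age at least 18), hospital stay
#' longer than 24 hours, and at least one document (the operational proxy
#' for "lacking diagnostic information"). Exclusion is not an error; each
#' excluded record is tagged with the first rule it failed.
#'
#' @param records List of `vte_record` objects.
#' @return List with `included` (list of records) and `excluded` (data frame
#'   with columns `patient_id`, `reason`). The two parts partition the
#'   input: every record appears in exactly one.
#' @export
filter_cohort <- function(records) {
  reasons <- vapply(records, function(rec) {
    if (rec$age < 18) return("age")
    stay <- as.numeric(difftime(parse_timestamp(rec$discharge_time),
                                parse_timestamp(rec$admission_time),
                                units = "hours"))
    if (is.na(stay) || stay <= 24) return("short stay")
    if (length(rec$documents) == 0L) return("no diagnostic information")
    ""
  }, character(1))
  excluded_idx <- which(nzchar(reasons))
  list(
    included = records[which(!nzchar(reasons))],
    excluded = data.frame(
      patient_id = vapply(records[excluded_idx], `[[`, character(1), "patient_id"),
      reason = reasons[excluded_idx],
      stringsAsFactors = FALSE
    )
  )
}

#' Read a reference-label file
#'
#' CSV with header `patient_id,vte_any,pe,dvt,onset`, where the boolean
#' columns are `true`/`false` (or `TRUE`/`FALSE`) and `onset` is one of
#' `on_admission`, `in_hospital`, `none`. Consistency rules are enforced:
#' `vte_any = pe OR dvt`, and `onset = none` exactly for label-negative
#' patients.
#'
#' @param path CSV path.
#' @return Data frame with columns `patient_id` (character), `vte_any`,
#'   `pe`, `dvt` (logical), `onset` (character).
#' @export
read_reference_labels <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, encoding = "UTF-8")
  need <- c("patient_id", "vte_any", "pe", "dvt", "onset")
  if (!all(need %in% names(df))) {
    stop("reference labels must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  df$patient_id <- as.character(df$patient_id)
  for (col in c("vte_any", "pe", "dvt")) {
    v <- df[[col]]
    if (!is.logical(v)) v <- tolower(as.character(v)) %in% c("true", "1", "t")
    df[[col]] <- v
  }
  bad_onset <- setdiff(unique(df$onset), c("on_admission", "in_hospital", "none"))
  if (length(bad_onset)) {
    stop("invalid onset value(s): ", paste(bad_onset, collapse = ", "), call. = FALSE)
  }
  if (any(df$vte_any != (df$pe | df$dvt))) {
    stop("label inconsistency: vte_any must equal pe OR dvt", call. = FALSE)
  }
  if (any((df$onset == "none") != !df$vte_any)) {
    stop("label inconsistency: onset must be 'none' exactly when vte_any is false",
         call. = FALSE)
  }
  df[need]
}

#' Write a reference-label file
#'
#' @param labels Data frame as returned by [read_reference_labels()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_reference_labels <- function(labels, path) {
  out <- labels
  for (col in c("vte_any", "pe", "dvt")) out[[col]] <- tolower(as.character(out[[col]]))
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @export
print.vte_record <- function(x, ...) {
  cat(sprintf("<patient %s> %s/%s tier, %s, age %g, %d document(s), %s to %s\n",
              x$patient_id, x$department_class, x$vte_risk_tier, x$sex, x$age,
              length(x$documents), x$admission_time, x$discharge_time))
  invisible(x)
}

#' @export
print.vte_document <- function(x, ...) {
  cat(sprintf("<document %s> %s @ %s, %d chars%s\n", x$doc_id, x$doc_type,
              x$timestamp, nchar(x$text),
              if (is.null(x$structured_fields)) "" else
                sprintf(", fields: %s", paste(names(x$structured_fields), collapse = ", "))))
  invisible(x)
}
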