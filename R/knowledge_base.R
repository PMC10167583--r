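# The knowledge base drives the whole rule engine: the concept lexicon and
# excluded anatomical sites, the context triggers (assertion rules), the
# extraction-location map, and the patient-level expressions. It is data,
# not code, so a site can drop in its own lexicon without touching R.

CONCEPTS <- c("DVT", "PE")
CONTEXT_DIMENSIONS <- c("polarity", "temporality", "certainty")
TRIGGER_VALUES <- c(polarity = "negated", temporality = "historical",
                    certainty = "suspected")
LOCATION_TARGETS <- c("admission_with_vte", "discharged_with_vte")

# document aggregates that the pipeline itself binds before expressions run
PIPELINE_OUTPUTS <- c("admission_with_dvt", "admission_with_pe",
                      "discharged_with_dvt", "discharged_with_pe")

EXPRESSION_KEYWORDS <- c("AND", "OR", "NOT", "UNION", "INTERSECT",
                         "DIFFERENCE", "COUNT", "TRUE", "FALSE")

#' Path to the bundled default knowledge base
#'
#' @return Path of the YAML file shipped with the package.
#' @export
default_kb_path <- function() {
  system.file("extdata", "default_kb.yaml", package = "vtenlp", mustWork = TRUE)
}

#' Load a VTE knowledge base
#'
#' Reads a YAML (or JSON) knowledge-base file with sections `concepts`,
#' `triggers`, `locations`, `expressions` and `options`, validates every
#' structural invariant (see [validate_kb()]) and returns the parsed object.
#' With `path = NULL` the bundled bilingual default is loaded.
#'
#' @param path Path to a KB file, or `NULL` for the bundled default.
#' @return An object of class `vte_kb`.
#' @export
#' @examples
#' kb <- load_kb()
#' names(kb$concepts)
load_kb <- function(path = NULL) {
  if (is.null(path)) path <- default_kb_path()
  if (!file.exists(path)) stop("knowledge base file not found: ", path, call. = FALSE)
  raw <- yaml::read_yaml(path)
  kb <- kb_from_list(raw)
  diagnostics <- validate_kb(kb)
  if (length(diagnostics)) {
    stop("invalid knowledge base (", path, "):\n  ",
         paste(diagnostics, collapse = "\n  "), call. = FALSE)
  }
  kb
}

kb_from_list <- function(raw) {
  concepts <- list()
  for (entry in raw$concepts) {
    concepts[[entry$concept]] <- list(
      terms = as.character(unlist(entry$terms)),
      excluded_site_terms = as.character(unlist(entry$excluded_site_terms))
    )
  }
  trig <- raw$triggers
  triggers <- data.frame(
    trigger_text = vapply(trig, function(t) as.character(t$trigger_text), character(1)),
    dimension = vapply(trig, function(t) as.character(t$dimension), character(1)),
    value = vapply(trig, function(t) as.character(t$value), character(1)),
    direction = vapply(trig, function(t) as.character(t$direction), character(1)),
    scope_window = vapply(trig, function(t) as.numeric(t$scope_window), numeric(1)),
    stringsAsFactors = FALSE
  )
  locations <- lapply(raw$locations, function(x) as.character(unlist(x)))
  expressions <- vapply(raw$expressions, as.character, character(1))
  options <- raw$options
  if (is.null(options)) options <- list()
  if (is.null(options$suspected_counts_as_positive)) {
    options$suspected_counts_as_positive <- TRUE
  }
  structure(
    list(concepts = concepts, triggers = triggers, locations = locations,
         expressions = expressions, options = options),
    class = "vte_kb"
  )
}

#' Validate a knowledge base
#'
#' Checks every structural invariant: concept names and non-empty term
#' lists, no term shared between concepts, trigger enumerations and positive
#' scope windows, the mandatory extraction-location map (admission
#' confirmation from admission notes only; discharge confirmation from
#' imaging reports, discharge summaries, progress notes and surgical notes),
#' and the expression section (only known names referenced, no cyclic
#' dependencies).
#'
#' @param kb A `vte_kb` object.
#' @return Character vector of diagnostics, each naming the violated rule
#'   and the offending entry; empty when all invariants hold.
#' @export
validate_kb <- function(kb) {
  diagnostics <- character(0)
  note <- function(...) diagnostics <<- c(diagnostics, sprintf(...))

  unknown <- setdiff(names(kb$concepts), CONCEPTS)
  for (u in unknown) note("concepts: unknown concept '%s'", u)
  for (cname in names(kb$concepts)) {
    if (length(kb$concepts[[cname]]$terms) == 0L) {
      note("concepts: '%s' has an empty term list", cname)
    }
  }
  if (length(kb$concepts) >= 2L) {
    all_terms <- lapply(kb$concepts, `[[`, "terms")
    dup <- Reduce(intersect, all_terms)
    for (d in dup) note("concepts: term '%s' appears under more than one concept", d)
  }

  tr <- kb$triggers
  for (i in seq_len(nrow(tr))) {
    if (!tr$dimension[i] %in% CONTEXT_DIMENSIONS) {
      note("triggers: '%s' has unknown dimension '%s'", tr$trigger_text[i], tr$dimension[i])
    } else if (!identical(tr$value[i], unname(TRIGGER_VALUES[tr$dimension[i]]))) {
      note("triggers: '%s' has value '%s' invalid for dimension '%s'",
           tr$trigger_text[i], tr$value[i], tr$dimension[i])
    }
    if (!tr$direction[i] %in% c("forward", "backward", "bidirectional")) {
      note("triggers: '%s' has unknown direction '%s'", tr$trigger_text[i], tr$direction[i])
    }
    if (is.na(tr$scope_window[i]) || tr$scope_window[i] <= 0) {
      note("triggers: '%s' must have scope_window > 0", tr$trigger_text[i])
    }
  }

  for (target in LOCATION_TARGETS) {
    if (is.null(kb$locations[[target]])) {
      note("locations: missing mandatory entry '%s'", target)
    }
  }
  if (!is.null(kb$locations$admission_with_vte) &&
      !setequal(kb$locations$admission_with_vte, "admission_note")) {
    note("locations: admission_with_vte must map to exactly {admission_note}")
  }
  discharge_set <- c("imaging_report", "discharge_summary", "progress_note", "surgical_note")
  if (!is.null(kb$locations$discharged_with_vte) &&
      !setequal(kb$locations$discharged_with_vte, discharge_set)) {
    note("locations: discharged_with_vte must map to exactly {%s}",
         paste(discharge_set, collapse = ", "))
  }

  known <- c(PIPELINE_OUTPUTS, names(kb$expressions))
  deps <- list()
  for (nm in names(kb$expressions)) {
    refs <- tryCatch(expression_names(kb$expressions[[nm]]),
                     error = function(e) {
                       note("expressions: '%s' does not parse (%s)", nm, conditionMessage(e))
                       character(0)
                     })
    unknown_refs <- setdiff(refs, known)
    for (u in unknown_refs) {
      note("expressions: '%s' references unknown name '%s'", nm, u)
    }
    deps[[nm]] <- intersect(refs, names(kb$expressions))
  }
  cycle <- find_cycle(deps)
  if (!is.null(cycle)) {
    note("expressions: cyclic dependency %s", paste(cycle, collapse = " -> "))
  }

  if (!is.logical(kb$options$suspected_counts_as_positive)) {
    note("options: suspected_counts_as_positive must be true or false")
  }
  diagnostics
}

# depth-first search for a cycle in the expression dependency graph;
# returns the cycle path or NULL
find_cycle <- function(deps) {
  state <- new.env(parent = emptyenv())
  for (nm in names(deps)) assign(nm, "white", envir = state)
  path <- character(0)
  visit <- function(nm) {
    assign(nm, "grey", envir = state)
    path <<- c(path, nm)
    for (dep in deps[[nm]]) {
      col <- get0(dep, envir = state, ifnotfound = "white")
      if (col == "grey") {
        return(c(path[which(path == dep)[1]:length(path)], dep))
      }
      if (col == "white" && !is.null(deps[[dep]])) {
        found <- visit(dep)
        if (!is.null(found)) return(found)
      }
    }
    assign(nm, "black", envir = state)
    path <<- path[-length(path)]
    NULL
  }
  for (nm in names(deps)) {
    if (get(nm, envir = state) == "white") {
      found <- visit(nm)
      if (!is.null(found)) return(found)
    }
  }
  NULL
}

# topological evaluation order for kb expressions (validated KBs are acyclic)
expression_order <- function(kb) {
  deps <- lapply(kb$expressions, function(e) {
    intersect(expression_names(e), names(kb$expressions))
  })
  ordered <- character(0)
  remaining <- names(deps)
  while (length(remaining)) {
    ready <- remaining[vapply(remaining, function(nm) {
      all(deps[[nm]] %in% ordered)
    }, logical(1))]
    if (!length(ready)) stop("cyclic expressions", call. = FALSE)
    ordered <- c(ordered, ready)
    remaining <- setdiff(remaining, ready)
  }
  ordered
}

# precompiled artefacts derived from a KB (combined lexicon pattern, parsed
# expression ASTs in evaluation order); cached on the object so corpus-scale
# runs pay the parse cost once
kb_runtime <- function(kb) {
  rt <- attr(kb, "runtime")
  if (!is.null(rt)) return(rt)
  list(
    combined = paste(unlist(lapply(kb$concepts, `[[`, "terms")), collapse = "|"),
    order = expression_order(kb),
    asts = lapply(kb$expressions, parse_expression)
  )
}

prepare_kb <- function(kb) {
  attr(kb, "runtime") <- kb_runtime(kb)
  kb
}

#' @export
print.vte_kb <- function(x, ...) {
  cat("<VTE knowledge base>\n")
  for (cname in names(x$concepts)) {
    cat(sprintf("  %s: %d term(s), %d excluded-site term(s)\n", cname,
                length(x$concepts[[cname]]$terms),
                length(x$concepts[[cname]]$excluded_site_terms)))
  }
  cat(sprintf("  triggers: %d (%s)\n", nrow(x$triggers),
              paste(sprintf("%s %d", names(table(x$triggers$dimension)),
                            as.integer(table(x$triggers$dimension))), collapse = ", ")))
  cat(sprintf("  expressions: %s\n", paste(names(x$expressions), collapse = ", ")))
  cat(sprintf("  suspected counts as positive: %s\n",
              x$options$suspected_counts_as_positive))
  invisible(x)
}
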