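---
title: "Detecting venous thromboembolism from clinical notes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting venous thromboembolism from clinical notes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(vtenlp)
```

## The problem

Venous thromboembolism (VTE) — deep vein thrombosis (DVT) and pulmonary
embolism (PE) — is a leading preventable cause of hospital death, and
hospitals are increasingly measured on how reliably they detect and manage
it. The gold standard for counting VTE events, manual chart review, does
not scale; administrative codes are only available after discharge and are
known to be unreliable. A rule-based natural-language-processing detector
that reads the documents already in the electronic record — admission
notes, progress notes, surgical notes, discharge summaries, imaging
reports — can flag events as they are documented, and distinguish events
present on admission from new-onset in-hospital events, which is the
quantity that hospital-acquired-VTE surveillance actually needs.

`vtenlp` implements such a detector as a transparent, fully configurable
rule pipeline, together with the diagnostic-accuracy statistics used to
validate one against chart review, and a synthetic-cohort generator so the
whole system can be exercised and audited without protected health data.

## The inference pipeline and its assumptions

Detection runs per patient record through seven stages; every stage's
behaviour is data in the knowledge base, not code.

**Location detection.** Admission-with-VTE conclusions are extracted from
admission notes only; discharged-with-VTE conclusions from imaging
reports, discharge summaries, progress notes, and surgical notes. This
split encodes the clinical reading of "on admission": what the admitting
clinician documented at entry versus what the hospitalization's record
shows by discharge.

**Sentence segmentation.** Sentences end at `.`, `!`, `?`, `;`, newline,
or their full-width counterparts. Two guards prevent false splits: a
period between two digits (decimal numbers such as `D-dimer 1.5 mg/L`),
and a period ending a known abbreviation (`e.g.`, `Dr.`, single
initials). Offsets are 0-based, half-open, counted in characters, so
spans index the original text exactly.

**Entity recognition.** The lexicon maps each concept (DVT, PE) to
case-insensitive Perl regular expressions; matching is over raw sentence
text, which behaves identically for unsegmented Chinese and for English.
All non-overlapping matches are returned, longest match first, so
`深静脉血栓形成` wins over its prefix `深静脉血栓`. A mention is marked
site-invalid when an excluded-site term (upper extremity, internal
jugular, superior/inferior vena cava and Chinese equivalents) occurs in
the same sentence: thrombosis at those sites does not count as valid VTE
for surveillance.

**Context (assertion) detection.** Triggers assert three dimensions per
mention — polarity (affirmed/negated), temporality (present/historical),
certainty (confirmed/suspected) — with NegEx-style directional scopes.
The bundled trigger inventories are documented defaults authored for this
package, not a published inventory from any deployed system; sites are
expected to tune them. A trigger reaches a mention when the character gap
between them is within its scope window; the nearest trigger wins within
each dimension; defaults are affirmed/present/confirmed. Scope windows
are measured in characters for both scripts (defaults: forward 30,
backward 15). A dual unit (tokens for spaced text, characters otherwise)
was considered and rejected: it would make assertion behaviour depend on
a language guess, and for the short gaps that matter the two units
behave almost identically.

**Sentence, document, patient inference.** A sentence concludes a concept
positive iff at least one mention is site-valid, affirmed, present, and
confirmed — or suspected, when the `suspected_counts_as_positive` option
is on (the default; see below). A document is positive for a concept if
any sentence is, else negative if any sentence mentions it, else
not-mentioned. The any-positive tie-break (an affirmed sentence dominates
a negated one elsewhere in the document) is deliberate: it maximizes
sensitivity, which is the posture surveillance systems take, and it is
consistent with the false-positive modes such systems exhibit in
practice. Patient-level flags are then computed by knowledge-base
expressions from the four document-level aggregates; the shipped defaults
encode the defining identity

```
in_hospital_vte = discharged_with_vte AND NOT admission_with_vte
```

so "new-onset in-hospital VTE" is exactly "concluded by discharge but not
on admission". The expression language (boolean logic, arithmetic,
comparison, and set operations with `COUNT`) is a deliberately small DSL:
keeping aggregation in configuration means a site can redefine, say, what
counts as admission-with-VTE without touching code. Structured fields
(e.g. a coded diagnosis list) are scanned with the same lexicon and enter
as mentions with default context — a coded diagnosis is taken at face
value.

**Degenerate inputs.** Empty text yields no sentences; a document with
neither text nor structured fields is rejected at construction; records
failing the schema or the eligibility rules (age under 18, stay of 24
hours or less, no documents) are collected with line numbers on read and
partitioned with reasons by `filter_cohort()`. The "no documents" rule is
the package's operational proxy for records lacking diagnostic
information; it is a proxy, and flagged as such here.

## Key options

| Parameter | Default | Why |
|---|---|---|
| `suspected_counts_as_positive` | `TRUE` | Deployed rule systems assert uncertain mentions; their leading false-positive mode is "suspected, later disproved". The default reproduces that behaviour; set `FALSE` for a stricter detector. |
| forward / backward trigger scope | 30 / 15 characters | Negation and temporality cues mostly sit immediately left of the concept in both languages; backward cues ("ruled out", "待排") sit tight to it. Tunable per trigger. |
| location map | fixed | Admission conclusions from admission notes only; discharge conclusions from the other four types. The map is validated, not silently overridable, because the on-admission/in-hospital split depends on it. |

## What the synthetic generator emulates — and what it does not

`generate_corpus()` draws a hospital cohort with the department mix
(45.1% surgery, 52% internal medicine, 2.9% ICU), per-department VTE
prevalence (0.6% / 2.7% / 14.5%), PE/DVT composition (28.3% / 85.0% of
events, overlapping), sex ratio (47.3% female) and age distribution
(log-normal matched to median 56, IQR 41–67) of a large tertiary-hospital
validation cohort, giving an overall event rate near 2.1%. The fraction
of events already present on admission is not published for that cohort;
the default 0.8 is a declared assumption chosen because most clinically
recognised VTE in a general inpatient population is documented at entry.
Department class is mapped monotonically to the VTE-risk tier (surgery →
low, internal medicine → intermediate, ICU → high); this is a
simplification — in reality tiers are assigned per department from
historical death counts and cut across classes.

Notes are rendered from short English/Chinese templates containing
exactly one assertion-controlled mention region, so every corpus is
parseable by the bundled knowledge base by construction. Error modes then
rewrite narratives while leaving labels untouched, reproducing the
documented failure taxonomy of such detectors at its observed rates
(per-negative: suspected-then-disproved 29/29,526, untriggered prior-VTE
wording 23/29,526; per-positive: undocumented calf-vein events 44/626,
modified admission diagnosis 12/626, unrecognised iliac wording 7/626 — a
70/19/11 split of forced false negatives). The "modified admission
diagnosis" cause also produces a small number of false positives in
practice (3 cases in the reference taxonomy); the generator models it on
the false-negative side only, where its rate is an order of magnitude
larger.

What passing tests on this corpus shows is that the pipeline implements
its stated rules exactly (on a zero-noise corpus, sensitivity and
specificity are identically 1) and that its failure behaviour under the
configured error modes matches the configured proportions. What it does
not show is performance on real notes: real narratives are longer,
messier, use wording outside any fixed template bank, and contain
assertion constructions (double negation, conditional phrasing, temporal
reconciliation across documents) that templates do not exercise. The
generator validates the machinery, not the lexicon's clinical coverage.

## Statistical methods and numerical choices

**Proportions.** Sensitivity, specificity, PPV, NPV and prevalence get
exact Clopper–Pearson intervals by default. The exact interval — not
Wilson — reproduces printed clinical-report intervals for this kind of
validation (for 563/626 it gives 87.3%–92.2%; Wilson's upper bound is
92.0%); Wilson remains available as `method = "wilson"` and is the
variant whose ~95% coverage the calibration tests verify.

**Likelihood ratios.** LR+ and LR− get delta-method intervals on the log
scale (the Simel variance, a sum of two binomial terms). When a defining
cell is zero the log-variance is undefined; the fallback is a smoothed
parametric bootstrap drawing each margin from its Jeffreys posterior
Beta(k + ½, n − k + ½). Plain resampling of a margin at an observed
proportion of exactly 1 would be degenerate (every replicate identical);
the Jeffreys draw keeps the interval defined and non-degenerate for a
detector with 100% sensitivity, where the LR− interval's lower bound is 0
at reporting precision and its upper bound stays positive.

**AUC.** A binary detector has a one-point ROC curve, so
AUC = (sensitivity + specificity)/2; its interval uses the delta method
over the two independent binomial variances. AUC comparison uses the
DeLong placement-value test (rank-based, tie-aware), with the covariance
term for paired predictions and a zero-covariance variance sum for
independent strata. The implementation is checked in the test suite
against an independent reference implementation on continuous scores.

**F1 and kappa.** F1 intervals and the F1 comparison z-test use bootstrap
standard errors (multinomial resampling of the table, or paired/unpaired
patient resampling), since F1 has no standard closed-form interval.
Cohen's kappa uses the large-sample standard error
`sqrt(po(1−po)/n)/(1−pe)` with truncation to [−1, 1].

**Comparing strata.** The relative diagnostic likelihood ratio test
compares two independent strata's LRs on the log scale with summed
delta-method variances; with a zero cell it falls back to the smoothed
bootstrap, taking the p-value from the percentile position of ratio = 1.
Categorical tables use the Pearson chi-square without continuity
correction — the convention of clinical baseline tables, and the variant
that reproduces printed cohort p-values — switching to the Fisher exact
test whenever an expected cell is below 5. Multiplicity across pairwise
stratum comparisons is handled by Bonferroni (`alpha/m`, adjusted
p = min(1, p·m)). P-values print in clinical style: two decimals, three
below .01, `<.001` below .001.

**Undefined quantities** (a likelihood ratio with a zero denominator,
kappa with degenerate margins, metrics of an empty class) are reported as
flagged `NA`s with a reason — never silently dropped, never an exception.

**Determinism.** Every stochastic component (bootstraps, the generator,
error injection) takes an explicit seed and restores the caller's RNG
state, so corpora and intervals are bit-reproducible.

## Problem sizes

The test suite exercises the sentence/document/patient rules against
brute-force oracles over the full assertion cross-product (all 17
sentence variants, all 289 two-sentence documents and admission×discharge
pairings, a seeded sample of three-sentence documents), runs the
end-to-end exactness check at 10,000 patients, and calibrates interval
coverage and test size with 2,000 simulated tables at n = 1,000. The
acceptance script uses 10,000 patients for the zero-noise check and
three replicate 100,000-patient cohorts for estimating the
false-negative reason split, the latter because that split is a
proportion over the rare missed events (~2 per 1,000 patients) and needs
several hundred of them for a stable estimate.

## Known limitations

- Each document is asserted independently; there is no temporal
  reconciliation (a suspected mention is not resolved by a later negative
  imaging report). Real systems may reconcile; this divergence is
  deliberate and documented.
- The "present medical history" section of admission notes is recognised
  (for provenance annotation) but mentions inside any section still need
  an explicit temporality trigger to be marked historical.
- The bundled lexicon and trigger inventories are starting defaults; any
  serious deployment must replace them with a site-curated knowledge
  base, which is exactly what the KB-as-data design is for.
- Trigger scope is linear distance in characters; clause structure,
  double negation, and cross-sentence anaphora are out of scope for a
  rule matcher of this design.
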