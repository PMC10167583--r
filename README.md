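# vtenlp

Rule-based detection of venous thromboembolism (VTE) from multi-document
electronic health records, with the diagnostic-accuracy statistics used to
validate such detectors against manual chart review.

## Who this is for

Hospital quality teams and clinical-informatics researchers who need to
flag deep vein thrombosis (DVT) and pulmonary embolism (PE) from inpatient
notes — admission notes, progress notes, surgical notes, discharge
summaries, and imaging reports — and to report how well the detector
performs overall and across departments, risk tiers, and demographic
subgroups. Real EHR corpora are protected, so the package also ships a
seeded synthetic-cohort generator that emulates a realistic hospital
population (department mix, per-department VTE prevalence, bilingual
English/Chinese notes) together with the characteristic failure modes of
deployed rule systems, making every pipeline stage testable without any
patient data.

## The method

Detection is a seven-component inference pipeline driven by a
configurable knowledge base (lexicon, context triggers, location map,
expressions):

1. **Location detection** — admission-with-VTE is read from admission
   notes only; discharged-with-VTE from imaging reports, discharge
   summaries, progress notes, and surgical notes.
2. **Sentence segmentation** — boundary characters with decimal and
   abbreviation guards; works on unsegmented Chinese.
3. **Entity recognition** — case-insensitive lexicon/regex matching for
   DVT and PE, longest match first; mentions qualified by an excluded
   anatomical site (upper extremity, internal jugular, vena cava) are
   marked invalid.
4. **Context detection** — NegEx-style triggers assert each mention on
   three dimensions: polarity (affirmed/negated), temporality
   (present/historical), certainty (confirmed/suspected), nearest trigger
   winning within its directional scope window.
5. **Sentence inference** — a concept is positive in a sentence iff some
   mention is site-valid, affirmed, present, and confirmed (or suspected,
   under the default option).
6. **Document inference** — any positive sentence makes the document
   positive; else any mention makes it negative.
7. **Patient inference** — document conclusions aggregate to
   `admission_with_*` and `discharged_with_*` flags, and knowledge-base
   expressions derive the rest, in particular the defining identity

   ```
   in_hospital_vte = discharged_with_vte AND NOT admission_with_vte
   ```

Evaluation against a manual reference standard covers sensitivity,
specificity, PPV, NPV (exact binomial CIs), positive/negative likelihood
ratios LR+ = sens/(1−spec) and LR− = (1−sens)/spec (log-method CIs, with a
smoothed bootstrap when a cell is zero), AUC (for a binary detector,
(sens+spec)/2) with the DeLong test, F1 with a bootstrap z test, Cohen's
kappa, the relative diagnostic likelihood ratio test for comparing strata,
chi-square/Fisher selection for categorical tables, and Bonferroni
adjustment for multiple comparisons.

## Worked example

```r
library(vtenlp)

# simulate a small hospital cohort, run the detector, evaluate
corpus <- generate_corpus(sim_config(n_patients = 2000, seed = 42))
kb  <- load_kb()                               # bundled bilingual KB
pred <- detect_corpus(corpus$records, kb)
cm  <- confusion_matrix(pred, corpus$labels)
diagnostic_metrics(cm)
```

```
Diagnostic report (n = 2000; TP 32, FP 4, FN 5, TN 1959)
  sensitivity  86.5% (95% CI 71.2%-95.5%)
  specificity  99.8% (95% CI 99.5%-99.9%)
  ppv          88.9% (95% CI 73.9%-96.9%)
  npv          99.7% (95% CI 99.4%-99.9%)
  lr_pos      424 (95% CI 158-1140)
  lr_neg      0.135 (95% CI 0.0599-0.306)
  auc         0.931 (95% CI 0.876-0.987)
  f1          0.877 (95% CI 0.788-0.949)
  kappa       0.874 (95% CI 0.793-0.956)
  prevalence    1.8% (95% CI 1.3%-2.5%)
```

The simulated prevalence (1.8%) reflects the configured department mix and
per-department event rates; the misses and false alarms come from the
injected error modes (undocumented calf-vein events, prior-VTE wording,
suspected-then-disproved admissions). With
`error_mode_rates = no_error_rates()` the detector is exact on its own
synthetic corpus — sensitivity and specificity are both 1.

A 2×2 table from a published validation can be analysed directly:

```r
diagnostic_metrics(vte_confusion(tp = 563, fp = 55, fn = 63, tn = 29471))
```

Command-line entry points wrap the same functions
(`inst/cli/vtenlp.R detect|evaluate|simulate`), reading JSON-Lines patient
records and writing prediction CSVs and stratified TSV/JSON reports.

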