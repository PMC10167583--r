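# Default bilingual VTE knowledge base.
#
# Terms and triggers are case-insensitive Perl regular expressions matched
# against raw sentence text, so they behave identically for unsegmented
# Chinese and for English. Trigger scopes are measured in characters from
# the edge of the trigger match to the edge of the concept match.
#
# These trigger inventories are NegEx-style documented defaults authored for
# this package; they are not a published inventory from any deployed system.
# Sites excluded from valid VTE: upper extremity, internal jugular vein,
# and superior or inferior vena cava.

concepts:
  - concept: DVT
    terms:
      - 'deep vein thrombos\w*'
      - 'deep venous thrombos\w*'
      - '\bDVT\b'
      - '深静脉血栓形成'
      - '深静脉血栓'
      - '下肢静脉血栓'
    excluded_site_terms:
      - 'upper extremity'
      - 'upper limb'
      - 'internal jugular'
      - 'jugular vein'
      - 'superior vena cava'
      - 'inferior vena cava'
      - '上肢'
      - '颈内静脉'
      - '上腔静脉'
      - '下腔静脉'
  - concept: PE
    terms:
      - 'pulmonary embol\w*'
      - 'pulmonary thromboembol\w*'
      - '\bPE\b'
      - '肺栓塞'
      - '肺血栓栓塞'
      - '肺动脉栓塞'
    excluded_site_terms: []

triggers:
  # polarity: negated
  - {trigger_text: 'no evidence of',      dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: 'no signs? of',        dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: 'without evidence of', dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: 'negative for',        dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: '\bno\b',              dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: '\bdenies\b',          dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: '未见',                dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: '无明显',              dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: '(?<![不能未])排除',   dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: '不考虑',              dimension: polarity, value: negated, direction: forward,  scope_window: 30}
  - {trigger_text: 'ruled out',           dimension: polarity, value: negated, direction: backward, scope_window: 15}
  - {trigger_text: 'is excluded',         dimension: polarity, value: negated, direction: backward, scope_window: 15}
  - {trigger_text: 'not demonstrated',    dimension: polarity, value: negated, direction: backward, scope_window: 15}
  - {trigger_text: '已排除',              dimension: polarity, value: negated, direction: backward, scope_window: 15}
  # temporality: historical
  - {trigger_text: 'history of',          dimension: temporality, value: historical, direction: forward,  scope_window: 30}
  - {trigger_text: '\bprior\b',           dimension: temporality, value: historical, direction: forward,  scope_window: 30}
  - {trigger_text: '\bprevious\b',        dimension: temporality, value: historical, direction: forward,  scope_window: 30}
  - {trigger_text: '既往',                dimension: temporality, value: historical, direction: forward,  scope_window: 30}
  - {trigger_text: '陈旧性?',             dimension: temporality, value: historical, direction: forward,  scope_window: 30}
  - {trigger_text: 'years? ago',          dimension: temporality, value: historical, direction: backward, scope_window: 15}
  - {trigger_text: '病史',                dimension: temporality, value: historical, direction: backward, scope_window: 15}
  # certainty: suspected
  - {trigger_text: '\bsuspected\b',       dimension: certainty, value: suspected, direction: forward,  scope_window: 30}
  - {trigger_text: 'suspicion of',        dimension: certainty, value: suspected, direction: forward,  scope_window: 30}
  - {trigger_text: '\bpossible\b',        dimension: certainty, value: suspected, direction: forward,  scope_window: 30}
  - {trigger_text: '\bprobable\b',        dimension: certainty, value: suspected, direction: forward,  scope_window: 30}
  - {trigger_text: '疑似',                dimension: certainty, value: suspected, direction: forward,  scope_window: 30}
  - {trigger_text: '可疑',                dimension: certainty, value: suspected, direction: forward,  scope_window: 30}
  - {trigger_text: '不除外',              dimension: certainty, value: suspected, direction: forward,  scope_window: 30}
  - {trigger_text: '不能除外',            dimension: certainty, value: suspected, direction: forward,  scope_window: 30}
  - {trigger_text: '不能排除',            dimension: certainty, value: suspected, direction: forward,  scope_window: 30}
  - {trigger_text: '待排',                dimension: certainty, value: suspected, direction: backward, scope_window: 15}
  - {trigger_text: 'cannot be excluded',  dimension: certainty, value: suspected, direction: backward, scope_window: 15}

locations:
  admission_with_vte: [admission_note]
  discharged_with_vte: [imaging_report, discharge_summary, progress_note, surgical_note]

# Patient-level derived variables, computed from the four document-level
# aggregates (admission_with_dvt, admission_with_pe, discharged_with_dvt,
# discharged_with_pe) by the expression engine. New-onset in-hospital VTE is
# defined as discharged-with minus on-admission.
expressions:
  admission_with_vte: 'admission_with_dvt OR admission_with_pe'
  discharged_with_vte: 'discharged_with_dvt OR discharged_with_pe'
  in_hospital_dvt: 'discharged_with_dvt AND NOT admission_with_dvt'
  in_hospital_pe: 'discharged_with_pe AND NOT admission_with_pe'
  in_hospital_vte: 'discharged_with_vte AND NOT admission_with_vte'

options:
  # A mention asserted as suspected (uncertain) still counts toward a
  # positive sentence conclusion. This mirrors observed behaviour of
  # deployed rule systems, whose leading false-positive mode is "initially
  # suspected, subsequently disproved"; set to false for a stricter system.
  suspected_counts_as_positive: true
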