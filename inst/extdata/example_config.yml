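# Example pipeline configuration: synthetic cohort of 2039 participants,
# full outcome validation.
input:
  generator:
    n: 2039
seed: 1
include_language: true
outcomes:
  - ed_visits_2plus
  - any_admission
  - admission_via_ed
  - ed_system_reasons
  - sf12_decline
  - problem_worse_delay
  - felt_abandoned
  - unmet_need
ratio_threshold: 1.75
threshold_candidates: [1, 2, 3, 4]
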