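parameters:
- name: p_gen_mort
  point: 0.055
  ci_low: ~
  ci_high: ~
  source: population life table
- name: p_cirr_mort
  point: 0.027
  ci_low: ~
  ci_high: ~
  source: cirrhosis natural history
- name: p_prog_mort
  point: 0.746
  ci_low: 0.573
  ci_high: 0.843
  source: untreated progressive HCC
- name: p_periop_mort
  point: 0.033
  ci_low: 0.011
  ci_high: 0.054
  source: resection series
- name: p_incomplete_resection
  point: 0.114
  ci_low: 0.06
  ci_high: 0.216
  source: resection series
- name: p_annual_recurrence
  point: 0.245
  ci_low: 0.186
  ci_high: 0.303
  source: post-resection recurrence
- name: p_recurrence_progression
  point: 0.235
  ci_low: 0.224
  ci_high: 0.243
  source: recurrent HCC progression
- name: p_tace_cr
  point: 0.156
  ci_low: 0.025
  ci_high: 0.406
  source: TACE response
- name: p_tace_pr
  point: 0.494
  ci_low: 0.268
  ci_high: 0.725
  source: TACE response
- name: p_tace_sd
  point: 0.202
  ci_low: 0.072
  ci_high: 0.263
  source: TACE response
- name: p_tace_pd
  point: 0.148
  ci_low: 0.09
  ci_high: 0.269
  source: TACE response
- name: p_cr_recurrence
  point: 0.663
  ci_low: 0.576
  ci_high: 0.75
  source: post-CR recurrence
- name: p_response_to_pd
  point: 0.127
  ci_low: ~
  ci_high: ~
  source: response-to-progression
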