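# Scoring key for the 20-item blatant/subtle prejudice questionnaire.
# The reverse-keyed set is configurable; this default reverse-keys the
# positively worded subscales (intimacy, positive emotions). Edit and load
# with read_scale_key().
items:
  - {item_id: b01, scale: blatant, subscale: threat_reject, reverse_keyed: false}
  - {item_id: b02, scale: blatant, subscale: threat_reject, reverse_keyed: false}
  - {item_id: b03, scale: blatant, subscale: threat_reject, reverse_keyed: false}
  - {item_id: b04, scale: blatant, subscale: threat_reject, reverse_keyed: false}
  - {item_id: b05, scale: blatant, subscale: threat_reject, reverse_keyed: false}
  - {item_id: b06, scale: blatant, subscale: threat_reject, reverse_keyed: false}
  - {item_id: b07, scale: blatant, subscale: intimacy, reverse_keyed: true}
  - {item_id: b08, scale: blatant, subscale: intimacy, reverse_keyed: true}
  - {item_id: b09, scale: blatant, subscale: intimacy, reverse_keyed: true}
  - {item_id: b10, scale: blatant, subscale: intimacy, reverse_keyed: true}
  - {item_id: s01, scale: subtle, subscale: traditional_values, reverse_keyed: false}
  - {item_id: s02, scale: subtle, subscale: traditional_values, reverse_keyed: false}
  - {item_id: s03, scale: subtle, subscale: traditional_values, reverse_keyed: false}
  - {item_id: s04, scale: subtle, subscale: traditional_values, reverse_keyed: false}
  - {item_id: s05, scale: subtle, subscale: cultural_differences, reverse_keyed: false}
  - {item_id: s06, scale: subtle, subscale: cultural_differences, reverse_keyed: false}
  - {item_id: s07, scale: subtle, subscale: cultural_differences, reverse_keyed: false}
  - {item_id: s08, scale: subtle, subscale: cultural_differences, reverse_keyed: false}
  - {item_id: s09, scale: subtle, subscale: positive_emotions, reverse_keyed: true}
  - {item_id: s10, scale: subtle, subscale: positive_emotions, reverse_keyed: true}
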