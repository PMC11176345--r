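eligibility:
  HAP:
    cohort: HAP
    required_forms:
    - baseline
    - discharge
    require_consent: yes
    require_case_review: no
  POP:
    cohort: POP
    required_forms:
    - initial-interview
    - on-site
    require_consent: yes
    require_case_review: no
  SUEP:
    cohort: SUEP
    required_forms:
    - baseline
    - discharge
    require_consent: yes
    require_case_review: yes
bio:
- sample_type: pbmc
  min_aliquots: 2
  item_id: pbmc
img:
- modality: echo
  require_upload: yes
  item_id: echo
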