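ecrf_item_id,reimbursement_item_id,condition,reviewed
crf-doc-screening-baseline,doc-screening-baseline,plausibility-pass,TRUE
crf-doc-ward,doc-ward,plausibility-pass,TRUE
crf-doc-icu,doc-icu,plausibility-pass,TRUE
crf-doc-clinical-status,doc-clinical-status,plausibility-pass,TRUE
crf-ecg,ecg,plausibility-pass,TRUE
crf-spirometry,spirometry,plausibility-pass,TRUE
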