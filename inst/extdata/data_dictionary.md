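# Export data dictionary

All exports are UTF-8 CSV with comma separators, dot decimals and ISO-8601
dates; an equivalent JSON-lines form (`.jsonl`) uses identical field names.
All person-level identifiers are per-system pseudonyms issued by the trusted
third party; no identity fields exist in any schema.

## ecrf.csv — clinical documentation (anchor system)

| column | type | meaning |
|---|---|---|
| ecrf_pseudonym | text | per-case pseudonym of the eCRF system |
| centre_id | text | recruiting centre |
| visit_id | text | unique visit identifier |
| visit_type_id | text | visit type (baseline, ward-day, icu-day, discharge, fu-3mo, fu-12mo, pop-initial-interview, pop-onsite) |
| visit_date | date | visit date |
| form_id | text | eCRF form the record belongs to |
| item_id | text | eCRF data item (mapped to reimbursement items) |
| value | text | opaque documented value |
| submitted | logical | form pages submitted by the centre |
| plausibility_pass | logical | automated plausibility/completeness check |
| case_review_pass | logical | local case review of the sub-form |
| consent_registered | logical | informed consent registered (case level) |

The key (ecrf_pseudonym, visit_id, form_id, item_id) is unique.

## biosamples.csv — biosampling registry

| column | type | meaning |
|---|---|---|
| bio_pseudonym | text | per-case pseudonym of the biosampling system |
| visit_id | text | visit the sample belongs to |
| sample_type | text | sample type (e.g. pbmc) |
| aliquot_count | integer >= 0 | registered aliquots |
| registered | logical | sample registered in the biobank |

## imaging.csv — imaging upload metadata

| column | type | meaning |
|---|---|---|
| img_pseudonym | text | per-case pseudonym of the imaging system |
| visit_id | text | visit the series belongs to |
| modality | text | imaging modality (e.g. echo) |
| series_count | integer >= 0 | uploaded series |
| uploaded | logical | upload completed |

## centres.csv — centre registry

| column | type | meaning |
|---|---|---|
| centre_id | text | centre identifier |
| display_letter | text | A-Z pseudonym, unique within cohort |
| cohort | text | HAP, POP or SUEP |
| centre_class | text | AMC or non-AMC |
| target_cases | number >= 0 | targeted case number (fractional allowed) |

## linkage.csv — trusted-third-party pseudonym linkage

| column | type | meaning |
|---|---|---|
| case_id | text | reimbursement case identifier |
| ecrf_pseudonym | text | eCRF pseudonym of the case |
| bio_pseudonym | text, optional | biosampling pseudonym |
| img_pseudonym | text, optional | imaging pseudonym |

Each system pseudonym maps to at most one case. Cases without any eCRF
record are not reimbursable; their biosampling/imaging records are reported
as orphans.
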