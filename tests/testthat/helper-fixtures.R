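# Shared fixtures, built in code at test time.

CAT <- default_catalogue()
RULES <- default_rules()
MAPPING <- default_mapping(CAT, RULES)

# A tiny hand-built export set: one SUEP AMC centre, three cases.
#  - CASE-A: complete, everything passes
#  - CASE-B: baseline + discharge submitted but one record fails case review
#  - CASE-C: discharge form never submitted
tiny_exports <- function() {
  ecrf_row <- function(pseud, visit, vt, date, form, item, submitted = TRUE,
                       plaus = TRUE, review = TRUE, consent = TRUE) {
    tibble::tibble(ecrf_pseudonym = pseud, centre_id = "C01",
                   visit_id = visit, visit_type_id = vt,
                   visit_date = as.Date(date), form_id = form,
                   item_id = item, value = "v1", submitted = submitted,
                   plausibility_pass = plaus, case_review_pass = review,
                   consent_registered = consent)
  }
  ecrf <- dplyr::bind_rows(
    ecrf_row("E-1", "A-V1", "baseline", "2021-01-04", "baseline",
             "crf-doc-screening-baseline"),
    ecrf_row("E-1", "A-V1", "baseline", "2021-01-04", "baseline", "crf-ecg"),
    ecrf_row("E-1", "A-V2", "ward-day", "2021-01-05", "ward-day",
             "crf-doc-ward"),
    ecrf_row("E-1", "A-V3", "discharge", "2021-01-06", "discharge",
             "crf-doc-clinical-status"),
    ecrf_row("E-1", "A-V3", "discharge", "2021-01-06", "discharge",
             "crf-ecg"),
    ecrf_row("E-2", "B-V1", "baseline", "2021-02-01", "baseline",
             "crf-doc-screening-baseline"),
    ecrf_row("E-2", "B-V2", "discharge", "2021-02-03", "discharge",
             "crf-doc-clinical-status", review = FALSE),
    ecrf_row("E-3", "C-V1", "baseline", "2021-03-01", "baseline",
             "crf-doc-screening-baseline"),
    ecrf_row("E-3", "C-V2", "discharge", "2021-03-04", "discharge",
             "crf-doc-clinical-status", submitted = FALSE))
  bio <- tibble::tibble(
    bio_pseudonym = c("B-1", "B-1"), visit_id = c("A-V1", "A-V1"),
    sample_type = c("pbmc", "pbmc"), aliquot_count = c(5L, 1L),
    registered = TRUE)
  imaging <- tibble::tibble(
    img_pseudonym = "I-1", visit_id = "A-V1", modality = "echo",
    series_count = 2L, uploaded = TRUE)
  centres <- tibble::tibble(centre_id = "C01", display_letter = "A",
                            cohort = "SUEP", centre_class = "AMC",
                            target_cases = 98.1)
  linkage <- tibble::tibble(
    case_id = c("CASE-A", "CASE-B", "CASE-C"),
    ecrf_pseudonym = c("E-1", "E-2", "E-3"),
    bio_pseudonym = c("B-1", NA, NA),
    img_pseudonym = c("I-1", NA, NA))
  list(ecrf = ecrf, biosamples = bio, imaging = imaging, centres = centres,
       linkage = linkage)
}

tiny_dossiers <- function(exp = tiny_exports()) {
  link_cases(exp$linkage, exp$ecrf, exp$biosamples, exp$imaging,
             exp$centres)
}

# noise-free simulation config with a fixed inpatient path
noise_free_config <- function(seed, n_centres = 1, cases = 5,
                              cohort = "HAP") {
  sim_config(seed = seed, cohort = cohort, centre_class = "AMC",
             n_centres = n_centres,
             cases_per_centre = rep(cases, n_centres),
             p_icu = 0, los_ward = list(dist = "pmf", values = 2, probs = 1),
             p_dropout = 0, fu_compliance = 1,
             p_consent = 1, p_form_missing = 0, p_plausibility_fail = 0,
             p_case_review_fail = 0, p_bio = 1, p_aliquot_low = 0,
             p_imaging = 1, p_upload_fail = 0)
}
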