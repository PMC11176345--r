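#' Coded quality-gate reasons
#'
#' Closed vocabulary of machine-diffable exclusion / ineligibility codes.
#' Case-level: `NO_CONSENT`, `FORMS_MISSING`, `CASE_REVIEW_MISSING`.
#' Record-level: `NOT_SUBMITTED`, `PLAUSIBILITY_FAIL`, `ALIQUOTS_BELOW_MIN`,
#' `NOT_REGISTERED`, `NOT_UPLOADED`, `UNMAPPED_ITEM`, `UNMAPPED_SAMPLE_TYPE`,
#' `UNMAPPED_MODALITY`.
#'
#' @return character vector of reason codes.
#' @export
qc_reasons <- function() {
  c("NO_CONSENT", "FORMS_MISSING", "CASE_REVIEW_MISSING",
    "NOT_SUBMITTED", "PLAUSIBILITY_FAIL", "ALIQUOTS_BELOW_MIN",
    "NOT_REGISTERED", "NOT_UPLOADED", "UNMAPPED_ITEM",
    "UNMAPPED_SAMPLE_TYPE", "UNMAPPED_MODALITY")
}

#' Eligibility rules for one cohort
#'
#' A case is reimbursable only if an informed consent is registered and all
#' relevant pages of the baseline and discharge visit forms (or the initial
#' interview and on-site visit for the population-based cohort) were
#' submitted. The cross-sectoral cohort additionally requires a passed local
#' case review for every sub-form.
#'
#' @param cohort `"HAP"`, `"POP"` or `"SUEP"`.
#' @return list with `cohort`, `required_forms`, `require_consent`,
#'   `require_case_review`.
#' @export
eligibility_rules <- function(cohort = c("HAP", "POP", "SUEP")) {
  cohort <- match.arg(cohort)
  list(
    cohort = cohort,
    required_forms = switch(cohort,
                            HAP = c("baseline", "discharge"),
                            SUEP = c("baseline", "discharge"),
                            POP = c("initial-interview", "on-site")),
    require_consent = TRUE,
    require_case_review = identical(cohort, "SUEP")
  )
}

#' Default rule set (eligibility + biosampling + imaging rules)
#'
#' Biosampling records are reimbursed per sample type when at least
#' `min_aliquots` aliquots are registered; imaging records when the series
#' was uploaded with at least one series. The fee item ids resolve in the
#' packaged catalogue.
#'
#' @return list with `eligibility` (per cohort), `bio`, `img` rule tables.
#' @seealso [read_rules()], [write_rules()]
#' @export
default_rules <- function() {
  list(
    eligibility = list(HAP = eligibility_rules("HAP"),
                       POP = eligibility_rules("POP"),
                       SUEP = eligibility_rules("SUEP")),
    bio = tibble::tibble(sample_type = "pbmc", min_aliquots = 2L,
                         item_id = "pbmc"),
    img = tibble::tibble(modality = "echo", require_upload = TRUE,
                         item_id = "echo")
  )
}

#' Read / write a rule set as YAML
#'
#' @param path a `.yaml` file.
#' @return `read_rules()`: a rule set as from [default_rules()];
#'   `write_rules()`: `path` invisibly.
#' @export
read_rules <- function(path) {
  if (!file.exists(path)) {
    pbrm_abort(paste0("rules file not found: ", path), class = "pbrm_io_error")
  }
  y <- yaml::read_yaml(path)
  elig <- lapply(y$eligibility, function(e) {
    list(cohort = e$cohort,
         required_forms = as.character(e$required_forms),
         require_consent = isTRUE(e$require_consent),
         require_case_review = isTRUE(e$require_case_review))
  })
  bio <- dplyr::bind_rows(lapply(y$bio, tibble::as_tibble))
  img <- dplyr::bind_rows(lapply(y$img, tibble::as_tibble))
  if (nrow(bio)) bio$min_aliquots <- as.integer(bio$min_aliquots)
  list(eligibility = elig, bio = bio, img = img)
}

#' @rdname read_rules
#' @param rules a rule set.
#' @export
write_rules <- function(rules, path) {
  y <- list(
    eligibility = rules$eligibility,
    bio = lapply(seq_len(nrow(rules$bio)), function(i) as.list(rules$bio[i, ])),
    img = lapply(seq_len(nrow(rules$img)), function(i) as.list(rules$img[i, ]))
  )
  yaml::write_yaml(y, path)
  invisible(path)
}

#' Eligibility verdict for the eCRF records of one case
#'
#' @param ecrf_records eCRF records of a single case (possibly empty).
#' @param rules cohort eligibility rules from [eligibility_rules()].
#' @return list with `reimbursable` flag and coded `reasons` (empty iff
#'   reimbursable).
#' @export
case_verdict <- function(ecrf_records, rules) {
  reasons <- character()
  consent_ok <- nrow(ecrf_records) > 0 &&
    !any(ecrf_records$consent_registered %in% c(FALSE, NA))
  if (rules$require_consent && !consent_ok) reasons <- c(reasons, "NO_CONSENT")
  forms_ok <- vapply(rules$required_forms, function(f) {
    rec <- ecrf_records[ecrf_records$form_id == f, ]
    nrow(rec) > 0 && all(rec$submitted %in% TRUE)
  }, logical(1))
  if (!all(forms_ok)) reasons <- c(reasons, "FORMS_MISSING")
  if (rules$require_case_review &&
      any(ecrf_records$case_review_pass %in% FALSE)) {
    reasons <- c(reasons, "CASE_REVIEW_MISSING")
  }
  list(reimbursable = length(reasons) == 0, reasons = reasons)
}

#' Evaluate reimbursability of every case
#'
#' Applies the cohort's minimum reimbursement criteria to every dossier.
#' Verdicts are data, not exceptions: every failed criterion yields a coded
#' reason and a non-reimbursable case contributes zero billable lines
#' downstream.
#'
#' @param dossiers a [link_cases()] result.
#' @param rules a rule set as from [default_rules()].
#' @return tibble with `case_id`, `reimbursable`, `consent_registered`, and a
#'   `reasons` list-column.
#' @export
evaluate_cases <- function(dossiers, rules = default_rules()) {
  cases <- dossiers$cases
  ecrf_by_case <- split(dossiers$ecrf, factor(dossiers$ecrf$case_id,
                                              levels = cases$case_id))
  verdicts <- lapply(seq_len(nrow(cases)), function(i) {
    cohort <- cases$cohort[i]
    erules <- rules$eligibility[[cohort]] %||% eligibility_rules(cohort)
    recs <- ecrf_by_case[[cases$case_id[i]]]
    v <- case_verdict(recs, erules)
    tibble::tibble(case_id = cases$case_id[i],
                   reimbursable = v$reimbursable,
                   consent_registered = nrow(recs) > 0 &&
                     !any(recs$consent_registered %in% c(FALSE, NA)),
                   reasons = list(v$reasons))
  })
  dplyr::bind_rows(verdicts)
}

.case_primary_reason <- function(verdicts) {
  setNames(vapply(verdicts$reasons, function(r) {
    if (length(r)) r[[1]] else NA_character_
  }, character(1)), verdicts$case_id)
}

#' Filter records through the quality gates
#'
#' Splits every record of every dossier into exactly one of: survivor
#' (eligible for reimbursement) or one coded exclusion bucket. Records of a
#' non-reimbursable case are bucketed under the case's primary reason. For
#' surviving cases: eCRF records must be submitted and pass the automated
#' plausibility checks; biosampling records must be registered, match a
#' biosampling rule and meet its aliquot threshold; imaging records must
#' match an imaging rule and be uploaded with at least one series.
#'
#' @param dossiers a [link_cases()] result.
#' @param verdicts from [evaluate_cases()] (computed if omitted).
#' @param rules a rule set as from [default_rules()].
#' @return list with `events` (per-system survivor tibbles), `exclusions`
#'   (one row per removed record with its reason) and `counts` (removed
#'   records per source and reason).
#' @export
filter_records <- function(dossiers, rules = default_rules(),
                           verdicts = NULL) {
  verdicts <- verdicts %||% evaluate_cases(dossiers, rules)
  primary <- .case_primary_reason(verdicts)
  ok_cases <- verdicts$case_id[verdicts$reimbursable]

  reason_of <- function(df, record_reason) {
    r <- rep(NA_character_, nrow(df))
    ineligible <- !df$case_id %in% ok_cases
    r[ineligible] <- unname(primary[df$case_id[ineligible]])
    r[!ineligible] <- record_reason(df[!ineligible, , drop = FALSE])
    r
  }

  ecrf_reason <- function(df) {
    r <- rep(NA_character_, nrow(df))
    r[!df$submitted %in% TRUE] <- "NOT_SUBMITTED"
    miss <- is.na(r) & !df$plausibility_pass %in% TRUE
    r[miss] <- "PLAUSIBILITY_FAIL"
    r
  }
  bio_reason <- function(df) {
    r <- rep(NA_character_, nrow(df))
    r[!df$registered %in% TRUE] <- "NOT_REGISTERED"
    known <- df$sample_type %in% rules$bio$sample_type
    r[is.na(r) & !known] <- "UNMAPPED_SAMPLE_TYPE"
    minal <- rules$bio$min_aliquots[match(df$sample_type,
                                          rules$bio$sample_type)]
    r[is.na(r) & df$aliquot_count < minal] <- "ALIQUOTS_BELOW_MIN"
    r
  }
  img_reason <- function(df) {
    r <- rep(NA_character_, nrow(df))
    known <- df$modality %in% rules$img$modality
    r[!known] <- "UNMAPPED_MODALITY"
    r[is.na(r) & (!df$uploaded %in% TRUE | df$series_count < 1)] <-
      "NOT_UPLOADED"
    r
  }

  split_one <- function(df, source, record_reason) {
    if (nrow(df) == 0) {
      return(list(events = df,
                  excl = tibble::tibble(source = character(),
                                        case_id = character(),
                                        .row = integer(),
                                        reason = character())))
    }
    r <- reason_of(df, record_reason)
    list(events = df[is.na(r), , drop = FALSE],
         excl = tibble::tibble(source = source,
                               case_id = df$case_id[!is.na(r)],
                               .row = df$.row[!is.na(r)],
                               reason = r[!is.na(r)]))
  }

  e <- split_one(dossiers$ecrf, "ecrf", ecrf_reason)
  b <- split_one(dossiers$bio, "bio", bio_reason)
  i <- split_one(dossiers$imaging, "imaging", img_reason)
  exclusions <- dplyr::bind_rows(e$excl, b$excl, i$excl)
  counts <- dplyr::count(exclusions, .data$source, .data$reason,
                         name = "n_removed")
  list(events = list(ecrf = e$events, bio = b$events, imaging = i$events),
       exclusions = exclusions, counts = counts)
}

#' Default eCRF-to-catalogue mapping table
#'
#' In the deployed model every eCRF data item was mapped (and two-reviewer
#' proof-read) to a reimbursement item. The packaged default maps the
#' simulator's eCRF item ids (`crf-<item>`) to their catalogue items with the
#' `plausibility-pass` condition.
#'
#' @param catalogue a [cost_catalogue()]; mapped items are the catalogue
#'   items not handled by biosampling/imaging rules.
#' @param rules rule set; its bio/img fee items are excluded from the eCRF
#'   mapping.
#' @return tibble with `ecrf_item_id`, `reimbursement_item_id`, `condition`,
#'   `reviewed`.
#' @export
default_mapping <- function(catalogue = default_catalogue(),
                            rules = default_rules()) {
  ids <- setdiff(catalogue$items$item_id,
                 c(rules$bio$item_id, rules$img$item_id))
  tibble::tibble(ecrf_item_id = paste0("crf-", ids),
                 reimbursement_item_id = ids,
                 condition = "plausibility-pass",
                 reviewed = TRUE)
}

#' Read / write a mapping table
#'
#' @param path a `.csv` file with columns `ecrf_item_id`,
#'   `reimbursement_item_id`, `condition` (one of `always`, `value-present`,
#'   `plausibility-pass`) and optional `reviewed` metadata.
#' @return the mapping tibble / `path` invisibly.
#' @export
read_mapping <- function(path) {
  if (!file.exists(path)) {
    pbrm_abort(paste0("mapping file not found: ", path),
               class = "pbrm_io_error")
  }
  m <- readr::read_csv(path, show_col_types = FALSE,
                       col_types = readr::cols(.default = "c"))
  if ("reviewed" %in% names(m)) m$reviewed <- as.logical(m$reviewed)
  m
}

#' @rdname read_mapping
#' @param mapping a mapping tibble.
#' @export
write_mapping <- function(mapping, path) {
  readr::write_csv(mapping, path, na = "NA")
  invisible(path)
}

.validate_mapping <- function(mapping, catalogue) {
  bad <- setdiff(mapping$reimbursement_item_id, catalogue$items$item_id)
  if (length(bad)) {
    pbrm_abort(paste0("mapping references unknown catalogue item(s): ",
                      paste(bad, collapse = ", ")),
               class = "pbrm_config_error")
  }
  bad <- setdiff(mapping$condition,
                 c("always", "value-present", "plausibility-pass"))
  if (length(bad)) {
    pbrm_abort(paste0("unknown mapping condition(s): ",
                      paste(bad, collapse = ", ")),
               class = "pbrm_config_error")
  }
  invisible(mapping)
}

#' Turn eligible events into billable lines
#'
#' Joins surviving eCRF events to the mapping table (each event contributes
#' per its mapping row if the row's condition holds) and surviving
#' biosampling / imaging events to their rule fee items. Unmapped eCRF items
#' are counted and reported, never billed.
#'
#' @param events the `events` element of a [filter_records()] result.
#' @param mapping mapping table, see [default_mapping()].
#' @param catalogue a [cost_catalogue()] (mapping is validated against it).
#' @param rules rule set supplying the biosampling/imaging fee items.
#' @return list with `lines` (case_id, visit_id, visit_type_id, item_id,
#'   count, source) and `unmapped` (eCRF
#'   events without a mapping row, with reason `UNMAPPED_ITEM`).
#' @export
apply_mapping <- function(events, mapping, catalogue,
                          rules = default_rules()) {
  .validate_mapping(mapping, catalogue)
  ec <- events$ecrf
  m <- dplyr::inner_join(ec, mapping, by = c(item_id = "ecrf_item_id"),
                         relationship = "many-to-many")
  cond_ok <- (m$condition == "always") |
    (m$condition == "value-present" & !is.na(m$value) & m$value != "") |
    (m$condition == "plausibility-pass" & m$plausibility_pass %in% TRUE)
  m <- m[cond_ok, , drop = FALSE]
  unmapped <- dplyr::anti_join(ec, mapping, by = c(item_id = "ecrf_item_id"))
  unmapped$reason <- if (nrow(unmapped)) "UNMAPPED_ITEM" else character(0)

  ecrf_lines <- dplyr::summarise(
    dplyr::group_by(m, .data$case_id, .data$visit_id, .data$visit_type_id,
                    item_id = .data$reimbursement_item_id),
    count = dplyr::n(), .groups = "drop")
  ecrf_lines$source <- rep("ecrf", nrow(ecrf_lines))

  bio_lines <- tibble::tibble(case_id = character(), visit_id = character(),
                              visit_type_id = character(),
                              item_id = character(), count = integer(),
                              source = character())
  if (nrow(events$bio)) {
    bl <- dplyr::inner_join(events$bio, rules$bio, by = "sample_type")
    bio_lines <- tibble::tibble(case_id = bl$case_id, visit_id = bl$visit_id,
                                visit_type_id = NA_character_,
                                item_id = bl$item_id, count = 1L,
                                source = "bio")
  }
  img_lines <- tibble::tibble(case_id = character(), visit_id = character(),
                              visit_type_id = character(),
                              item_id = character(), count = integer(),
                              source = character())
  if (nrow(events$imaging)) {
    il <- dplyr::inner_join(events$imaging, rules$img, by = "modality")
    img_lines <- tibble::tibble(case_id = il$case_id, visit_id = il$visit_id,
                                visit_type_id = NA_character_,
                                item_id = il$item_id, count = 1L,
                                source = "imaging")
  }
  lines <- dplyr::bind_rows(ecrf_lines, bio_lines, img_lines)
  lines <- dplyr::arrange(lines, .data$case_id, .data$source, .data$visit_id,
                          .data$item_id)
  list(lines = lines, unmapped = unmapped)
}
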