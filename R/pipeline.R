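#' Run the full reimbursement pipeline
#'
#' Exports in, statements out: links the system exports into case dossiers,
#' evaluates the minimum reimbursement criteria, filters records through the
#' quality gates, maps surviving eCRF items to reimbursement items, prices
#' everything from the catalogue, optionally imputes announced future
#' visits, and aggregates to centre and cohort summaries under an immutable
#' run ledger.
#'
#' @param exports a [simulate_cohort()] bundle, a [read_exports_dir()] list,
#'   or a directory path holding the five export files.
#' @param catalogue a [cost_catalogue()].
#' @param mapping eCRF mapping table ([default_mapping()]).
#' @param rules rule set ([default_rules()]).
#' @param imputation optional [impute_future_visits()] spec; a bundle's
#'   `announced` table is used automatically when a `freeze_date` is given
#'   here without an `announced` element.
#' @param initiation_fee_eur study initiation fee for qualifying
#'   cross-sectoral non-academic centres.
#' @param fu_schedule expected follow-up visit types per case (`NULL` to
#'   skip fulfilment reporting).
#' @param iteration correction-loop iteration recorded in the ledger.
#' @return object of class `pbrm_run`: list with `dossiers`, `verdicts`,
#'   `filtered`, `unmapped`, `statements`, `case_totals`,
#'   `centre_summaries`, `cohort_summaries`, `ledger`.
#' @export
run_pbrm <- function(exports, catalogue = default_catalogue(),
                     mapping = default_mapping(catalogue),
                     rules = default_rules(), imputation = NULL,
                     initiation_fee_eur = 0,
                     fu_schedule = c("fu-3mo", "fu-12mo"),
                     iteration = 1L) {
  if (is.character(exports)) exports <- read_exports_dir(exports)
  if (inherits(exports, "pbrm_bundle")) {
    if (!is.null(imputation) && is.null(imputation$announced)) {
      imputation$announced <- exports$announced
    }
    exports <- list(ecrf = exports$ecrf, biosamples = exports$biosamples,
                    imaging = exports$imaging, centres = exports$centres,
                    linkage = exports$linkage)
  }
  dossiers <- link_cases(exports$linkage, exports$ecrf, exports$biosamples,
                         exports$imaging, exports$centres)
  verdicts <- evaluate_cases(dossiers, rules)
  filtered <- filter_records(dossiers, rules, verdicts)
  mapped <- apply_mapping(filtered$events, mapping, catalogue, rules)
  statements <- compute_case_statements(mapped$lines, catalogue,
                                        cases = dossiers$cases)
  if (!is.null(imputation)) {
    statements <- impute_future_visits(statements, imputation)
  }
  centre_summaries <- aggregate_centres(
    statements, dossiers, verdicts,
    initiation_fee_eur = initiation_fee_eur, fu_schedule = fu_schedule)
  ledger <- build_run_ledger(
    list(ecrf = exports$ecrf, biosamples = exports$biosamples,
         imaging = exports$imaging, centres = exports$centres,
         linkage = exports$linkage, mapping = mapping, rules = rules,
         catalogue = catalogue),
    catalogue_version = catalogue$meta$schema_version,
    iteration = iteration)
  structure(list(
    dossiers = dossiers, verdicts = verdicts, filtered = filtered,
    unmapped = mapped$unmapped, statements = statements,
    case_totals = case_totals(statements,
                              cases = dossiers$cases[
                                dossiers$cases$case_id %in%
                                  verdicts$case_id[verdicts$reimbursable], ]),
    centre_summaries = centre_summaries,
    cohort_summaries = aggregate_cohorts(centre_summaries),
    ledger = ledger
  ), class = "pbrm_run")
}

#' @export
print.pbrm_run <- function(x, ...) {
  cat(sprintf(
    "<pbrm_run %s> %d cases (%d reimbursable) in %d centres; total %.2f EUR\n",
    substr(x$ledger$run_id, 1, 8), nrow(x$verdicts),
    sum(x$verdicts$reimbursable), nrow(x$centre_summaries),
    money_sum(x$centre_summaries$total_eur)))
  invisible(x)
}

#' Generate audience-scoped reports
#'
#' Writes `statements.csv`, `case_totals.csv`, `centre_summary.csv`,
#' `cohort_summary.csv`, `report.md` and `run_ledger.json`. The
#' `"coordination"` audience sees all centres; a `"centre"` audience sees
#' only its own cases and summary (confidentiality scoping by file content).
#' Output is a pure function of the run, so regenerating from the same run
#' yields byte-identical files.
#'
#' @param run a [run_pbrm()] result.
#' @param audience `"coordination"` or `"centre"`.
#' @param centre_id required for the centre audience.
#' @param out_dir output directory.
#' @return `out_dir`, invisibly.
#' @export
generate_reports <- function(run, audience = c("coordination", "centre"),
                             centre_id = NULL, out_dir) {
  audience <- match.arg(audience)
  st <- tibble::as_tibble(run$statements)
  cs <- run$centre_summaries
  ct <- run$case_totals
  cases <- run$dossiers$cases
  if (audience == "centre") {
    if (is.null(centre_id) || !centre_id %in% cases$centre_id) {
      pbrm_abort(paste0("unknown centre: ", centre_id %||% "<missing>"),
                 class = "pbrm_lookup_error")
    }
    keep <- cases$case_id[cases$centre_id == centre_id]
    st <- st[st$case_id %in% keep, ]
    ct <- ct[ct$case_id %in% keep, ]
    cs <- cs[cs$centre_id == centre_id, ]
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(st, file.path(out_dir, "statements.csv"), na = "NA")
  readr::write_csv(ct, file.path(out_dir, "case_totals.csv"), na = "NA")
  readr::write_csv(cs, file.path(out_dir, "centre_summary.csv"), na = "NA")
  readr::write_csv(run$cohort_summaries,
                   file.path(out_dir, "cohort_summary.csv"), na = "NA")
  jsonlite::write_json(run$ledger, file.path(out_dir, "run_ledger.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)

  md <- c(
    sprintf("# Reimbursement report (run %s, iteration %d)",
            run$ledger$run_id, run$ledger$iteration),
    "",
    sprintf("Audience: %s%s", audience,
            if (audience == "centre") paste0(" (", centre_id, ")") else ""),
    "",
    "## Centre summary", "",
    "| centre | cohort | recruited | reimbursable | total EUR | mean/case EUR | eCRF % | bio % | imaging % |",
    "|---|---|---|---|---|---|---|---|---|",
    vapply(seq_len(nrow(cs)), function(i) sprintf(
      "| %s | %s | %d | %d | %.2f | %s | %s | %s | %s |",
      cs$centre_id[i], cs$cohort[i], cs$n_recruited[i],
      cs$n_reimbursable[i], cs$total_eur[i],
      .fmt_na(cs$mean_per_case_eur[i]), .fmt_na(cs$share_ecrf_pct[i], 1),
      .fmt_na(cs$share_bio_pct[i], 1), .fmt_na(cs$share_imaging_pct[i], 1)),
      character(1)),
    "",
    sprintf("Cases in statement: %d; statement lines: %d (%d imputed).",
            length(unique(st$case_id)), nrow(st), sum(st$imputed)))
  writeLines(md, file.path(out_dir, "report.md"))
  invisible(out_dir)
}

.fmt_na <- function(x, digits = 2) {
  if (is.na(x)) "-" else formatC(x, format = "f", digits = digits)
}
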