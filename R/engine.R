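#' Itemised case statements from billable lines
#'
#' Prices every billable line from the catalogue (`amount = count * unit
#' cost`) and returns the statement line table. Totals at every level are
#' exact integer-cent sums, so case, centre and cohort aggregates conserve to
#' the cent.
#'
#' @param lines billable lines from [apply_mapping()] (columns `case_id`,
#'   `visit_id`, `visit_type_id`, `item_id`, `count`, `source`).
#' @param catalogue a [cost_catalogue()].
#' @param cases optional case table (from `dossiers$cases`) used to attach
#'   `centre_id`, `cohort`, `centre_class`.
#' @return a `pbrm_statements` tibble: one row per line with `unit_cost_eur`,
#'   `amount_eur` and an `imputed` flag (all `FALSE` here).
#' @seealso [case_totals()], [impute_future_visits()]
#' @export
compute_case_statements <- function(lines, catalogue, cases = NULL) {
  lines <- tibble::as_tibble(lines)
  if (nrow(lines)) {
    unit <- unname(item_total_cost(catalogue, lines$item_id))
    lines$unit_cost_eur <- unit
    lines$amount_eur <- round(lines$count * unit * 100) / 100
  } else {
    lines$unit_cost_eur <- numeric(0)
    lines$amount_eur <- numeric(0)
  }
  lines$imputed <- rep(FALSE, nrow(lines))
  lines$provenance <- rep(NA_character_, nrow(lines))
  if (!is.null(cases)) {
    lines <- dplyr::left_join(
      lines, cases[, c("case_id", "centre_id", "cohort", "centre_class")],
      by = "case_id")
  }
  class(lines) <- c("pbrm_statements", class(lines))
  lines
}

#' Per-case totals of a statement table
#'
#' @param statements a [compute_case_statements()] result.
#' @param cases optional case table; when given, reimbursable cases without
#'   any line appear with a 0.00 total.
#' @return tibble with `case_id`, `total_eur` and per-source totals
#'   (`ecrf_eur`, `bio_eur`, `imaging_eur`, `imputed_eur`).
#' @export
case_totals <- function(statements, cases = NULL) {
  st <- tibble::as_tibble(statements)
  sum_by <- function(df) {
    out <- dplyr::summarise(
      dplyr::group_by(df, .data$case_id),
      total_eur = money_sum(.data$amount_eur),
      ecrf_eur = money_sum(.data$amount_eur[.data$source == "ecrf" &
                                              !.data$imputed]),
      bio_eur = money_sum(.data$amount_eur[.data$source == "bio"]),
      imaging_eur = money_sum(.data$amount_eur[.data$source == "imaging"]),
      imputed_eur = money_sum(.data$amount_eur[.data$imputed]),
      .groups = "drop")
    out
  }
  out <- sum_by(st)
  if (!is.null(cases)) {
    missing <- setdiff(cases$case_id, out$case_id)
    if (length(missing)) {
      out <- dplyr::bind_rows(out, tibble::tibble(
        case_id = missing, total_eur = 0, ecrf_eur = 0, bio_eur = 0,
        imaging_eur = 0, imputed_eur = 0))
    }
    out <- out[order(out$case_id), ]
  }
  out
}

#' Impute announced future visits
#'
#' Visits announced for the current reimbursement period that fall after the
#' documentation freeze are reimbursed from experience values: the mean
#' realised cost of completed visits of the same type, taken at centre level,
#' falling back to cohort level and finally to a configured default. Original
#' lines are never altered; every imputed line carries `imputed = TRUE` and
#' its provenance (`centre`, `cohort` or `configured`).
#'
#' @param statements a [compute_case_statements()] result carrying
#'   `centre_id` and `cohort` columns.
#' @param spec list with `freeze_date` (Date), `announced` (tibble `case_id`,
#'   `visit_type_id`, `due_date`), optional `period_end` (Date) and
#'   `defaults` (named numeric, euro per visit type).
#' @return the statement table with imputed lines appended.
#' @export
impute_future_visits <- function(statements, spec) {
  stopifnot(!is.null(spec$freeze_date))
  ann <- spec$announced
  if (is.null(ann) || nrow(ann) == 0) return(statements)
  ann <- ann[ann$due_date > as.Date(spec$freeze_date), , drop = FALSE]
  if (!is.null(spec$period_end)) {
    ann <- ann[ann$due_date <= as.Date(spec$period_end), , drop = FALSE]
  }
  if (nrow(ann) == 0) return(statements)

  st <- tibble::as_tibble(statements)
  done <- dplyr::distinct(st[!st$imputed, c("case_id", "visit_type_id")])
  ann <- dplyr::anti_join(ann, done, by = c("case_id", "visit_type_id"))
  if (nrow(ann) == 0) return(statements)

  case_info <- dplyr::distinct(st[, intersect(
    c("case_id", "centre_id", "cohort", "centre_class"), names(st))])
  ann <- dplyr::left_join(ann, case_info, by = "case_id")

  visit_totals <- dplyr::summarise(
    dplyr::group_by(st[!st$imputed, ], .data$centre_id, .data$cohort,
                    .data$visit_type_id, .data$case_id, .data$visit_id),
    cost = money_sum(.data$amount_eur), .groups = "drop")
  centre_mean <- dplyr::summarise(
    dplyr::group_by(visit_totals, .data$centre_id, .data$visit_type_id),
    value = money(mean(.data$cost)), .groups = "drop")
  cohort_mean <- dplyr::summarise(
    dplyr::group_by(visit_totals, .data$cohort, .data$visit_type_id),
    value = money(mean(.data$cost)), .groups = "drop")

  value_for <- function(i) {
    vt <- ann$visit_type_id[i]
    j <- which(centre_mean$centre_id == ann$centre_id[i] &
                 centre_mean$visit_type_id == vt)
    if (length(j)) return(list(v = centre_mean$value[j[1]], p = "centre"))
    j <- which(cohort_mean$cohort == ann$cohort[i] &
                 cohort_mean$visit_type_id == vt)
    if (length(j)) return(list(v = cohort_mean$value[j[1]], p = "cohort"))
    if (!is.null(spec$defaults) && vt %in% names(spec$defaults)) {
      return(list(v = money(spec$defaults[[vt]]), p = "configured"))
    }
    pbrm_abort(sprintf(
      "no experience value resolvable for visit type '%s' (centre %s)",
      vt, ann$centre_id[i]), class = "pbrm_config_error")
  }
  vals <- lapply(seq_len(nrow(ann)), value_for)
  imp <- tibble::tibble(
    case_id = ann$case_id,
    visit_id = sprintf("IMP-%04d", seq_len(nrow(ann))),
    visit_type_id = ann$visit_type_id,
    item_id = paste0("imputed-", ann$visit_type_id),
    count = 1L,
    source = "ecrf",
    unit_cost_eur = vapply(vals, `[[`, numeric(1), "v"),
    amount_eur = vapply(vals, `[[`, numeric(1), "v"),
    imputed = TRUE,
    provenance = vapply(vals, `[[`, character(1), "p"))
  for (col in intersect(c("centre_id", "cohort", "centre_class"), names(st))) {
    imp[[col]] <- ann[[col]]
  }
  out <- dplyr::bind_rows(st, imp)
  class(out) <- c("pbrm_statements", class(tibble::tibble()))
  out
}

#' Follow-up fulfilment
#'
#' Percentage of protocol-expected follow-up visits that were actually
#' documented (a submitted eCRF record exists for the visit type), reported
#' to one decimal. Reported as `NA` when no follow-up visits are expected.
#'
#' @param dossiers a [link_cases()] result.
#' @param schedule character vector of expected follow-up visit types per
#'   case.
#' @param by `"overall"` or `"centre"`.
#' @return a percentage, or a tibble per centre.
#' @export
fu_fulfilment <- function(dossiers, schedule = c("fu-3mo", "fu-12mo"),
                          by = c("overall", "centre")) {
  by <- match.arg(by)
  cases <- dossiers$cases
  ec <- dossiers$ecrf
  done <- dplyr::distinct(
    ec[ec$visit_type_id %in% schedule & ec$submitted %in% TRUE,
       c("case_id", "visit_type_id")])
  if (by == "overall") {
    expected <- nrow(cases) * length(schedule)
    if (expected == 0) return(NA_real_)
    return(pct1(100 * nrow(done) / expected))
  }
  done <- dplyr::left_join(done, cases[, c("case_id", "centre_id")],
                           by = "case_id")
  n_done <- dplyr::count(done, .data$centre_id, name = "n_documented")
  out <- dplyr::count(cases, .data$centre_id, name = "n_cases")
  out <- dplyr::left_join(out, n_done, by = "centre_id")
  out$n_documented[is.na(out$n_documented)] <- 0L
  out$n_expected <- out$n_cases * length(schedule)
  out$fu_fulfilment_pct <- ifelse(
    out$n_expected == 0, NA_real_,
    pct1(100 * out$n_documented / out$n_expected))
  out
}

#' Aggregate statements to centre summaries
#'
#' Per centre: recruited and reimbursable case counts, total and mean
#' reimbursement per case, relative source-system shares, follow-up
#' fulfilment, and the study initiation fee (granted to cross-sectoral
#' non-academic centres with at least `initiation_fee_min_cases`
#' reimbursable cases; the amount is configurable and not part of the
#' per-line conservation identity).
#'
#' @param statements a [compute_case_statements()] result.
#' @param dossiers a [link_cases()] result.
#' @param verdicts from [evaluate_cases()].
#' @param initiation_fee_eur fee amount (default 0 disables it).
#' @param initiation_fee_min_cases minimum reimbursable cases (default 5).
#' @param fu_schedule follow-up schedule for [fu_fulfilment()], or `NULL`.
#' @return tibble, one row per centre.
#' @export
aggregate_centres <- function(statements, dossiers, verdicts,
                              initiation_fee_eur = 0,
                              initiation_fee_min_cases = 5,
                              fu_schedule = c("fu-3mo", "fu-12mo")) {
  cases <- dplyr::left_join(dossiers$cases,
                            verdicts[, c("case_id", "reimbursable",
                                         "consent_registered")],
                            by = "case_id")
  ct <- case_totals(statements, cases = cases[cases$reimbursable, ])
  cases <- dplyr::left_join(cases, ct, by = "case_id")
  for (col in c("total_eur", "ecrf_eur", "bio_eur", "imaging_eur",
                "imputed_eur")) {
    cases[[col]][is.na(cases[[col]])] <- 0
  }
  out <- dplyr::summarise(
    dplyr::group_by(cases, .data$centre_id, .data$cohort,
                    .data$centre_class, .data$display_letter,
                    .data$target_cases),
    n_recruited = sum(.data$consent_registered),
    n_reimbursable = sum(.data$reimbursable),
    total_eur = money_sum(.data$total_eur[.data$reimbursable]),
    ecrf_eur = money_sum(c(.data$ecrf_eur[.data$reimbursable],
                           .data$imputed_eur[.data$reimbursable])),
    bio_eur = money_sum(.data$bio_eur[.data$reimbursable]),
    imaging_eur = money_sum(.data$imaging_eur[.data$reimbursable]),
    .groups = "drop")
  out$mean_per_case_eur <- ifelse(out$n_reimbursable > 0,
                                  money(out$total_eur / out$n_reimbursable),
                                  NA_real_)
  share <- function(part) ifelse(out$total_eur > 0,
                                 pct1(100 * part / out$total_eur), NA_real_)
  out$share_ecrf_pct <- share(out$ecrf_eur)
  out$share_bio_pct <- share(out$bio_eur)
  out$share_imaging_pct <- share(out$imaging_eur)
  if (!is.null(fu_schedule)) {
    fu <- fu_fulfilment(dossiers, fu_schedule, by = "centre")
    out <- dplyr::left_join(out,
                            fu[, c("centre_id", "fu_fulfilment_pct")],
                            by = "centre_id")
  } else {
    out$fu_fulfilment_pct <- NA_real_
  }
  out$initiation_fee_eur <- ifelse(
    out$cohort == "SUEP" & out$centre_class == "non-AMC" &
      out$n_reimbursable >= initiation_fee_min_cases,
    money(initiation_fee_eur), 0)
  out$funding_eur <- money_sum_by_row(out$total_eur, out$initiation_fee_eur)
  dplyr::arrange(out, .data$cohort, .data$centre_class, .data$centre_id)
}

money_sum_by_row <- function(a, b) (round(a * 100) + round(b * 100)) / 100

#' Cohort-level summary
#'
#' @param centre_summaries from [aggregate_centres()].
#' @return tibble per cohort and centre class with case counts, total and
#'   mean reimbursement per case, and a two-sided t-based 95% confidence
#'   interval over centre-level means (absent for a single centre).
#' @export
aggregate_cohorts <- function(centre_summaries) {
  cs <- centre_summaries
  out <- dplyr::summarise(
    dplyr::group_by(cs, .data$cohort, .data$centre_class),
    n_centres = dplyr::n(),
    n_recruited = sum(.data$n_recruited),
    n_reimbursable = sum(.data$n_reimbursable),
    total_eur = money_sum(.data$total_eur),
    mean_per_case_eur = ifelse(sum(.data$n_reimbursable) > 0,
                               money(money_sum(.data$total_eur) /
                                       sum(.data$n_reimbursable)), NA_real_),
    centre_mean_eur = money(mean(.data$mean_per_case_eur, na.rm = TRUE)),
    ci_lo_eur = .t_ci(.data$mean_per_case_eur)[1],
    ci_hi_eur = .t_ci(.data$mean_per_case_eur)[2],
    .groups = "drop")
  out
}

.t_ci <- function(x, level = 0.95) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 2) return(c(NA_real_, NA_real_))
  se <- stats::sd(x) / sqrt(n)
  q <- stats::qt(1 - (1 - level) / 2, df = n - 1)
  c(mean(x) - q * se, mean(x) + q * se)
}

#' Random audit sample of cases
#'
#' Uniform sample of cases without replacement for item-by-item accuracy
#' checks, reproducible under an explicit seed (sampling never touches the
#' global RNG state).
#'
#' @param statements a statement table with a `case_id` column.
#' @param n number of cases to draw (default 10).
#' @param seed integer seed.
#' @return the statement rows of the sampled cases; the sampled ids are in
#'   attribute `"case_ids"`.
#' @export
random_audit_sample <- function(statements, n = 10, seed) {
  ids <- sort(unique(statements$case_id))
  if (n > length(ids)) {
    pbrm_abort(sprintf("cannot sample %d cases from %d", n, length(ids)),
               class = "pbrm_sampling_error")
  }
  picked <- withr::with_seed(seed, sample(ids, n))
  out <- statements[statements$case_id %in% picked, , drop = FALSE]
  attr(out, "case_ids") <- sort(picked)
  out
}

md5_of_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  con <- file(f, open = "wb")
  serialize(x, con, version = 2)
  close(con)
  unname(tools::md5sum(f))
}

#' Build the immutable run ledger
#'
#' Every run is content-addressed: the run id is a digest over the input
#' digests, so identical inputs give an identical run id and reports can be
#' regenerated bit-exactly. Correction loops are modelled as new runs with an
#' incremented iteration counter, never as in-place edits.
#'
#' @param inputs named list of input objects (tibbles, rule sets, paths...).
#' @param catalogue_version catalogue schema version string.
#' @param iteration correction-loop iteration counter.
#' @param timestamp optional run timestamp string, recorded verbatim; never
#'   part of the digest (and omitted by default so that repeated runs over
#'   identical inputs produce byte-identical ledgers).
#' @return list with `run_id`, `input_digests`, `catalogue_version`,
#'   `iteration`, `timestamp`.
#' @export
build_run_ledger <- function(inputs, catalogue_version = "1.0",
                             iteration = 1L, timestamp = NULL) {
  digests <- vapply(inputs, md5_of_object, character(1))
  run_id <- md5_of_object(list(digests = digests,
                               catalogue_version = catalogue_version,
                               iteration = iteration))
  list(run_id = run_id, input_digests = as.list(digests),
       catalogue_version = catalogue_version, iteration = iteration,
       timestamp = timestamp)
}
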