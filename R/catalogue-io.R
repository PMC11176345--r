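#' Read / write a cost catalogue
#'
#' Two equivalent on-disk forms are supported: a directory of CSV files
#' (`items.csv` in long one-row-per-role-effort form, `rates.csv`,
#' `visits.csv`, `case_fees.csv`, `meta.json`) or a single JSON document
#' (path ending in `.json`). Both dialects use UTF-8, comma separators and
#' dot decimals, and round-trip to an identical catalogue.
#'
#' @param path directory or `.json` file.
#' @return `read_catalogue()`: a [cost_catalogue()]; `write_catalogue()`:
#'   `path`, invisibly.
#' @export
read_catalogue <- function(path) {
  if (grepl("\\.json$", path)) {
    if (!file.exists(path)) {
      pbrm_abort(paste0("catalogue file not found: ", path),
                 class = "pbrm_io_error")
    }
    doc <- jsonlite::read_json(path, simplifyVector = TRUE)
    return(.catalogue_from_long(
      tibble::as_tibble(doc$items), tibble::as_tibble(doc$rates),
      if (!is.null(doc$visits) && length(doc$visits)) tibble::as_tibble(doc$visits) else NULL,
      if (!is.null(doc$case_fees) && length(doc$case_fees)) tibble::as_tibble(doc$case_fees) else NULL,
      schema_version = doc$schema_version %||% "1.0",
      currency = doc$currency %||% "EUR"))
  }
  if (!dir.exists(path)) {
    pbrm_abort(paste0("catalogue directory not found: ", path),
               class = "pbrm_io_error")
  }
  items_long <- readr::read_csv(
    file.path(path, "items.csv"), show_col_types = FALSE,
    col_types = readr::cols(
      item_id = "c", label = "c", data_points = "i",
      material_cost_eur = "d", overhead_rate = "d", printed_total_eur = "d",
      role = "c", minutes = "d", salary_percent = "d",
      explicit_cost_eur = "d"))
  rates <- readr::read_csv(
    file.path(path, "rates.csv"), show_col_types = FALSE,
    col_types = readr::cols(role = "c", rate_eur_per_min = "d",
                            tariff_percent_per_min = "d"))
  visits <- NULL
  if (file.exists(file.path(path, "visits.csv"))) {
    visits <- readr::read_csv(
      file.path(path, "visits.csv"), show_col_types = FALSE,
      col_types = readr::cols(visit_type_id = "c", cohort = "c",
                              centre_class = "c", item_id = "c", count = "i"))
  }
  case_fees <- NULL
  if (file.exists(file.path(path, "case_fees.csv"))) {
    case_fees <- readr::read_csv(
      file.path(path, "case_fees.csv"), show_col_types = FALSE,
      col_types = readr::cols(cohort = "c", centre_class = "c",
                              configured_fee_eur = "d"))
  }
  meta <- list(schema_version = "1.0", currency = "EUR")
  if (file.exists(file.path(path, "meta.json"))) {
    meta <- utils::modifyList(meta, jsonlite::read_json(
      file.path(path, "meta.json"), simplifyVector = TRUE))
  }
  .catalogue_from_long(items_long, rates, visits, case_fees,
                       schema_version = meta$schema_version,
                       currency = meta$currency)
}

.catalogue_from_long <- function(items_long, rates, visits, case_fees,
                                 schema_version, currency) {
  item_cols <- c("item_id", "label", "data_points", "material_cost_eur",
                 "overhead_rate", "printed_total_eur")
  for (col in setdiff(item_cols, names(items_long))) {
    items_long[[col]] <- NA
  }
  items <- dplyr::distinct(items_long[, item_cols])
  dup <- items$item_id[duplicated(items$item_id)]
  if (length(dup)) {
    rows <- which(items_long$item_id %in% dup)
    pbrm_abort(paste0(
      "conflicting item-level fields for item_id ",
      paste(unique(dup), collapse = ", "),
      " (rows ", paste(rows, collapse = ", "), ")"),
      class = "pbrm_validation_error")
  }
  has_effort <- !is.na(items_long$role) & items_long$role != ""
  efforts <- items_long[has_effort,
                        intersect(c("item_id", "role", "minutes",
                                    "salary_percent", "explicit_cost_eur"),
                                  names(items_long))]
  cost_catalogue(items, efforts, rates, visits, case_fees,
                 schema_version = schema_version, currency = currency)
}

.catalogue_items_long <- function(cat) {
  long <- dplyr::left_join(cat$items, cat$efforts, by = "item_id")
  long[, c("item_id", "label", "data_points", "material_cost_eur",
           "overhead_rate", "printed_total_eur", "role", "minutes",
           "salary_percent", "explicit_cost_eur")]
}

#' @rdname read_catalogue
#' @param catalogue a [cost_catalogue()].
#' @export
write_catalogue <- function(catalogue, path) {
  stopifnot(inherits(catalogue, "pbrm_catalogue"))
  if (grepl("\\.json$", path)) {
    doc <- list(schema_version = catalogue$meta$schema_version,
                currency = catalogue$meta$currency,
                rates = catalogue$rates,
                items = .catalogue_items_long(catalogue),
                visits = catalogue$visits,
                case_fees = catalogue$case_fees)
    jsonlite::write_json(doc, path, dataframe = "columns", auto_unbox = TRUE,
                         digits = NA, na = "null", pretty = TRUE)
    return(invisible(path))
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  readr::write_csv(.catalogue_items_long(catalogue),
                   file.path(path, "items.csv"), na = "NA")
  readr::write_csv(catalogue$rates, file.path(path, "rates.csv"), na = "NA")
  readr::write_csv(catalogue$visits, file.path(path, "visits.csv"), na = "NA")
  readr::write_csv(catalogue$case_fees, file.path(path, "case_fees.csv"),
                   na = "NA")
  jsonlite::write_json(catalogue$meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' The packaged exemplary catalogue
#'
#' Eight exemplary reimbursement items (screening/baseline, ward and ICU
#' documentation, clinical status, ECG, PBMC biosampling, spirometry,
#' echocardiogram) with the public-service tariff role rates, visit
#' definitions for the three cohort platforms (HAP, POP, SUEP with AMC and
#' non-AMC visit schemes), and the negotiated case fees.
#'
#' @return a [cost_catalogue()].
#' @export
default_catalogue <- function() {
  read_catalogue(system.file("extdata", "catalogue", package = "pbrm",
                             mustWork = TRUE))
}
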