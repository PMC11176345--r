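#' Construct a cost catalogue
#'
#' The catalogue is the pricing backbone of the reimbursement model: a set of
#' reimbursement items (lump sums for single study activities such as an ECG
#' or one day of ward documentation), per-minute tariff rates for the three
#' personnel roles, visit definitions (which items a visit type comprises, per
#' cohort and centre class), and optional configured case fees (the expected
#' mean reimbursement per case and cohort).
#'
#' Each item cost is composed of per-role efforts. An effort is priced by its
#' explicit component cost when one is given, otherwise by `minutes` times the
#' role's `rate_eur_per_min`. Component costs are rounded to whole cents
#' before summation; the item total is `(sum of role costs + material) *
#' (1 + overhead_rate)`, rounded half-up to 2 decimals.
#'
#' @param items data frame with columns `item_id`, `label`, and optionally
#'   `material_cost_eur` (default 0), `overhead_rate` (default 0),
#'   `data_points`, `printed_total_eur` (reference total from the source
#'   costing table, used only by [catalogue_consistency()]).
#' @param efforts data frame with columns `item_id`, `role` (one of
#'   `"SP"`, `"PH"`, `"MS"`), `minutes`, and optionally `explicit_cost_eur`,
#'   `salary_percent` (opaque tariff metadata).
#' @param rates data frame with columns `role`, `rate_eur_per_min`, optionally
#'   `tariff_percent_per_min`.
#' @param visits data frame with columns `visit_type_id`, `cohort`,
#'   `centre_class`, `item_id`, `count`.
#' @param case_fees data frame with columns `cohort`, `centre_class`,
#'   `configured_fee_eur`.
#' @param schema_version,currency catalogue metadata.
#' @return an object of class `pbrm_catalogue`.
#' @seealso [default_catalogue()] for the packaged exemplary catalogue.
#' @export
cost_catalogue <- function(items, efforts = NULL, rates = NULL, visits = NULL,
                           case_fees = NULL, schema_version = "1.0",
                           currency = "EUR") {
  items <- tibble::as_tibble(items)
  for (col in c("material_cost_eur", "overhead_rate")) {
    if (!col %in% names(items)) items[[col]] <- 0
    items[[col]][is.na(items[[col]])] <- 0
  }
  if (!"data_points" %in% names(items)) items$data_points <- NA_integer_
  if (!"printed_total_eur" %in% names(items)) {
    items$printed_total_eur <- NA_real_
  }
  items$data_points <- as.integer(items$data_points)
  items$printed_total_eur <- as.numeric(items$printed_total_eur)
  items$material_cost_eur <- as.numeric(items$material_cost_eur)
  items$overhead_rate <- as.numeric(items$overhead_rate)
  items <- items[, c("item_id", "label", "data_points", "material_cost_eur",
                     "overhead_rate", "printed_total_eur")]

  efforts <- if (is.null(efforts)) {
    tibble::tibble(item_id = character(), role = character(),
                   minutes = numeric(), salary_percent = numeric(),
                   explicit_cost_eur = numeric())
  } else {
    efforts <- tibble::as_tibble(efforts)
    for (col in c("explicit_cost_eur", "salary_percent", "minutes")) {
      if (!col %in% names(efforts)) efforts[[col]] <- NA_real_
      efforts[[col]] <- as.numeric(efforts[[col]])
    }
    efforts[, c("item_id", "role", "minutes", "salary_percent",
                "explicit_cost_eur")]
  }

  rates <- if (is.null(rates)) {
    tibble::tibble(role = character(), rate_eur_per_min = numeric(),
                   tariff_percent_per_min = numeric())
  } else {
    rates <- tibble::as_tibble(rates)
    if (!"tariff_percent_per_min" %in% names(rates)) {
      rates$tariff_percent_per_min <- NA_real_
    }
    rates$tariff_percent_per_min <- as.numeric(rates$tariff_percent_per_min)
    rates$rate_eur_per_min <- as.numeric(rates$rate_eur_per_min)
    rates[, c("role", "rate_eur_per_min", "tariff_percent_per_min")]
  }

  visits <- if (is.null(visits)) {
    tibble::tibble(visit_type_id = character(), cohort = character(),
                   centre_class = character(), item_id = character(),
                   count = integer())
  } else {
    visits <- tibble::as_tibble(visits)
    visits$count <- as.integer(visits$count)
    visits[, c("visit_type_id", "cohort", "centre_class", "item_id", "count")]
  }

  case_fees <- if (is.null(case_fees)) {
    tibble::tibble(cohort = character(), centre_class = character(),
                   configured_fee_eur = numeric())
  } else {
    cf <- tibble::as_tibble(case_fees)
    cf$configured_fee_eur <- as.numeric(cf$configured_fee_eur)
    cf[, c("cohort", "centre_class", "configured_fee_eur")]
  }

  cat <- structure(
    list(items = items, efforts = efforts, rates = rates, visits = visits,
         case_fees = case_fees,
         meta = list(schema_version = schema_version, currency = currency)),
    class = "pbrm_catalogue"
  )
  validate_catalogue(cat)
  cat
}

validate_catalogue <- function(cat) {
  problems <- character()
  it <- cat$items
  dup <- it$item_id[duplicated(it$item_id)]
  if (length(dup)) {
    problems <- c(problems, paste0("duplicate item_id: ",
                                   paste(unique(dup), collapse = ", ")))
  }
  bad <- which(it$material_cost_eur < 0)
  if (length(bad)) problems <- c(problems, paste0(
    "negative material_cost_eur in items rows: ", paste(bad, collapse = ", ")))
  bad <- which(it$overhead_rate < 0)
  if (length(bad)) problems <- c(problems, paste0(
    "negative overhead_rate in items rows: ", paste(bad, collapse = ", ")))

  ef <- cat$efforts
  bad <- which(!ef$role %in% .pbrm_roles)
  if (length(bad)) problems <- c(problems, paste0(
    "unknown role in efforts rows: ", paste(bad, collapse = ", ")))
  bad <- which(!is.na(ef$minutes) & ef$minutes < 0)
  if (length(bad)) problems <- c(problems, paste0(
    "negative minutes in efforts rows: ", paste(bad, collapse = ", ")))
  bad <- which(!is.na(ef$explicit_cost_eur) & ef$explicit_cost_eur < 0)
  if (length(bad)) problems <- c(problems, paste0(
    "negative explicit_cost_eur in efforts rows: ", paste(bad, collapse = ", ")))
  dup <- duplicated(ef[, c("item_id", "role")])
  if (any(dup)) problems <- c(problems, paste0(
    "duplicated (item_id, role) in efforts rows: ",
    paste(which(dup), collapse = ", ")))
  bad <- setdiff(ef$item_id, it$item_id)
  if (length(bad)) problems <- c(problems, paste0(
    "efforts reference unknown item_id: ", paste(bad, collapse = ", ")))

  rt <- cat$rates
  if (anyDuplicated(rt$role)) {
    problems <- c(problems, "a role appears more than once in the rate table")
  }
  if (any(rt$rate_eur_per_min < 0, na.rm = TRUE)) {
    problems <- c(problems, "negative rate_eur_per_min")
  }
  bad <- which(!rt$role %in% .pbrm_roles)
  if (length(bad)) problems <- c(problems, paste0(
    "unknown role in rates rows: ", paste(bad, collapse = ", ")))

  vs <- cat$visits
  bad <- setdiff(vs$item_id, it$item_id)
  if (length(bad)) problems <- c(problems, paste0(
    "visit definitions reference unknown item_id: ",
    paste(bad, collapse = ", ")))
  bad <- which(is.na(vs$count) | vs$count < 0)
  if (length(bad)) problems <- c(problems, paste0(
    "negative or missing count in visits rows: ", paste(bad, collapse = ", ")))
  bad <- which(!vs$cohort %in% .pbrm_cohorts)
  if (length(bad)) problems <- c(problems, paste0(
    "unknown cohort in visits rows: ", paste(bad, collapse = ", ")))

  cf <- cat$case_fees
  bad <- which(!cf$cohort %in% .pbrm_cohorts)
  if (length(bad)) problems <- c(problems, paste0(
    "unknown cohort in case_fees rows: ", paste(bad, collapse = ", ")))

  if (length(problems)) {
    pbrm_abort(paste0("invalid catalogue:\n",
                      paste0("- ", problems, collapse = "\n")),
               class = "pbrm_validation_error")
  }
  invisible(cat)
}

#' @export
print.pbrm_catalogue <- function(x, ...) {
  cat(sprintf(
    "<pbrm_catalogue> %d items, %d role rates, %d visit-definition rows, %d case fees (schema %s, %s)\n",
    nrow(x$items), nrow(x$rates), nrow(x$visits), nrow(x$case_fees),
    x$meta$schema_version, x$meta$currency))
  invisible(x)
}

.rate_for_role <- function(cat, role) {
  i <- match(role, cat$rates$role)
  if (is.na(i)) NA_real_ else cat$rates$rate_eur_per_min[i]
}

#' Total cost of reimbursement items
#'
#' Prices one or more catalogue items: each role effort contributes its
#' explicit component cost if present, otherwise `minutes * rate` for its
#' role (rounded to cents per component); material cost is added and the sum
#' scaled by `1 + overhead_rate`, rounded half-up to 2 decimals.
#'
#' @param catalogue a [cost_catalogue()].
#' @param item_id character vector of item ids; default all items.
#' @return named numeric vector of item totals in euro.
#' @examples
#' cat <- default_catalogue()
#' item_total_cost(cat, c("ecg", "doc-icu"))
#' @export
item_total_cost <- function(catalogue, item_id = NULL) {
  ids <- item_id %||% catalogue$items$item_id
  unknown <- setdiff(unique(ids), catalogue$items$item_id)
  if (length(unknown)) {
    pbrm_abort(paste0("unknown catalogue item(s): ",
                      paste(unknown, collapse = ", ")),
               class = "pbrm_lookup_error")
  }
  uids <- unique(ids)
  costs <- vapply(uids, function(id) .item_cost_one(catalogue, id), numeric(1))
  setNames(costs[match(ids, uids)], ids)
}

.item_cost_one <- function(cat, id) {
  ef <- cat$efforts[cat$efforts$item_id == id, ]
  comp <- numeric(0)
  if (nrow(ef)) {
    comp <- vapply(seq_len(nrow(ef)), function(i) {
      if (!is.na(ef$explicit_cost_eur[i])) return(money(ef$explicit_cost_eur[i]))
      rate <- .rate_for_role(cat, ef$role[i])
      if (is.na(rate) || is.na(ef$minutes[i])) {
        pbrm_abort(sprintf(
          "item '%s': no explicit cost and no rate resolvable for role '%s'",
          id, ef$role[i]), class = "pbrm_unresolved_rate_error")
      }
      money(ef$minutes[i] * rate)
    }, numeric(1))
  }
  row <- cat$items[cat$items$item_id == id, ]
  base <- money_sum(c(comp, money(row$material_cost_eur)))
  money(base * (1 + row$overhead_rate))
}

#' Check computed item totals against the printed reference totals
#'
#' Some source costing tables carry printed totals that disagree with their
#' own components at the cent level. This never silently "fixes" either side:
#' the catalogue stores both, computation uses the components, and this
#' function reports the discrepancies.
#'
#' @param catalogue a [cost_catalogue()].
#' @return tibble with `item_id`, `computed_total_eur`, `printed_total_eur`,
#'   `consistent`.
#' @export
catalogue_consistency <- function(catalogue) {
  computed <- item_total_cost(catalogue)
  tibble::tibble(
    item_id = catalogue$items$item_id,
    computed_total_eur = unname(computed),
    printed_total_eur = catalogue$items$printed_total_eur,
    consistent = is.na(catalogue$items$printed_total_eur) |
      abs(computed - catalogue$items$printed_total_eur) < 0.005
  )
}

#' Cost of one study visit
#'
#' A visit type is defined as a multiset of reimbursement items; its cost is
#' the sum of `count * item_total_cost` over the definition. Either name a
#' visit type defined in the catalogue (with cohort / centre class to
#' disambiguate) or pass an explicit `items` definition.
#'
#' @param catalogue a [cost_catalogue()].
#' @param visit_type_id visit type defined in the catalogue.
#' @param cohort,centre_class filters for the visit definition lookup.
#' @param items optional data frame with `item_id`, `count` overriding the
#'   catalogue lookup.
#' @return visit cost in euro (length 1).
#' @export
visit_cost <- function(catalogue, visit_type_id = NULL, cohort = NULL,
                       centre_class = NULL, items = NULL) {
  if (is.null(items)) {
    vs <- catalogue$visits
    vs <- vs[vs$visit_type_id == visit_type_id, ]
    if (!is.null(cohort)) vs <- vs[vs$cohort == cohort, ]
    if (!is.null(centre_class)) vs <- vs[vs$centre_class == centre_class, ]
    if (nrow(vs) == 0) {
      pbrm_abort(sprintf("no visit definition for '%s'%s", visit_type_id,
                         if (is.null(cohort)) "" else paste0(" in ", cohort)),
                 class = "pbrm_lookup_error")
    }
    if (length(unique(paste(vs$cohort, vs$centre_class))) > 1) {
      pbrm_abort(sprintf(
        "visit type '%s' is defined for several cohorts/classes; pass cohort and centre_class",
        visit_type_id), class = "pbrm_lookup_error")
    }
    items <- vs[, c("item_id", "count")]
  }
  if (nrow(items) == 0) return(0)
  costs <- item_total_cost(catalogue, items$item_id)
  money_sum(items$count * costs)
}

#' Expected reimbursement per case (the "case fee")
#'
#' The case fee is the expected mean reimbursement per case for a cohort and
#' centre class, adjusted for expected loss to follow-up and disease severity.
#' A configured constant (as negotiated for a study) takes precedence; absent
#' one, the fee is derived as the expectation over a distribution of visit
#' paths: `sum(probability * path cost)` where a path is an ordered vector of
#' visit type ids and its cost the sum of its visit costs.
#'
#' @param catalogue a [cost_catalogue()].
#' @param cohort,centre_class which case fee.
#' @param paths optional path distribution: data frame with a numeric
#'   `probability` column and a `visits` list-column of character vectors
#'   (an empty path costs 0).
#' @param use_configured set `FALSE` to force derivation from `paths` even
#'   when a configured fee exists.
#' @return expected case fee in euro.
#' @examples
#' expected_case_fee(default_catalogue(), "HAP", "AMC")
#' @export
expected_case_fee <- function(catalogue, cohort, centre_class = "AMC",
                              paths = NULL, use_configured = TRUE) {
  if (use_configured) {
    cf <- catalogue$case_fees
    i <- which(cf$cohort == cohort & cf$centre_class == centre_class)
    if (length(i) == 1 && !is.na(cf$configured_fee_eur[i])) {
      return(money(cf$configured_fee_eur[i]))
    }
  }
  if (is.null(paths)) {
    pbrm_abort(sprintf(
      "no configured case fee for %s/%s and no path distribution given",
      cohort, centre_class), class = "pbrm_spec_error")
  }
  paths <- tibble::as_tibble(paths)
  if (abs(sum(paths$probability) - 1) > 1e-9) {
    pbrm_abort("path probabilities must sum to 1", class = "pbrm_spec_error")
  }
  costs <- vapply(paths$visits, function(p) {
    if (length(p) == 0) return(0)
    money_sum(vapply(p, function(v) {
      visit_cost(catalogue, v, cohort = cohort, centre_class = centre_class)
    }, numeric(1)))
  }, numeric(1))
  money(sum(paths$probability * costs))
}
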