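.pbrm_schemas <- list(
  ecrf = c(ecrf_pseudonym = "c", centre_id = "c", visit_id = "c",
           visit_type_id = "c", visit_date = "D", form_id = "c",
           item_id = "c", value = "c", submitted = "l",
           plausibility_pass = "l", case_review_pass = "l",
           consent_registered = "l"),
  bio = c(bio_pseudonym = "c", visit_id = "c", sample_type = "c",
          aliquot_count = "i", registered = "l"),
  imaging = c(img_pseudonym = "c", visit_id = "c", modality = "c",
              series_count = "i", uploaded = "l"),
  centres = c(centre_id = "c", display_letter = "c", cohort = "c",
              centre_class = "c", target_cases = "d"),
  linkage = c(case_id = "c", ecrf_pseudonym = "c", bio_pseudonym = "c",
              img_pseudonym = "c")
)

#' Schema of a data-management-system export
#'
#' Returns the documented column set (name and type code in readr shorthand:
#' c character, D ISO-8601 date, i integer, d double, l logical) for one of
#' the five tabular exports: the eCRF clinical documentation (`ecrf`), the
#' biosampling registry (`bio`), the imaging upload metadata (`imaging`), the
#' centre registry (`centres`) and the trusted-third-party pseudonym linkage
#' (`linkage`). All identifiers are pseudonyms; no identity fields exist in
#' any schema.
#'
#' @param which one of `"ecrf"`, `"bio"`, `"imaging"`, `"centres"`,
#'   `"linkage"`.
#' @return named character vector of column type codes.
#' @export
export_schema <- function(which = c("ecrf", "bio", "imaging", "centres",
                                    "linkage")) {
  which <- match.arg(which)
  .pbrm_schemas[[which]]
}

.empty_export <- function(which) {
  sch <- .pbrm_schemas[[which]]
  cols <- lapply(sch, function(t) switch(
    t, c = character(), D = as.Date(character()), i = integer(),
    d = numeric(), l = logical()))
  tibble::as_tibble(cols)
}

#' Read one system export
#'
#' Reads a CSV (UTF-8, comma separator, dot decimal, ISO dates) or JSON-lines
#' (`.jsonl`) export, validates it against the documented schema and returns
#' typed records with their source row numbers (`.row`) preserved for error
#' reporting. Header mismatches, unparsable dates, negative counts and
#' duplicate keys are validation errors naming the offending rows.
#'
#' @param path file to read.
#' @param which which schema, see [export_schema()].
#' @return tibble of typed records with a `.row` column.
#' @export
read_export <- function(path, which = c("ecrf", "bio", "imaging", "centres",
                                        "linkage")) {
  which <- match.arg(which)
  if (!file.exists(path)) {
    pbrm_abort(paste0("export file not found: ", path),
               class = "pbrm_io_error")
  }
  sch <- .pbrm_schemas[[which]]
  if (grepl("\\.jsonl$", path)) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(lines)]
    df <- if (length(lines)) {
      tibble::as_tibble(jsonlite::stream_in(textConnection(lines),
                                            verbose = FALSE))
    } else {
      .empty_export(which)
    }
    missing <- setdiff(names(sch), names(df))
    for (col in missing) df[[col]] <- NA
    df <- df[, names(sch)]
    for (i in seq_along(sch)) {
      df[[i]] <- switch(sch[[i]], c = as.character(df[[i]]),
                        D = as.Date(df[[i]]), i = as.integer(df[[i]]),
                        d = as.numeric(df[[i]]), l = as.logical(df[[i]]))
    }
  } else {
    hdr <- names(readr::read_csv(path, n_max = 0, show_col_types = FALSE,
                                 col_types = readr::cols(.default = "c")))
    if (!setequal(hdr, names(sch))) {
      pbrm_abort(sprintf(
        "header of %s does not match the '%s' schema; unexpected: [%s], missing: [%s]",
        path, which,
        paste(setdiff(hdr, names(sch)), collapse = ", "),
        paste(setdiff(names(sch), hdr), collapse = ", ")),
        class = "pbrm_validation_error")
    }
    df <- suppressWarnings(
      readr::read_csv(path, show_col_types = FALSE,
                      col_types = do.call(readr::cols, as.list(sch))))
    prob <- readr::problems(df)
    if (nrow(prob)) {
      pbrm_abort(paste0(
        "unparsable values in ", path, " (rows ",
        paste(unique(prob$row), collapse = ", "), ")"),
        class = "pbrm_validation_error")
    }
    df <- df[, names(sch)]
  }
  df$.row <- seq_len(nrow(df))
  .validate_export(df, which, path)
  df
}

.validate_export <- function(df, which, path = "<export>") {
  err <- function(msg) pbrm_abort(paste0(path, ": ", msg),
                                  class = "pbrm_validation_error")
  if (which == "ecrf") {
    key <- paste(df$ecrf_pseudonym, df$visit_id, df$form_id, df$item_id,
                 sep = "\r")
    d <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (any(d)) {
      err(paste0("duplicate (pseudonym, visit, form, item) key in rows ",
                 paste(df$.row[d], collapse = ", ")))
    }
    bad <- df$.row[is.na(df$visit_date)]
    if (length(bad)) err(paste0("missing/unparsable visit_date in rows ",
                                paste(bad, collapse = ", ")))
  } else if (which == "bio") {
    bad <- df$.row[is.na(df$aliquot_count) | df$aliquot_count < 0]
    if (length(bad)) err(paste0("negative or missing aliquot_count in rows ",
                                paste(bad, collapse = ", ")))
  } else if (which == "imaging") {
    bad <- df$.row[is.na(df$series_count) | df$series_count < 0]
    if (length(bad)) err(paste0("negative or missing series_count in rows ",
                                paste(bad, collapse = ", ")))
  } else if (which == "centres") {
    bad <- df$.row[is.na(df$target_cases) | df$target_cases < 0]
    if (length(bad)) err(paste0("negative or missing target_cases in rows ",
                                paste(bad, collapse = ", ")))
    key <- paste(df$cohort, df$centre_class, df$display_letter)
    d <- duplicated(key) | duplicated(key, fromLast = TRUE)
    if (any(d)) err(paste0("display_letter not unique within cohort, rows ",
                           paste(df$.row[d], collapse = ", ")))
  } else if (which == "linkage") {
    for (col in c("ecrf_pseudonym", "bio_pseudonym", "img_pseudonym")) {
      v <- df[[col]]
      d <- !is.na(v) & (duplicated(v, incomparables = NA) |
                          duplicated(v, incomparables = NA, fromLast = TRUE))
      if (any(d)) {
        err(paste0(col, " appears under more than one case, rows ",
                   paste(df$.row[d], collapse = ", ")))
      }
    }
    d <- duplicated(df$case_id) | duplicated(df$case_id, fromLast = TRUE)
    if (any(d)) err(paste0("duplicate case_id in rows ",
                           paste(df$.row[d], collapse = ", ")))
  }
  invisible(df)
}

#' Write one system export
#'
#' @param df records (extra bookkeeping columns such as `.row` are dropped).
#' @param path destination `.csv` or `.jsonl` file.
#' @param which which schema, see [export_schema()].
#' @return `path`, invisibly.
#' @export
write_export <- function(df, path, which = c("ecrf", "bio", "imaging",
                                             "centres", "linkage")) {
  which <- match.arg(which)
  sch <- .pbrm_schemas[[which]]
  missing <- setdiff(names(sch), names(df))
  if (length(missing)) {
    pbrm_abort(paste0("cannot write '", which, "' export, missing columns: ",
                      paste(missing, collapse = ", ")),
               class = "pbrm_validation_error")
  }
  df <- df[, names(sch)]
  if (grepl("\\.jsonl$", path)) {
    con <- file(path, open = "w", encoding = "UTF-8")
    on.exit(close(con))
    jsonlite::stream_out(as.data.frame(df), con, verbose = FALSE)
  } else {
    readr::write_csv(df, path, na = "NA")
  }
  invisible(path)
}

#' Link system exports into reimbursement-case dossiers
#'
#' Joins the three pseudonymised system exports through the
#' trusted-third-party linkage table into one dossier per case. The eCRF is
#' the anchor system: a case without any eCRF record is not a dossier and its
#' biosampling/imaging records are reported as orphans (report-and-continue;
#' partial uploads are normal in practice). Biosampling and imaging records
#' whose pseudonym has no linkage row are likewise orphaned, never silently
#' dropped. The result is independent of input row order.
#'
#' @param linkage,ecrf,bio,imaging,centres record tibbles as returned by
#'   [read_export()] (or built in memory with the same columns).
#' @return an object of class `pbrm_dossiers`: a list with `cases` (one row
#'   per dossier: case_id, centre, cohort, class, target), the per-system
#'   record tibbles augmented with `case_id`, the `orphans` per system, and
#'   the centre registry.
#' @export
link_cases <- function(linkage, ecrf, bio = NULL, imaging = NULL,
                       centres = NULL) {
  linkage <- .with_rows(tibble::as_tibble(linkage))
  ecrf <- .with_rows(tibble::as_tibble(ecrf))
  bio <- .with_rows(tibble::as_tibble(bio %||% .empty_export("bio")))
  imaging <- .with_rows(tibble::as_tibble(imaging %||% .empty_export("imaging")))
  centres <- tibble::as_tibble(centres %||% .empty_export("centres"))
  .validate_export(linkage, "linkage", "<linkage>")

  ecrf2 <- dplyr::inner_join(ecrf,
                             linkage[, c("case_id", "ecrf_pseudonym")],
                             by = "ecrf_pseudonym")
  orph_ecrf <- dplyr::anti_join(ecrf, linkage[, "ecrf_pseudonym", drop = FALSE],
                                by = "ecrf_pseudonym")

  case_centre <- dplyr::distinct(ecrf2[, c("case_id", "centre_id")])
  d <- duplicated(case_centre$case_id) |
    duplicated(case_centre$case_id, fromLast = TRUE)
  if (any(d)) {
    pbrm_abort(paste0("case linked to more than one centre: ",
                      paste(unique(case_centre$case_id[d]), collapse = ", ")),
               class = "pbrm_linkage_error")
  }
  cases <- dplyr::left_join(case_centre, centres, by = "centre_id")
  cases <- dplyr::arrange(cases, .data$case_id)

  link_bio <- linkage[!is.na(linkage$bio_pseudonym) &
                        linkage$case_id %in% cases$case_id,
                      c("case_id", "bio_pseudonym")]
  bio2 <- dplyr::inner_join(bio, link_bio, by = "bio_pseudonym")
  orph_bio <- bio[!bio$bio_pseudonym %in% link_bio$bio_pseudonym, ]

  link_img <- linkage[!is.na(linkage$img_pseudonym) &
                        linkage$case_id %in% cases$case_id,
                      c("case_id", "img_pseudonym")]
  img2 <- dplyr::inner_join(imaging, link_img, by = "img_pseudonym")
  orph_img <- imaging[!imaging$img_pseudonym %in% link_img$img_pseudonym, ]

  sort_by <- function(df, cols) {
    df[do.call(order, unname(as.list(df[, cols]))), , drop = FALSE]
  }
  structure(list(
    cases = cases,
    ecrf = sort_by(ecrf2, c("case_id", "visit_id", "form_id", "item_id")),
    bio = sort_by(bio2, c("case_id", "visit_id", "sample_type",
                          "aliquot_count", "registered")),
    imaging = sort_by(img2, c("case_id", "visit_id", "modality",
                              "series_count", "uploaded")),
    orphans = list(ecrf = orph_ecrf, bio = orph_bio, imaging = orph_img),
    centres = centres
  ), class = "pbrm_dossiers")
}

.with_rows <- function(df) {
  if (!".row" %in% names(df)) df$.row <- seq_len(nrow(df))
  df
}

#' @export
print.pbrm_dossiers <- function(x, ...) {
  cat(sprintf(
    "<pbrm_dossiers> %d cases | records: %d eCRF, %d biosampling, %d imaging | orphans: %d/%d/%d\n",
    nrow(x$cases), nrow(x$ecrf), nrow(x$bio), nrow(x$imaging),
    nrow(x$orphans$ecrf), nrow(x$orphans$bio), nrow(x$orphans$imaging)))
  invisible(x)
}
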