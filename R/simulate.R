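#' Synthetic cohort simulation configuration
#'
#' Describes the generative model of a multi-centre cohort: heterogeneous
#' per-centre recruitment, disease severity (ICU probability and lengths of
#' stay driving the number of inpatient visits), follow-up compliance,
#' drop-out, and the documentation noise the quality gates exist for
#' (unsubmitted forms, plausibility failures, missed case reviews, missing
#' biosampling/imaging participation, under-threshold aliquot counts). All
#' randomness is driven by the mandatory seed.
#'
#' Length-of-stay distributions are either `list(dist = "geometric", mean =
#' m)` (days >= 1, memoryless discharge) or an explicit
#' `list(dist = "pmf", values = v, probs = p)`.
#'
#' @param seed integer seed (mandatory).
#' @param cohort,centre_class cohort platform and centre class.
#' @param n_centres number of centres (at most 26; centres are
#'   pseudonymised A..Z).
#' @param cases_per_centre integer vector of length `n_centres`, or
#'   `list(dist = "uniform_int", min =, max =)`.
#' @param target_cases targeted case number per centre.
#' @param p_icu probability that a case has an ICU episode.
#' @param los_ward,los_icu length-of-stay distributions (days).
#' @param p_dropout probability that a case drops out before discharge
#'   (no discharge form, hence not reimbursable).
#' @param fu_compliance probability that each scheduled follow-up visit is
#'   attended and documented.
#' @param fu_visits follow-up visit types scheduled per case.
#' @param fu_due_days days after recruitment each follow-up is due.
#' @param p_consent probability that informed consent is registered.
#' @param p_form_missing probability that a visit's form set is not
#'   submitted.
#' @param p_plausibility_fail per-record probability of failing the
#'   automated plausibility checks.
#' @param p_case_review_fail per-record probability that the local case
#'   review is missing/failed (relevant for the cross-sectoral cohort).
#' @param p_bio probability that biosampling of a scheduled visit takes
#'   place.
#' @param min_aliquots,aliquot_lambda aliquot count is
#'   `min_aliquots + Poisson(aliquot_lambda)` for compliant samples.
#' @param p_aliquot_low probability that a sample registers fewer than
#'   `min_aliquots` aliquots (and is hence not reimbursable).
#' @param p_imaging probability that a scheduled imaging series is acquired.
#' @param p_upload_fail probability that an acquired series is not uploaded.
#' @param start_date,recruit_days recruitment window.
#' @param freeze_date documentation freeze; follow-ups due later are
#'   announced (for imputation) rather than documented.
#' @return validated `pbrm_sim_config` list.
#' @export
sim_config <- function(seed,
                       cohort = c("HAP", "POP", "SUEP"),
                       centre_class = c("AMC", "non-AMC"),
                       n_centres = 5,
                       cases_per_centre = list(dist = "uniform_int",
                                               min = 1, max = 30),
                       target_cases = 73.5,
                       p_icu = 0.3,
                       los_ward = list(dist = "geometric", mean = 4),
                       los_icu = list(dist = "geometric", mean = 3),
                       p_dropout = 0.05,
                       fu_compliance = 0.6,
                       fu_visits = c("fu-3mo", "fu-12mo"),
                       fu_due_days = c(90, 360),
                       p_consent = 1,
                       p_form_missing = 0.02,
                       p_plausibility_fail = 0.03,
                       p_case_review_fail = 0,
                       p_bio = 0.9,
                       min_aliquots = 2L,
                       aliquot_lambda = 3,
                       p_aliquot_low = 0.08,
                       p_imaging = 0.8,
                       p_upload_fail = 0.02,
                       start_date = as.Date("2020-11-01"),
                       recruit_days = 365,
                       freeze_date = as.Date("2029-12-31")) {
  if (missing(seed) || is.null(seed) || is.na(seed)) {
    pbrm_abort("a seed is mandatory for the simulator",
               class = "pbrm_config_error")
  }
  cfg <- list(seed = as.integer(seed), cohort = match.arg(cohort),
              centre_class = match.arg(centre_class),
              n_centres = as.integer(n_centres),
              cases_per_centre = cases_per_centre,
              target_cases = target_cases, p_icu = p_icu,
              los_ward = los_ward, los_icu = los_icu,
              p_dropout = p_dropout, fu_compliance = fu_compliance,
              fu_visits = fu_visits, fu_due_days = fu_due_days,
              p_consent = p_consent, p_form_missing = p_form_missing,
              p_plausibility_fail = p_plausibility_fail,
              p_case_review_fail = p_case_review_fail, p_bio = p_bio,
              min_aliquots = as.integer(min_aliquots),
              aliquot_lambda = aliquot_lambda,
              p_aliquot_low = p_aliquot_low, p_imaging = p_imaging,
              p_upload_fail = p_upload_fail,
              start_date = as.Date(start_date),
              recruit_days = as.integer(recruit_days),
              freeze_date = as.Date(freeze_date))
  class(cfg) <- "pbrm_sim_config"
  validate_sim_config(cfg)
  cfg
}

validate_sim_config <- function(cfg) {
  probs <- c(cfg$p_icu, cfg$p_dropout, cfg$fu_compliance, cfg$p_consent,
             cfg$p_form_missing, cfg$p_plausibility_fail,
             cfg$p_case_review_fail, cfg$p_bio, cfg$p_aliquot_low,
             cfg$p_imaging, cfg$p_upload_fail)
  if (any(is.na(probs)) || any(probs < 0) || any(probs > 1)) {
    pbrm_abort("all probabilities must lie in [0, 1]",
               class = "pbrm_config_error")
  }
  if (cfg$n_centres < 1 || cfg$n_centres > 26) {
    pbrm_abort("n_centres must be between 1 and 26",
               class = "pbrm_config_error")
  }
  .validate_los(cfg$los_ward)
  .validate_los(cfg$los_icu)
  if (is.numeric(cfg$cases_per_centre)) {
    if (length(cfg$cases_per_centre) != cfg$n_centres ||
        any(cfg$cases_per_centre < 1)) {
      pbrm_abort(
        "explicit cases_per_centre must give a positive count per centre",
        class = "pbrm_config_error")
    }
  } else {
    cc <- cfg$cases_per_centre
    if (!identical(cc$dist, "uniform_int") || cc$min < 1 ||
        cc$max < cc$min) {
      pbrm_abort("invalid cases_per_centre sampler",
                 class = "pbrm_config_error")
    }
  }
  if (length(cfg$fu_due_days) != length(cfg$fu_visits)) {
    pbrm_abort("fu_due_days must match fu_visits",
               class = "pbrm_config_error")
  }
  if (cfg$min_aliquots < 0 || cfg$aliquot_lambda < 0) {
    pbrm_abort("invalid aliquot parameters", class = "pbrm_config_error")
  }
  invisible(cfg)
}

.validate_los <- function(los) {
  ok <- is.list(los) && (
    (identical(los$dist, "geometric") && is.numeric(los$mean) &&
       los$mean >= 1) ||
      (identical(los$dist, "pmf") && length(los$values) &&
         length(los$values) == length(los$probs) &&
         all(los$probs >= 0) && abs(sum(los$probs) - 1) < 1e-9 &&
         all(los$values >= 0)))
  if (!ok) {
    pbrm_abort("invalid length-of-stay distribution",
               class = "pbrm_config_error")
  }
  invisible(los)
}

.draw_los <- function(los) {
  if (identical(los$dist, "pmf")) {
    if (length(los$values) == 1) return(los$values)
    sample(los$values, 1, prob = los$probs)
  } else {
    1 + rgeom(1, prob = 1 / los$mean)
  }
}

.los_pmf <- function(los, tail_tol = 1e-10) {
  if (identical(los$dist, "pmf")) {
    return(list(values = los$values, probs = los$probs))
  }
  p <- 1 / los$mean
  kmax <- max(1, ceiling(log(tail_tol) / log(1 - p + 1e-15)))
  k <- seq_len(kmax)
  probs <- p * (1 - p)^(k - 1)
  list(values = k, probs = probs / sum(probs))
}

#' Preset simulation configurations
#'
#' Study-shaped presets: `hap_like` (deep-phenotyping inpatient cohort, 10
#' centres with strongly heterogeneous recruitment of 4-164 cases around a
#' 73.5-case target, ICU episodes, 50% follow-up compliance), `pop_like`
#' (population-based cohort: an initial interview plus exactly one on-site
#' visit per case, 3 large centres, targets 330/660), `suep_amc_like`
#' (cross-sectoral academic centres, 98.1-case target, case reviews
#' required) and `suep_nonamc_like` (non-academic centres, documentation
#' only, no biosampling).
#'
#' @param name preset name.
#' @param seed integer seed.
#' @param ... overrides forwarded to [sim_config()].
#' @return a [sim_config()].
#' @export
sim_preset <- function(name = c("hap_like", "pop_like", "suep_amc_like",
                                "suep_nonamc_like"), seed, ...) {
  name <- match.arg(name)
  args <- switch(
    name,
    hap_like = list(
      cohort = "HAP", centre_class = "AMC", n_centres = 10,
      cases_per_centre = c(164, 102, 60, 40, 28, 20, 12, 8, 6, 4),
      target_cases = 73.5, p_icu = 0.3,
      los_ward = list(dist = "geometric", mean = 4),
      los_icu = list(dist = "geometric", mean = 3),
      p_dropout = 0.05, fu_compliance = 0.5),
    pop_like = list(
      cohort = "POP", centre_class = "AMC", n_centres = 3,
      cases_per_centre = c(301, 348, 1663), target_cases = 330,
      fu_visits = character(), fu_due_days = numeric(),
      p_dropout = 0, p_icu = 0),
    suep_amc_like = list(
      cohort = "SUEP", centre_class = "AMC", n_centres = 20,
      cases_per_centre = list(dist = "uniform_int", min = 3, max = 110),
      target_cases = 98.1, p_icu = 0.2,
      los_ward = list(dist = "geometric", mean = 3),
      p_dropout = 0.05, fu_compliance = 0.63, p_case_review_fail = 0.01),
    suep_nonamc_like = list(
      cohort = "SUEP", centre_class = "non-AMC", n_centres = 12,
      cases_per_centre = list(dist = "uniform_int", min = 1, max = 40),
      target_cases = 30, p_icu = 0.05,
      los_ward = list(dist = "geometric", mean = 2),
      p_dropout = 0.05, fu_compliance = 0.7, p_bio = 0, p_imaging = 0.3))
  do.call(sim_config, utils::modifyList(args, c(list(seed = seed),
                                                list(...))))
}

.form_for_visit <- function(vt) {
  c("pop-initial-interview" = "initial-interview",
    "pop-onsite" = "on-site")[vt] -> f
  ifelse(is.na(f), vt, f)
}

.visit_items <- function(catalogue, cohort, centre_class) {
  vs <- catalogue$visits
  vs <- vs[vs$cohort == cohort & vs$centre_class == centre_class, ]
  split(vs[, c("item_id", "count")], vs$visit_type_id)
}

.case_visit_types <- function(cfg) {
  if (cfg$cohort == "POP") {
    return(list(visits = c("pop-initial-interview", "pop-onsite"),
                dropout = FALSE, fu = character()))
  }
  dropout <- runif(1) < cfg$p_dropout
  w <- .draw_los(cfg$los_ward)
  icu_days <- if (runif(1) < cfg$p_icu) .draw_los(cfg$los_icu) else 0
  fu <- if (!dropout) {
    cfg$fu_visits[runif(length(cfg$fu_visits)) < cfg$fu_compliance]
  } else {
    character()
  }
  visits <- c("baseline", rep("ward-day", w), rep("icu-day", icu_days),
              if (!dropout) "discharge")
  list(visits = visits, dropout = dropout, fu = fu)
}

#' Simulate a multi-centre study bundle
#'
#' Generates the five pseudonymised exports (eCRF, biosampling, imaging,
#' centre registry, pseudonym linkage) for a synthetic cohort plus a ground
#' truth table carrying, for every case, its reimbursability and the exact
#' reimbursable amount implied by the generated records under the catalogue
#' and rules. The generator computes ground truth record-by-record during
#' generation, so downstream tests never have to re-derive it through the
#' statement engine. Byte-identical under a fixed seed.
#'
#' @param config a [sim_config()] or [sim_preset()].
#' @param catalogue a [cost_catalogue()] whose visit definitions cover the
#'   configured cohort.
#' @param rules rule set ([default_rules()]); determines which visit items
#'   are biosampling / imaging activities and their reimbursement gates.
#' @return object of class `pbrm_bundle`: list with `ecrf`, `biosamples`,
#'   `imaging`, `centres`, `linkage`, `ground_truth`, `announced`, `config`.
#' @export
simulate_cohort <- function(config, catalogue = default_catalogue(),
                            rules = default_rules()) {
  validate_sim_config(config)
  withr::with_seed(config$seed, .simulate_impl(config, catalogue, rules))
}

.simulate_impl <- function(cfg, catalogue, rules) {
  item_cost <- item_total_cost(catalogue)
  vdefs <- .visit_items(catalogue, cfg$cohort, cfg$centre_class)
  if (length(vdefs) == 0) {
    pbrm_abort(sprintf("catalogue defines no visits for %s/%s", cfg$cohort,
                       cfg$centre_class), class = "pbrm_config_error")
  }
  bio_items <- rules$bio$item_id
  img_items <- rules$img$item_id

  counts <- if (is.numeric(cfg$cases_per_centre)) {
    as.integer(cfg$cases_per_centre)
  } else {
    cc <- cfg$cases_per_centre
    sample(seq(cc$min, cc$max), cfg$n_centres, replace = TRUE)
  }
  centres <- tibble::tibble(
    centre_id = sprintf("C%02d", seq_len(cfg$n_centres)),
    display_letter = LETTERS[seq_len(cfg$n_centres)],
    cohort = cfg$cohort, centre_class = cfg$centre_class,
    target_cases = cfg$target_cases)

  ecrf_l <- list(); bio_l <- list(); img_l <- list(); ann_l <- list()
  gt_l <- list()
  case_no <- 0L
  for (ci in seq_len(cfg$n_centres)) {
    for (k in seq_len(counts[ci])) {
      case_no <- case_no + 1L
      ids <- list(case = sprintf("CASE-%05d", case_no),
                  e = sprintf("E-%05d", case_no),
                  b = sprintf("B-%05d", case_no),
                  i = sprintf("I-%05d", case_no))
      recruit <- cfg$start_date + floor(runif(1) * cfg$recruit_days)
      consent <- runif(1) < cfg$p_consent
      path <- .case_visit_types(cfg)

      visit_dates <- recruit + seq_along(path$visits) - 1
      fu_idx <- match(path$fu, cfg$fu_visits)
      fu_dates <- recruit + cfg$fu_due_days[fu_idx]
      announced <- path$fu[fu_dates > cfg$freeze_date]
      doc_fu <- path$fu[fu_dates <= cfg$freeze_date]
      doc_fu_dates <- fu_dates[fu_dates <= cfg$freeze_date]

      all_visits <- c(path$visits, doc_fu)
      all_dates <- c(visit_dates, doc_fu_dates)

      n_rec <- 0L
      rec_rows <- vector("list", length(all_visits))
      bio_rows <- list(); img_rows <- list()
      cents <- 0
      forms_ok <- list()
      review_ok <- TRUE

      for (vi in seq_along(all_visits)) {
        vt <- all_visits[vi]
        vd <- vdefs[[vt]]
        if (is.null(vd)) {
          pbrm_abort(sprintf("no visit definition for '%s' in %s/%s", vt,
                             cfg$cohort, cfg$centre_class),
                     class = "pbrm_config_error")
        }
        visit_id <- sprintf("%s-V%02d", ids$case, vi)
        submitted <- runif(1) >= cfg$p_form_missing
        form <- unname(.form_for_visit(vt))
        forms_ok[[form]] <- isTRUE(forms_ok[[form]]) || submitted

        e_items <- vd$item_id[!vd$item_id %in% c(bio_items, img_items)]
        if (length(e_items)) {
          plaus <- runif(length(e_items)) >= cfg$p_plausibility_fail
          review <- runif(length(e_items)) >= cfg$p_case_review_fail
          if (any(!review)) review_ok <- FALSE
          n_rec <- n_rec + length(e_items)
          rec_rows[[vi]] <- tibble::tibble(
            ecrf_pseudonym = ids$e, centre_id = centres$centre_id[ci],
            visit_id = visit_id, visit_type_id = vt,
            visit_date = all_dates[vi], form_id = form,
            item_id = paste0("crf-", e_items),
            value = sprintf("v%03d", seq_along(e_items)),
            submitted = submitted, plausibility_pass = plaus,
            case_review_pass = review, consent_registered = consent)
          cents <- cents + sum(round(item_cost[e_items] * 100) *
                                 (submitted & plaus))
        }
        for (bi in intersect(vd$item_id, bio_items)) {
          if (runif(1) < cfg$p_bio) {
            low <- runif(1) < cfg$p_aliquot_low
            aliquots <- if (low && cfg$min_aliquots > 0) {
              sample(0:(cfg$min_aliquots - 1), 1)
            } else {
              cfg$min_aliquots + rpois(1, cfg$aliquot_lambda)
            }
            st <- rules$bio$sample_type[match(bi, rules$bio$item_id)]
            bio_rows[[length(bio_rows) + 1]] <- tibble::tibble(
              bio_pseudonym = ids$b, visit_id = visit_id, sample_type = st,
              aliquot_count = as.integer(aliquots), registered = TRUE)
            if (aliquots >= cfg$min_aliquots) {
              cents <- cents + round(item_cost[bi] * 100)
            }
          }
        }
        for (ii in intersect(vd$item_id, img_items)) {
          if (runif(1) < cfg$p_imaging) {
            uploaded <- runif(1) >= cfg$p_upload_fail
            series <- if (uploaded) 1L + rpois(1, 0.5) else 0L
            mo <- rules$img$modality[match(ii, rules$img$item_id)]
            img_rows[[length(img_rows) + 1]] <- tibble::tibble(
              img_pseudonym = ids$i, visit_id = visit_id, modality = mo,
              series_count = as.integer(series), uploaded = uploaded)
            if (uploaded && series >= 1) {
              cents <- cents + round(item_cost[ii] * 100)
            }
          }
        }
      }

      erules <- eligibility_rules(cfg$cohort)
      required_ok <- all(vapply(erules$required_forms,
                                function(f) isTRUE(forms_ok[[f]]),
                                logical(1)))
      reimb <- consent && required_ok &&
        (!erules$require_case_review || review_ok)

      ecrf_l[[case_no]] <- dplyr::bind_rows(rec_rows)
      if (length(bio_rows)) {
        bio_l[[length(bio_l) + 1]] <- dplyr::bind_rows(bio_rows)
      }
      if (length(img_rows)) {
        img_l[[length(img_l) + 1]] <- dplyr::bind_rows(img_rows)
      }
      if (length(announced)) {
        ann_l[[length(ann_l) + 1]] <- tibble::tibble(
          case_id = ids$case, visit_type_id = announced,
          due_date = fu_dates[fu_dates > cfg$freeze_date])
      }
      gt_l[[case_no]] <- tibble::tibble(
        case_id = ids$case, centre_id = centres$centre_id[ci],
        ecrf_pseudonym = ids$e, bio_pseudonym = ids$b,
        img_pseudonym = ids$i, reimbursable = reimb,
        true_total_eur = if (reimb) unname(cents) / 100 else 0,
        path = paste(all_visits, collapse = "|"))
    }
  }

  gt <- dplyr::bind_rows(gt_l)
  structure(list(
    ecrf = dplyr::bind_rows(ecrf_l),
    biosamples = if (length(bio_l)) dplyr::bind_rows(bio_l) else
      .empty_export("bio"),
    imaging = if (length(img_l)) dplyr::bind_rows(img_l) else
      .empty_export("imaging"),
    centres = centres,
    linkage = tibble::tibble(case_id = gt$case_id,
                             ecrf_pseudonym = gt$ecrf_pseudonym,
                             bio_pseudonym = gt$bio_pseudonym,
                             img_pseudonym = gt$img_pseudonym),
    ground_truth = gt[, c("case_id", "centre_id", "reimbursable",
                          "true_total_eur", "path")],
    announced = if (length(ann_l)) dplyr::bind_rows(ann_l) else
      tibble::tibble(case_id = character(), visit_type_id = character(),
                     due_date = as.Date(character())),
    config = cfg
  ), class = "pbrm_bundle")
}

#' @export
print.pbrm_bundle <- function(x, ...) {
  cat(sprintf(
    "<pbrm_bundle> %s/%s: %d cases in %d centres | %d eCRF, %d biosampling, %d imaging records\n",
    x$config$cohort, x$config$centre_class, nrow(x$ground_truth),
    nrow(x$centres), nrow(x$ecrf), nrow(x$biosamples), nrow(x$imaging)))
  invisible(x)
}

#' Write / read a simulated bundle as export files
#'
#' @param bundle a [simulate_cohort()] result.
#' @param dir output directory; receives `ecrf.csv`, `biosamples.csv`,
#'   `imaging.csv`, `centres.csv`, `linkage.csv` plus `ground_truth.csv`
#'   and `announced.csv`.
#' @return `dir` / a list of export tibbles, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_export(bundle$ecrf, file.path(dir, "ecrf.csv"), "ecrf")
  write_export(bundle$biosamples, file.path(dir, "biosamples.csv"), "bio")
  write_export(bundle$imaging, file.path(dir, "imaging.csv"), "imaging")
  write_export(bundle$centres, file.path(dir, "centres.csv"), "centres")
  write_export(bundle$linkage, file.path(dir, "linkage.csv"), "linkage")
  readr::write_csv(bundle$ground_truth, file.path(dir, "ground_truth.csv"),
                   na = "NA")
  readr::write_csv(bundle$announced, file.path(dir, "announced.csv"),
                   na = "NA")
  invisible(dir)
}

#' @rdname write_bundle
#' @param dir directory holding the five export files.
#' @export
read_exports_dir <- function(dir) {
  list(ecrf = read_export(file.path(dir, "ecrf.csv"), "ecrf"),
       biosamples = read_export(file.path(dir, "biosamples.csv"), "bio"),
       imaging = read_export(file.path(dir, "imaging.csv"), "imaging"),
       centres = read_export(file.path(dir, "centres.csv"), "centres"),
       linkage = read_export(file.path(dir, "linkage.csv"), "linkage"))
}

#' Analytic case-fee specification implied by a simulation configuration
#'
#' Enumerates the visit-path distribution a configuration implies (lengths
#' of stay, ICU episode, drop-out, follow-up compliance) so that
#' [expected_case_fee()] can price it in closed form. Only defined for
#' configurations without record-level documentation noise (no unsubmitted
#' forms, plausibility or review failures, full biosampling/imaging
#' participation), where the realised case cost is exactly the path cost; a
#' drop-out contributes an empty (zero-cost) path because it fails the
#' minimum reimbursement criteria.
#'
#' @param config a [sim_config()].
#' @return tibble with `probability` and a `visits` list-column, summing to
#'   probability 1.
#' @export
implied_case_paths <- function(config) {
  cfg <- config
  noisy <- cfg$p_consent < 1 || cfg$p_form_missing > 0 ||
    cfg$p_plausibility_fail > 0 || cfg$p_case_review_fail > 0 ||
    cfg$p_bio < 1 || cfg$p_aliquot_low > 0 || cfg$p_imaging < 1 ||
    cfg$p_upload_fail > 0
  if (noisy) {
    pbrm_abort(paste0(
      "the analytic path distribution is only defined for configurations ",
      "without record-level documentation noise"),
      class = "pbrm_config_error")
  }
  if (cfg$cohort == "POP") {
    return(tibble::tibble(
      probability = 1,
      visits = list(c("pop-initial-interview", "pop-onsite"))))
  }
  ward <- .los_pmf(cfg$los_ward)
  icu <- .los_pmf(cfg$los_icu)
  icu_branch <- list(list(p = 1 - cfg$p_icu, days = 0))
  for (j in seq_along(icu$values)) {
    icu_branch[[j + 1]] <- list(p = cfg$p_icu * icu$probs[j],
                                days = icu$values[j])
  }
  nfu <- length(cfg$fu_visits)
  fu_sets <- list(character())
  if (nfu > 0) {
    fu_sets <- unlist(lapply(0:nfu, function(k) {
      utils::combn(cfg$fu_visits, k, simplify = FALSE)
    }), recursive = FALSE)
  }
  rows <- list(tibble::tibble(probability = cfg$p_dropout,
                              visits = list(character())))
  for (wi in seq_along(ward$values)) {
    for (ib in icu_branch) {
      for (fs in fu_sets) {
        p <- (1 - cfg$p_dropout) * ward$probs[wi] * ib$p *
          cfg$fu_compliance^length(fs) *
          (1 - cfg$fu_compliance)^(nfu - length(fs))
        if (p <= 0) next
        rows[[length(rows) + 1]] <- tibble::tibble(
          probability = p,
          visits = list(c("baseline", rep("ward-day", ward$values[wi]),
                          rep("icu-day", ib$days), "discharge", fs)))
      }
    }
  }
  out <- dplyr::bind_rows(rows)
  out[out$probability > 0, ]
}
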