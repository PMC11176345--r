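#' Fixed-rate model specification
#'
#' The fixed-rate model (FRM) pays one post-hoc case fee per actually
#' reimbursed case. Defaults are the negotiated expected case fees per
#' cohort and centre class.
#'
#' @param fees data frame with `cohort`, `centre_class`, `case_fee_eur`.
#' @return tibble of fees.
#' @export
frm_spec <- function(fees = NULL) {
  fees <- fees %||% tibble::tibble(
    cohort = c("HAP", "POP", "SUEP", "SUEP"),
    centre_class = c("AMC", "AMC", "AMC", "non-AMC"),
    case_fee_eur = c(12871.70, 3400.76, 2904.67, 1071.23))
  fees <- tibble::as_tibble(fees)
  if (any(fees$case_fee_eur <= 0)) {
    pbrm_abort("FRM case fees must be positive",
               class = "pbrm_validation_error")
  }
  fees
}

.frm_fee <- function(spec, cohort, centre_class) {
  i <- which(spec$cohort == cohort & spec$centre_class == centre_class)
  if (length(i) != 1) {
    pbrm_abort(sprintf("no FRM case fee configured for %s/%s", cohort,
                       centre_class), class = "pbrm_config_error")
  }
  spec$case_fee_eur[i]
}

#' Fixed-rate funding of one centre
#'
#' @param n_reimbursable number of reimbursed cases.
#' @param cohort,centre_class which case fee applies.
#' @param spec a [frm_spec()].
#' @return funding in euro: `case_fee * n_reimbursable`.
#' @export
frm_funding <- function(n_reimbursable, cohort, centre_class = "AMC",
                        spec = frm_spec()) {
  money(.frm_fee(spec, cohort, centre_class) * n_reimbursable)
}

#' Up-front allocation model specification
#'
#' The up-front allocation model (UFAM) funds each centre before the study:
#' physician and study-nurse positions (rounded to the nearest quarter FTE,
#' ties away from zero) plus consumables per case times the targeted case
#' number. Where staffing inputs are unknown, a per-centre lump-sum
#' `total_eur` may be supplied instead.
#'
#' @param centres data frame with `centre_id` and either `total_eur` or the
#'   staffing columns `physician_fte`, `nurse_fte`,
#'   `fte_cost_physician_eur`, `fte_cost_nurse_eur`,
#'   `consumables_per_case_eur`.
#' @return tibble.
#' @export
ufam_spec <- function(centres) {
  centres <- tibble::as_tibble(centres)
  num_cols <- intersect(c("physician_fte", "nurse_fte",
                          "fte_cost_physician_eur", "fte_cost_nurse_eur",
                          "consumables_per_case_eur", "total_eur"),
                        names(centres))
  for (col in num_cols) {
    if (any(centres[[col]] < 0, na.rm = TRUE)) {
      pbrm_abort(paste0("negative values in UFAM column ", col),
                 class = "pbrm_validation_error")
    }
  }
  centres
}

#' Up-front allocation funding of one centre
#'
#' @param spec_row one row of a [ufam_spec()].
#' @param target_cases the centre's targeted case number.
#' @return funding in euro.
#' @export
ufam_funding <- function(spec_row, target_cases) {
  if ("total_eur" %in% names(spec_row) && !is.na(spec_row$total_eur)) {
    return(money(spec_row$total_eur))
  }
  staffing <- money_sum(c(
    money(round_quarter(spec_row$physician_fte) *
            spec_row$fte_cost_physician_eur),
    money(round_quarter(spec_row$nurse_fte) * spec_row$fte_cost_nurse_eur)))
  money_sum(c(staffing,
              money(spec_row$consumables_per_case_eur * target_cases)))
}

#' Funding of a model relative to the performance-based reference
#'
#' The performance-based model is the 100% reference per centre:
#' `reference = mean_per_case * n`, where `n` is the reimbursed case count,
#' capped at the centre's target number when `cap = TRUE` (a centre would
#' have stopped recruiting at target under an up-front model, so
#' over-recruiters are compared at target).
#'
#' @param model_funding funding of the alternative model, euro.
#' @param mean_per_case_eur performance-based mean reimbursement per case.
#' @param n_reimbursable reimbursed case count.
#' @param target_cases targeted case number (needed when `cap = TRUE`).
#' @param cap cap the reference at the target number?
#' @return percentage of the performance-based reference, 1 decimal.
#' @export
relative_to_pbrm <- function(model_funding, mean_per_case_eur,
                             n_reimbursable, target_cases = NULL,
                             cap = TRUE) {
  n_eff <- if (cap) {
    if (is.null(target_cases) || is.na(target_cases)) {
      pbrm_abort("capping requested but target_cases is unknown",
                 class = "pbrm_config_error")
    }
    pmin(n_reimbursable, target_cases)
  } else {
    n_reimbursable
  }
  ref <- mean_per_case_eur * n_eff
  if (is.na(ref) || ref == 0) {
    pbrm_abort("performance-based reference is zero; comparison undefined",
               class = "pbrm_undefined_comparison_error")
  }
  pct1(100 * model_funding / ref)
}

#' Cases affordable per budget unit
#'
#' Cost-efficiency statistic: the number of cases that a fixed budget
#' (default 10,000 euro) buys under a model, per centre, with the cohort
#' mean and a two-sided t-based 95% confidence interval across centres
#' (absent for a single centre; zero-width for identical centres).
#'
#' @param cost_per_case_eur per-centre effective cost per case under the
#'   model.
#' @param budget_eur budget unit.
#' @return list with `values` (per centre), `mean`, `ci_lo`, `ci_hi`
#'   (reported to 1 decimal), and `n_centres`.
#' @export
cases_per_budget_unit <- function(cost_per_case_eur, budget_eur = 10000) {
  if (any(is.na(cost_per_case_eur) | cost_per_case_eur == 0)) {
    pbrm_abort("zero or unknown cost per case; cases per unit undefined",
               class = "pbrm_undefined_comparison_error")
  }
  values <- budget_eur / cost_per_case_eur
  ci <- .t_ci(values)
  list(values = values, mean = round_half_up(mean(values), 1),
       ci_lo = if (is.na(ci[1])) NA_real_ else round_half_up(ci[1], 1),
       ci_hi = if (is.na(ci[2])) NA_real_ else round_half_up(ci[2], 1),
       n_centres = length(values))
}

#' Classical one-way ANOVA
#'
#' Between/within mean-square F with its p-value from the F distribution,
#' computed via `stats::lm()`. Degenerate inputs are handled explicitly: if
#' the between-group sum of squares is zero (all group means equal) the
#' statistic is F = 0, p = 1; a zero within-group sum of squares with
#' separated means gives F = Inf, p = 0.
#'
#' @param values numeric response.
#' @param groups group labels (at least 2 groups, total n > number of
#'   groups).
#' @return list with `f`, `p`, `df_between`, `df_within`.
#' @export
anova_one_way <- function(values, groups) {
  groups <- factor(groups)
  k <- nlevels(groups)
  n <- length(values)
  if (k < 2 || n <= k) {
    pbrm_abort("ANOVA needs at least 2 groups and more values than groups",
               class = "pbrm_analysis_error")
  }
  gm <- tapply(values, groups, mean)
  ssb <- sum(tabulate(groups) * (gm - mean(values))^2)
  ssw <- sum((values - gm[groups])^2)
  df1 <- k - 1
  df2 <- n - k
  if (ssb < 1e-12 * max(1, ssw)) {
    return(list(f = 0, p = 1, df_between = df1, df_within = df2))
  }
  if (ssw < 1e-12 * ssb) {
    return(list(f = Inf, p = 0, df_between = df1, df_within = df2))
  }
  a <- stats::anova(stats::lm(values ~ groups))
  list(f = a$`F value`[1], p = a$`Pr(>F)`[1], df_between = df1,
       df_within = df2)
}

#' Compare funding models per centre and cohort
#'
#' For every centre: funding under the performance-based model (capped and
#' uncapped reference), the fixed-rate model and (when specified) the
#' up-front allocation model, plus percent-of-reference ratios. Fixed-rate
#' ratios are per-case ratios (uncapped: fee over realised mean), up-front
#' ratios use the capped reference. Per cohort, the cases-per-budget-unit
#' statistic is computed per model with a one-way ANOVA across models.
#' Cross-sectoral non-academic centres have a separate financing structure
#' and are excluded unless `include_nonamc = TRUE`.
#'
#' @param centre_summaries tibble with at least `centre_id` (or
#'   `display_letter`), `cohort`, `centre_class`, `n_reimbursable`,
#'   `mean_per_case_eur`, `target_cases`.
#' @param frm a [frm_spec()].
#' @param ufam a [ufam_spec()] keyed by `centre_id`, or `NULL` to skip.
#' @param budget_eur budget unit for the efficiency statistic.
#' @param cap cap over-recruiters at their target number?
#' @param include_nonamc include cross-sectoral non-academic centres?
#' @return object of class `pbrm_comparison`: list with `centres`,
#'   `efficiency`, `anova` tibbles.
#' @export
compare_models <- function(centre_summaries, frm = frm_spec(), ufam = NULL,
                           budget_eur = 10000, cap = TRUE,
                           include_nonamc = FALSE) {
  cs <- tibble::as_tibble(centre_summaries)
  if (!"centre_id" %in% names(cs)) cs$centre_id <- cs$display_letter
  if (!include_nonamc) {
    cs <- cs[!(cs$cohort == "SUEP" & cs$centre_class == "non-AMC"), ]
  }
  cs <- cs[cs$n_reimbursable > 0, ]

  n_eff <- if (cap) pmin(cs$n_reimbursable, cs$target_cases) else
    cs$n_reimbursable
  cs$pbrm_funding_eur <- money(cs$mean_per_case_eur * cs$n_reimbursable)
  cs$pbrm_reference_eur <- money(cs$mean_per_case_eur * n_eff)
  cs$frm_funding_eur <- vapply(seq_len(nrow(cs)), function(i) {
    frm_funding(cs$n_reimbursable[i], cs$cohort[i], cs$centre_class[i], frm)
  }, numeric(1))
  cs$pct_frm_of_pbrm <- vapply(seq_len(nrow(cs)), function(i) {
    relative_to_pbrm(cs$frm_funding_eur[i], cs$mean_per_case_eur[i],
                     cs$n_reimbursable[i], cs$target_cases[i], cap = FALSE)
  }, numeric(1))

  if (!is.null(ufam)) {
    ufam <- ufam_spec(ufam)
    cs$ufam_funding_eur <- vapply(seq_len(nrow(cs)), function(i) {
      j <- match(cs$centre_id[i], ufam$centre_id)
      if (is.na(j)) {
        pbrm_abort(paste0("no UFAM specification for centre ",
                          cs$centre_id[i]), class = "pbrm_config_error")
      }
      ufam_funding(ufam[j, ], cs$target_cases[i])
    }, numeric(1))
    cs$pct_ufam_of_pbrm <- vapply(seq_len(nrow(cs)), function(i) {
      relative_to_pbrm(cs$ufam_funding_eur[i], cs$mean_per_case_eur[i],
                       cs$n_reimbursable[i], cs$target_cases[i], cap = cap)
    }, numeric(1))
  } else {
    cs$ufam_funding_eur <- NA_real_
    cs$pct_ufam_of_pbrm <- NA_real_
  }

  models <- c("PBRM", "FRM", if (!is.null(ufam)) "UFAM")
  eff_rows <- list()
  anova_rows <- list()
  for (coh in unique(cs$cohort)) {
    sub <- cs[cs$cohort == coh, ]
    cost <- list(
      PBRM = sub$mean_per_case_eur,
      FRM = vapply(seq_len(nrow(sub)), function(i) {
        .frm_fee(frm, sub$cohort[i], sub$centre_class[i])
      }, numeric(1)))
    if (!is.null(ufam)) {
      n_eff_sub <- if (cap) pmin(sub$n_reimbursable, sub$target_cases) else
        sub$n_reimbursable
      cost$UFAM <- sub$ufam_funding_eur / n_eff_sub
    }
    vals <- list()
    for (m in models) {
      cpu <- cases_per_budget_unit(cost[[m]], budget_eur)
      vals[[m]] <- cpu$values
      eff_rows[[paste(coh, m)]] <- tibble::tibble(
        cohort = coh, model = m, n_centres = cpu$n_centres,
        cases_per_unit = cpu$mean, ci_lo = cpu$ci_lo, ci_hi = cpu$ci_hi)
    }
    if (nrow(sub) >= 2) {
      a <- anova_one_way(unlist(vals), rep(names(vals), lengths(vals)))
      anova_rows[[coh]] <- tibble::tibble(cohort = coh, f = a$f, p = a$p)
    }
  }

  structure(list(centres = cs, efficiency = dplyr::bind_rows(eff_rows),
                 anova = dplyr::bind_rows(anova_rows)),
            class = "pbrm_comparison")
}

#' @export
print.pbrm_comparison <- function(x, ...) {
  cat(sprintf("<pbrm_comparison> %d centres, %d cohort(s)\n",
              nrow(x$centres), length(unique(x$centres$cohort))))
  print(x$efficiency)
  invisible(x)
}

#' Published first-funding-period centre outcomes
#'
#' Reimbursed case counts, mean reimbursement per case, recruitment targets
#' and (where published) the up-front per-case allocation for the NAPKON
#' centres whose first-funding-period outcomes were reported. Useful as
#' input to [compare_models()] when reproducing the published model
#' comparison; the underlying case-level study data are not public.
#'
#' @return tibble.
#' @export
published_centre_outcomes <- function() {
  readr::read_csv(system.file("extdata", "napkon", "centre_outcomes.csv",
                              package = "pbrm", mustWork = TRUE),
                  show_col_types = FALSE,
                  col_types = readr::cols(
                    cohort = "c", centre_class = "c", display_letter = "c",
                    n_reimbursable = "i", mean_per_case_eur = "d",
                    target_cases = "d", ufam_per_case_eur = "d"))
}
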