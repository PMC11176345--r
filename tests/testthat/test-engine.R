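mk_lines <- function(item_id, count = 1, case_id = "CASE-1",
                     source = "ecrf") {
  tibble::tibble(case_id = case_id, visit_id = "V1", visit_type_id = "t",
                 item_id = item_id, count = as.integer(count),
                 source = source)
}

test_that("case statements price lines from the catalogue and sum exactly", {
  st <- compute_case_statements(
    mk_lines(c("doc-ward", "doc-icu", "ecg")), CAT)
  expect_equal(money_sum(st$amount_eur), 206.67)
  expect_equal(st$amount_eur, c(66.00, 123.00, 17.67))

  empty <- compute_case_statements(mk_lines(character(0), integer(0)), CAT)
  expect_equal(nrow(empty), 0L)
  expect_equal(money_sum(empty$amount_eur), 0)

  expect_error(compute_case_statements(mk_lines("ghost"), CAT),
               class = "pbrm_lookup_error")
})

test_that("200 random lines equal a per-line multiply-and-sum oracle", {
  withr::with_seed(99, {
    ids <- CAT$items$item_id
    lines <- tibble::tibble(
      case_id = sample(paste0("CASE-", 1:20), 200, TRUE),
      visit_id = paste0("V", 1:200), visit_type_id = "t",
      item_id = sample(ids, 200, TRUE),
      count = sample(1:4, 200, TRUE),
      source = sample(c("ecrf", "bio", "imaging"), 200, TRUE))
  })
  st <- compute_case_statements(lines, CAT)
  costs <- oracle_item_costs()
  oracle_cents <- sum(vapply(seq_len(nrow(lines)), function(i) {
    lines$count[i] * round(costs[[lines$item_id[i]]] * 100)
  }, numeric(1)))
  expect_equal(money_sum(st$amount_eur), oracle_cents / 100)
  # per-case conservation against the same oracle
  ct <- case_totals(st)
  expect_equal(money_sum(ct$total_eur), oracle_cents / 100)
})

test_that("imputation values pending visits from experience means", {
  hist_lines <- tibble::tibble(
    case_id = paste0("CASE-", 1:3), visit_id = paste0("V", 1:3),
    visit_type_id = "fu-3mo", item_id = "x", count = 1L, source = "ecrf",
    unit_cost_eur = c(100, 120, 140), amount_eur = c(100, 120, 140),
    imputed = FALSE, provenance = NA_character_,
    centre_id = "C01", cohort = "HAP", centre_class = "AMC")
  spec <- list(freeze_date = as.Date("2021-06-01"),
               announced = tibble::tibble(case_id = "CASE-9",
                                          visit_type_id = "fu-3mo",
                                          due_date = as.Date("2021-08-01")))
  # the announced case belongs to the same centre
  hist2 <- dplyr::bind_rows(hist_lines, tibble::tibble(
    case_id = "CASE-9", visit_id = "V9", visit_type_id = "baseline",
    item_id = "x", count = 1L, source = "ecrf", unit_cost_eur = 10,
    amount_eur = 10, imputed = FALSE, provenance = NA_character_,
    centre_id = "C01", cohort = "HAP", centre_class = "AMC"))
  out <- impute_future_visits(hist2, spec)
  imp <- out[out$imputed, ]
  expect_equal(nrow(imp), 1L)
  expect_equal(imp$amount_eur, 120.00) # arithmetic mean of 100, 120, 140
  expect_equal(imp$provenance, "centre")
  # original lines untouched
  expect_equal(out[!out$imputed, names(hist2)], hist2, ignore_attr = TRUE)

  # fallback: centre without history inherits the cohort mean
  hist3 <- hist2
  hist3$centre_id[hist3$case_id == "CASE-9"] <- "C02"
  out3 <- impute_future_visits(hist3, spec)
  expect_equal(out3$provenance[out3$imputed], "cohort")

  # configured default as last resort, otherwise a configuration error
  spec4 <- list(freeze_date = spec$freeze_date,
                announced = tibble::tibble(case_id = "CASE-9",
                                           visit_type_id = "fu-12mo",
                                           due_date = as.Date("2021-08-01")),
                defaults = c("fu-12mo" = 90))
  out4 <- impute_future_visits(hist2, spec4)
  expect_equal(out4$amount_eur[out4$imputed], 90.00)
  expect_equal(out4$provenance[out4$imputed], "configured")
  spec4$defaults <- NULL
  expect_error(impute_future_visits(hist2, spec4),
               class = "pbrm_config_error")

  # nothing announced: statement unchanged
  expect_identical(impute_future_visits(
    hist2, list(freeze_date = spec$freeze_date,
                announced = spec$announced[0, ])), hist2)
})

test_that("centre aggregation grants the initiation fee only from 5 cases", {
  mk_run <- function(n_cases) {
    cfg <- noise_free_config(seed = 5, cases = n_cases, cohort = "SUEP")
    cfg$centre_class <- "non-AMC"
    b <- simulate_cohort(cfg)
    run_pbrm(b, initiation_fee_eur = 5000)
  }
  r4 <- mk_run(4)
  expect_equal(r4$centre_summaries$initiation_fee_eur, 0)
  r5 <- mk_run(5)
  expect_equal(r5$centre_summaries$initiation_fee_eur, 5000)
  expect_equal(r5$centre_summaries$funding_eur,
               money_sum(c(r5$centre_summaries$total_eur, 5000)))
})

test_that("identical statements aggregate to their common mean and shares", {
  lines <- dplyr::bind_rows(lapply(1:10, function(i) {
    tibble::tibble(case_id = paste0("CASE-", i), visit_id = "V1",
                   visit_type_id = "t",
                   item_id = c("doc-ward", "pbmc"), count = 1L,
                   source = c("ecrf", "bio"))
  }))
  st <- compute_case_statements(lines, CAT)
  ct <- case_totals(st)
  expect_equal(unique(ct$total_eur), 66.00 + 70.97)
  expect_equal(money_sum(ct$total_eur), 10 * 136.97)
})

test_that("aggregation conserves totals from lines to centres to cohorts", {
  b <- simulate_cohort(sim_config(seed = 23, cohort = "HAP", n_centres = 3,
                                  cases_per_centre = c(6, 4, 2)))
  run <- run_pbrm(b)
  lines_total <- money_sum(run$statements$amount_eur)
  case_total <- money_sum(run$case_totals$total_eur)
  centre_total <- money_sum(run$centre_summaries$total_eur)
  cohort_total <- money_sum(run$cohort_summaries$total_eur)
  expect_identical(case_total, lines_total)
  expect_identical(centre_total, lines_total)
  expect_identical(cohort_total, lines_total)
  # flat re-summation oracle over raw line amounts
  expect_identical(centre_total, sum(round(run$statements$amount_eur *
                                             100)) / 100)
  # source shares sum to 100 within rounding where a total exists
  cs <- run$centre_summaries
  sums <- cs$share_ecrf_pct + cs$share_bio_pct + cs$share_imaging_pct
  expect_true(all(abs(sums[cs$total_eur > 0] - 100) <= 0.2))
})

test_that("follow-up fulfilment is the documented share of expected visits", {
  # 5 cases, 2 expected FU each; construct 7 documented FU visits -> 70.0
  exp <- list()
  ecrf <- dplyr::bind_rows(lapply(1:5, function(i) {
    fu <- list(c("fu-3mo", "fu-12mo"), c("fu-3mo", "fu-12mo"),
               c("fu-3mo", "fu-12mo"), "fu-3mo", character(0))[[i]]
    dplyr::bind_rows(
      tibble::tibble(ecrf_pseudonym = paste0("E-", i), centre_id = "C01",
                     visit_id = paste0(i, "-V1"), visit_type_id = "baseline",
                     visit_date = as.Date("2021-01-01"),
                     form_id = "baseline", item_id = "crf-ecg", value = "v",
                     submitted = TRUE, plausibility_pass = TRUE,
                     case_review_pass = TRUE, consent_registered = TRUE),
      if (length(fu)) tibble::tibble(
        ecrf_pseudonym = paste0("E-", i), centre_id = "C01",
        visit_id = paste0(i, "-V", 1 + seq_along(fu)), visit_type_id = fu,
        visit_date = as.Date("2021-04-01"), form_id = fu,
        item_id = "crf-doc-clinical-status", value = "v", submitted = TRUE,
        plausibility_pass = TRUE, case_review_pass = TRUE,
        consent_registered = TRUE))
  }))
  linkage <- tibble::tibble(case_id = paste0("CASE-", 1:5),
                            ecrf_pseudonym = paste0("E-", 1:5),
                            bio_pseudonym = NA_character_,
                            img_pseudonym = NA_character_)
  centres <- tibble::tibble(centre_id = "C01", display_letter = "A",
                            cohort = "HAP", centre_class = "AMC",
                            target_cases = 73.5)
  dos <- link_cases(linkage, ecrf, centres = centres)
  expect_equal(fu_fulfilment(dos, c("fu-3mo", "fu-12mo")), 70.0)
  expect_equal(fu_fulfilment(dos, character()), NA_real_)
  # all documented -> 100.0
  dos2 <- link_cases(linkage[1:3, ], ecrf, centres = centres)
  expect_equal(fu_fulfilment(dos2, c("fu-3mo", "fu-12mo")), 100.0)
})

test_that("reports are audience-scoped and regenerate byte-identically", {
  b <- simulate_cohort(sim_config(seed = 31, cohort = "SUEP",
                                  n_centres = 2, cases_per_centre = c(4, 3)))
  run <- run_pbrm(b)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  generate_reports(run, "coordination", out_dir = d1)
  generate_reports(run, "coordination", out_dir = d2)
  for (f in list.files(d1)) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))), label = f)
  }
  generate_reports(run, "centre", centre_id = "C01", out_dir = d3)
  st_scoped <- readr::read_csv(file.path(d3, "statements.csv"),
                               show_col_types = FALSE)
  c2_cases <- run$dossiers$cases$case_id[
    run$dossiers$cases$centre_id == "C02"]
  expect_false(any(st_scoped$case_id %in% c2_cases))
  # the coordination statement partitions into the per-centre statements
  st_all <- readr::read_csv(file.path(d1, "statements.csv"),
                            show_col_types = FALSE)
  d4 <- withr::local_tempdir()
  generate_reports(run, "centre", centre_id = "C02", out_dir = d4)
  st_c2 <- readr::read_csv(file.path(d4, "statements.csv"),
                           show_col_types = FALSE)
  expect_equal(nrow(st_scoped) + nrow(st_c2), nrow(st_all))
  expect_error(generate_reports(run, "centre", centre_id = "C99",
                                out_dir = d3),
               class = "pbrm_lookup_error")
})

test_that("the run ledger is content-addressed and iteration-aware", {
  inputs <- list(a = tiny_exports()$ecrf, b = RULES)
  l1 <- build_run_ledger(inputs, timestamp = "t1")
  l2 <- build_run_ledger(inputs, timestamp = "t2")
  expect_identical(l1$run_id, l2$run_id) # timestamp is not part of identity
  l3 <- build_run_ledger(inputs, iteration = 2L)
  expect_false(identical(l1$run_id, l3$run_id))
  inputs$a$value[1] <- "changed"
  expect_false(identical(build_run_ledger(inputs)$run_id, l1$run_id))
})

test_that("audit sampling is seeded, uniform, and bounded", {
  st <- tibble::tibble(case_id = rep(sprintf("CASE-%02d", 1:20), each = 2),
                       amount_eur = 1)
  all20 <- random_audit_sample(st, n = 20, seed = 1)
  expect_setequal(attr(all20, "case_ids"), unique(st$case_id))
  s1 <- random_audit_sample(st, n = 5, seed = 42)
  s2 <- random_audit_sample(st, n = 5, seed = 42)
  expect_identical(attr(s1, "case_ids"), attr(s2, "case_ids"))
  expect_error(random_audit_sample(st, n = 21, seed = 1),
               class = "pbrm_sampling_error")
  # inclusion frequency over 10,000 resamples of 5-from-20 is ~ 0.25
  counts <- integer(20)
  names(counts) <- sprintf("CASE-%02d", 1:20)
  for (s in 1:10000) {
    ids <- attr(random_audit_sample(st, n = 5, seed = s), "case_ids")
    counts[ids] <- counts[ids] + 1L
  }
  phat <- counts / 10000
  # 5 sd of a binomial(10000, 0.25) proportion is ~0.022
  expect_true(all(abs(phat - 0.25) < 0.025))
})
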