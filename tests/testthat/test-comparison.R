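test_that("fixed-rate funding is the case fee times reimbursed cases", {
  expect_equal(frm_funding(0, "HAP"), 0.00)
  expect_equal(frm_funding(4, "HAP"), 51486.80)
  withr::with_seed(8, {
    for (rep in 1:10) {
      n <- sample(0:200, 1)
      fee <- money(runif(1, 100, 5000))
      spec <- frm_spec(data.frame(cohort = "POP", centre_class = "AMC",
                                  case_fee_eur = fee))
      # enumeration oracle: add the fee once per case
      oracle <- 0
      for (k in seq_len(n)) oracle <- oracle + round(fee * 100)
      expect_equal(frm_funding(n, "POP", "AMC", spec), oracle / 100)
    }
  })
  expect_error(frm_funding(1, "HAP", "non-AMC"),
               class = "pbrm_config_error")
})

test_that("up-front funding composes quarter-rounded staffing and consumables", {
  row <- tibble::tibble(centre_id = "C01", physician_fte = 0.6,
                        nurse_fte = 0.875, fte_cost_physician_eur = 120000,
                        fte_cost_nurse_eur = 60000,
                        consumables_per_case_eur = 50)
  # 0.6 -> 0.5, 0.875 -> 1.0 (tie away from zero)
  expect_equal(ufam_funding(row, target_cases = 73.5),
               money_sum(c(0.5 * 120000, 1.0 * 60000, 50 * 73.5)))
  lump <- tibble::tibble(centre_id = "C01", total_eur = 961281.96)
  expect_equal(ufam_funding(lump, target_cases = 73.5), 961281.96)
  expect_error(ufam_spec(tibble::tibble(centre_id = "C01",
                                        physician_fte = -1)),
               class = "pbrm_validation_error")
})

test_that("equal-share up-front allocation funds all centres identically", {
  spec <- ufam_spec(tibble::tibble(
    centre_id = sprintf("C%02d", 1:5), physician_fte = 0.5,
    nurse_fte = 1, fte_cost_physician_eur = 120000,
    fte_cost_nurse_eur = 60000, consumables_per_case_eur = 80))
  funding <- vapply(1:5, function(i) ufam_funding(spec[i, ], 73.5),
                    numeric(1))
  expect_equal(length(unique(funding)), 1L)
})

test_that("percent-of-reference reproduces the published centre ratios", {
  # fixed-rate ratios are per-case (uncapped)
  expect_equal(relative_to_pbrm(frm_funding(164, "HAP"), 6797.53, 164,
                                73.5, cap = FALSE), 189.4)
  expect_equal(relative_to_pbrm(frm_funding(4, "HAP"), 1901.91, 4, 73.5,
                                cap = FALSE), 676.8)
  expect_equal(relative_to_pbrm(frm_funding(86, "SUEP", "AMC"), 3479.29,
                                86, 98.1, cap = FALSE), 83.5)
  expect_equal(relative_to_pbrm(frm_funding(1663, "POP", "AMC"), 2658.20,
                                1663, 660, cap = FALSE), 127.9)
  # up-front comparison caps over-recruiters at target
  ufam_total <- money(240320.49 * 4)
  expect_equal(relative_to_pbrm(ufam_total, 6797.53, 164, 73.5,
                                cap = TRUE), 192.4)
  expect_equal(relative_to_pbrm(ufam_total, 3876.32, 102, 73.5,
                                cap = TRUE), 337.4)
  expect_equal(relative_to_pbrm(100, 100, 1, cap = FALSE), 100.0)
  expect_error(relative_to_pbrm(100, 0, 5, cap = FALSE),
               class = "pbrm_undefined_comparison_error")
})

test_that("capping never increases the reference and is inert below target", {
  withr::with_seed(12, {
    for (rep in 1:20) {
      mean_pc <- money(runif(1, 500, 8000))
      n <- sample(1:200, 1)
      target <- runif(1, 1, 150)
      funding <- money(runif(1, 1e4, 1e6))
      capped <- relative_to_pbrm(funding, mean_pc, n, target, cap = TRUE)
      uncapped <- relative_to_pbrm(funding, mean_pc, n, target,
                                   cap = FALSE)
      expect_gte(capped, uncapped) # smaller reference -> larger percentage
      if (n <= target) expect_equal(capped, uncapped)
    }
  })
})

test_that("fixed-rate percent of reference is independent of case count", {
  p1 <- relative_to_pbrm(frm_funding(10, "HAP"), 4000, 10, cap = FALSE)
  p2 <- relative_to_pbrm(frm_funding(150, "HAP"), 4000, 150, cap = FALSE)
  expect_equal(p1, p2)
  expect_equal(p1, round_half_up(100 * 12871.70 / 4000, 1))
})

test_that("a 10,000 budget buys the published case numbers under fixed rates", {
  cpu <- cases_per_budget_unit(rep(12871.70, 10))
  expect_equal(cpu$mean, 0.8)
  expect_equal(cpu$ci_lo, 0.8) # zero variance -> zero-width interval
  expect_equal(cpu$ci_hi, 0.8)
  expect_equal(cases_per_budget_unit(rep(3400.76, 3))$mean, 2.9)
  expect_equal(cases_per_budget_unit(rep(2904.67, 20))$mean, 3.4)
  single <- cases_per_budget_unit(2904.67)
  expect_true(is.na(single$ci_lo) && is.na(single$ci_hi))
  expect_error(cases_per_budget_unit(c(100, 0)),
               class = "pbrm_undefined_comparison_error")
})

test_that("one-way ANOVA matches its t-test equivalence and degenerate forms", {
  a <- anova_one_way(rep(5, 9), rep(c("x", "y", "z"), 3))
  expect_equal(a$f, 0)
  expect_equal(a$p, 1)

  withr::with_seed(77, {
    for (rep in 1:5) {
      x <- rnorm(12); y <- rnorm(15, mean = 1)
      a2 <- anova_one_way(c(x, y), rep(c("a", "b"), c(12, 15)))
      tt <- stats::t.test(x, y, var.equal = TRUE)
      expect_equal(a2$f, unname(tt$statistic)^2, tolerance = 1e-12)
      expect_equal(a2$p, tt$p.value, tolerance = 1e-12)
    }
  })

  # three strongly separated groups: p below 0.001
  withr::with_seed(5, {
    g <- rep(c("PBRM", "FRM", "UFAM"), each = 20)
    v <- c(rnorm(20, 3, .3), rnorm(20, .8, .1), rnorm(20, .3, .1))
  })
  expect_lt(anova_one_way(v, g)$p, 0.001)
  expect_error(anova_one_way(1:3, c("a", "a", "a")),
               class = "pbrm_analysis_error")
})

test_that("model comparison assembles centre ratios and efficiency per cohort", {
  outcomes <- published_centre_outcomes()
  hap <- outcomes[outcomes$cohort == "HAP", ]
  ufam_total <- money(hap$ufam_per_case_eur[hap$display_letter == "J"] *
                        hap$n_reimbursable[hap$display_letter == "J"])
  cmp <- compare_models(
    hap, ufam = tibble::tibble(centre_id = hap$display_letter,
                               total_eur = ufam_total))
  cc <- cmp$centres
  expect_equal(cc$pct_frm_of_pbrm[cc$display_letter == "A"], 189.4)
  expect_equal(cc$pct_frm_of_pbrm[cc$display_letter == "J"], 676.8)
  expect_equal(cc$pct_ufam_of_pbrm[cc$display_letter == "A"], 192.4)
  expect_equal(cc$pct_ufam_of_pbrm[cc$display_letter == "D"], 337.4)
  eff <- cmp$efficiency
  expect_equal(eff$cases_per_unit[eff$model == "FRM"], 0.8)
  expect_true(all(c("PBRM", "FRM", "UFAM") %in% eff$model))
  expect_equal(nrow(cmp$anova), 1L)

  # cross-sectoral non-academic centres are excluded by default
  mixed <- dplyr::bind_rows(hap, tibble::tibble(
    cohort = "SUEP", centre_class = "non-AMC", display_letter = "Z",
    n_reimbursable = 5L, mean_per_case_eur = 900, target_cases = 30,
    ufam_per_case_eur = NA_real_))
  cmp2 <- compare_models(mixed)
  expect_false("Z" %in% cmp2$centres$display_letter)
})
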