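test_that("packaged catalogue reproduces the self-consistent costing rows", {
  totals <- item_total_cost(CAT)
  expect_equal(unname(totals["doc-ward"]), 66.00)
  expect_equal(unname(totals["doc-icu"]), 123.00)
  expect_equal(unname(totals["doc-clinical-status"]), 5.50)
  expect_equal(unname(totals["ecg"]), 17.67)
  expect_equal(unname(totals["pbmc"]), 70.97)
  expect_equal(unname(totals["spirometry"]), 203.80)
})

test_that("inconsistent printed totals are flagged, not silently resolved", {
  cons <- catalogue_consistency(CAT)
  # components of these two rows disagree with their printed totals by 1 cent+
  expect_false(cons$consistent[cons$item_id == "doc-screening-baseline"])
  expect_false(cons$consistent[cons$item_id == "echo"])
  expect_equal(cons$computed_total_eur[cons$item_id == "doc-screening-baseline"],
               116.00)
  expect_equal(cons$computed_total_eur[cons$item_id == "echo"], 83.53)
  expect_true(all(cons$consistent[!cons$item_id %in%
                                    c("doc-screening-baseline", "echo")]))
})

test_that("rate-derived pricing: spirometry from role minutes alone", {
  cat2 <- cost_catalogue(
    items = data.frame(item_id = "spiro", label = "spirometry",
                       material_cost_eur = 70),
    efforts = data.frame(item_id = rep("spiro", 3),
                         role = c("SP", "PH", "MS"),
                         minutes = c(90, 60, 30)),
    rates = data.frame(role = c("SP", "PH", "MS"),
                       rate_eur_per_min = c(0.5498, 0.8027, 1.2053)))
  expect_equal(unname(item_total_cost(cat2, "spiro")), 203.80)
})

test_that("an item with no efforts and no material costs nothing", {
  cat2 <- cost_catalogue(items = data.frame(item_id = "empty", label = "x"))
  expect_equal(unname(item_total_cost(cat2, "empty")), 0.00)
})

test_that("random items with explicit costs match a hand-summation oracle", {
  withr::with_seed(42, {
    for (rep in 1:25) {
      n_eff <- sample(0:3, 1)
      material <- round(runif(1, 0, 50), 2)
      overhead <- sample(c(0, 0.1, 0.25), 1)
      costs <- round(runif(n_eff, 0, 120), 2)
      cat2 <- cost_catalogue(
        items = data.frame(item_id = "it", label = "x",
                           material_cost_eur = material,
                           overhead_rate = overhead),
        efforts = if (n_eff) data.frame(
          item_id = "it", role = c("SP", "PH", "MS")[seq_len(n_eff)],
          minutes = rep(1, n_eff), explicit_cost_eur = costs) else NULL)
      # independent oracle: plain component sum, then overhead, half-up
      expected <- (sum(round(costs * 100)) + round(material * 100)) / 100
      expected <- floor(expected * (1 + overhead) * 100 + 0.5 + 1e-9) / 100
      expect_equal(unname(item_total_cost(cat2, "it")), expected)
    }
  })
})

test_that("a role effort without cost or rate raises an unresolved-rate error", {
  cat2 <- cost_catalogue(
    items = data.frame(item_id = "it", label = "x"),
    efforts = data.frame(item_id = "it", role = "MS", minutes = 10))
  expect_error(item_total_cost(cat2, "it"),
               class = "pbrm_unresolved_rate_error")
  expect_match(tryCatch(item_total_cost(cat2, "it"),
                        error = conditionMessage), "MS")
})

test_that("visit cost sums item costs with multiplicities", {
  expect_equal(visit_cost(CAT, items = data.frame(
    item_id = c("ecg", "doc-clinical-status"), count = c(1, 1))), 23.17)
  expect_equal(visit_cost(CAT, items = data.frame(
    item_id = character(), count = integer())), 0.00)
  expect_equal(visit_cost(CAT, items = data.frame(
    item_id = "doc-icu", count = 2)), 246.00)
  expect_error(visit_cost(CAT, items = data.frame(item_id = "nope",
                                                  count = 1)),
               class = "pbrm_lookup_error")
})

test_that("visit cost is additive over concatenated item lists", {
  withr::with_seed(7, {
    ids <- CAT$items$item_id
    for (rep in 1:10) {
      a <- data.frame(item_id = sample(ids, 3), count = sample(1:3, 3,
                                                               TRUE))
      b <- data.frame(item_id = sample(ids, 2), count = sample(1:3, 2,
                                                               TRUE))
      expect_equal(visit_cost(CAT, items = rbind(a, b)),
                   money_sum(c(visit_cost(CAT, items = a),
                               visit_cost(CAT, items = b))))
    }
  })
})

test_that("item cost is monotone in minutes, rates, material and overhead", {
  base_args <- function(minutes = 50, rate = 0.6, material = 10,
                        overhead = 0.1) {
    cost_catalogue(
      items = data.frame(item_id = "it", label = "x",
                         material_cost_eur = material,
                         overhead_rate = overhead),
      efforts = data.frame(item_id = "it", role = "SP", minutes = minutes),
      rates = data.frame(role = "SP", rate_eur_per_min = rate))
  }
  ref <- unname(item_total_cost(base_args(), "it"))
  expect_gte(unname(item_total_cost(base_args(minutes = 80), "it")), ref)
  expect_gte(unname(item_total_cost(base_args(rate = 0.9), "it")), ref)
  expect_gte(unname(item_total_cost(base_args(material = 30), "it")), ref)
  expect_gte(unname(item_total_cost(base_args(overhead = 0.3), "it")), ref)
})

test_that("configured case fees take precedence and match the negotiated values", {
  expect_equal(expected_case_fee(CAT, "HAP", "AMC"), 12871.70)
  expect_equal(expected_case_fee(CAT, "POP", "AMC"), 3400.76)
  expect_equal(expected_case_fee(CAT, "SUEP", "AMC"), 2904.67)
  expect_equal(expected_case_fee(CAT, "SUEP", "non-AMC"), 1071.23)
})

test_that("path-distribution case fee is an expectation within path bounds", {
  p1 <- c("baseline", "ward-day", "discharge")
  p2 <- c("baseline", "ward-day", "ward-day", "icu-day", "discharge")
  cost <- function(p) money_sum(vapply(p, function(v) {
    visit_cost(CAT, v, cohort = "HAP", centre_class = "AMC")
  }, numeric(1)))
  # degenerate distribution: the fee is that path's cost
  fee1 <- expected_case_fee(CAT, "HAP", "AMC", use_configured = FALSE,
                            paths = tibble::tibble(probability = 1,
                                                   visits = list(p1)))
  expect_equal(fee1, cost(p1))
  # two equiprobable paths: the arithmetic mean (brute-force enumeration)
  fee2 <- expected_case_fee(CAT, "HAP", "AMC", use_configured = FALSE,
                            paths = tibble::tibble(probability = c(.5, .5),
                                                   visits = list(p1, p2)))
  expect_equal(fee2, money((cost(p1) + cost(p2)) / 2))
  expect_gte(fee2, min(cost(p1), cost(p2)))
  expect_lte(fee2, max(cost(p1), cost(p2)))
  expect_error(expected_case_fee(CAT, "HAP", "AMC", use_configured = FALSE),
               class = "pbrm_spec_error")
})

test_that("catalogue round-trips through CSV directory and JSON identically", {
  d <- withr::local_tempdir()
  write_catalogue(CAT, file.path(d, "cat"))
  expect_equal(read_catalogue(file.path(d, "cat")), CAT)
  write_catalogue(CAT, file.path(d, "cat.json"))
  expect_equal(read_catalogue(file.path(d, "cat.json")), CAT)
  # a randomly perturbed catalogue also round-trips
  cat2 <- CAT
  cat2$items$material_cost_eur <- money(runif(nrow(cat2$items), 0, 9))
  write_catalogue(cat2, file.path(d, "cat2"))
  expect_equal(read_catalogue(file.path(d, "cat2")), cat2)
})

test_that("the packaged fixture holds exactly the eight exemplary items", {
  expect_equal(nrow(CAT$items), 8L)
  expect_setequal(CAT$rates$role, c("SP", "PH", "MS"))
})

test_that("catalogue validation lists offending rows", {
  expect_error(cost_catalogue(
    items = data.frame(item_id = c("a", "a"), label = "x")),
    class = "pbrm_validation_error")
  expect_error(cost_catalogue(
    items = data.frame(item_id = "a", label = "x",
                       material_cost_eur = -1)),
    class = "pbrm_validation_error")
  expect_error(cost_catalogue(
    items = data.frame(item_id = "a", label = "x"),
    efforts = data.frame(item_id = "a", role = "SP", minutes = -5)),
    class = "pbrm_validation_error")
})
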