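# Independent brute-force oracles, written in plain base R against the
# documented rules, never through the package's engine functions.

# item costs re-derived from the packaged catalogue CSV by hand-summing the
# printed components (explicit cost per role effort + material)
oracle_item_costs <- function() {
  f <- system.file("extdata", "catalogue", "items.csv", package = "pbrm")
  d <- utils::read.csv(f, stringsAsFactors = FALSE)
  costs <- c()
  for (id in unique(d$item_id)) {
    rows <- d[d$item_id == id, ]
    cents <- sum(round(rows$explicit_cost_eur * 100)) +
      round(rows$material_cost_eur[1] * 100)
    costs[id] <- cents / 100
  }
  costs
}

# single-pass brute force over the raw export records of a bundle: applies
# the documented minimum criteria and quality gates record by record and
# multiplies/sums eligible fees with plain arithmetic
oracle_case_totals <- function(bundle, costs = oracle_item_costs(),
                               min_aliquots = 2) {
  ecrf <- as.data.frame(bundle$ecrf)
  bio <- as.data.frame(bundle$biosamples)
  img <- as.data.frame(bundle$imaging)
  link <- as.data.frame(bundle$linkage)
  cohort <- bundle$centres$cohort[1]
  required <- if (cohort == "POP") c("initial-interview", "on-site") else
    c("baseline", "discharge")

  totals <- numeric(0)
  reimb <- logical(0)
  for (i in seq_len(nrow(link))) {
    e <- ecrf[ecrf$ecrf_pseudonym == link$ecrf_pseudonym[i], ]
    ok <- nrow(e) > 0 && all(e$consent_registered)
    for (f in required) {
      ef <- e[e$form_id == f, ]
      ok <- ok && nrow(ef) > 0 && all(ef$submitted)
    }
    if (cohort == "SUEP") ok <- ok && all(e$case_review_pass)
    cents <- 0
    if (ok) {
      for (j in seq_len(nrow(e))) {
        if (e$submitted[j] && e$plausibility_pass[j]) {
          item <- sub("^crf-", "", e$item_id[j])
          cents <- cents + round(costs[[item]] * 100)
        }
      }
      b <- bio[!is.na(link$bio_pseudonym[i]) &
                 bio$bio_pseudonym == link$bio_pseudonym[i], ]
      for (j in seq_len(nrow(b))) {
        if (b$registered[j] && b$sample_type[j] == "pbmc" &&
            b$aliquot_count[j] >= min_aliquots) {
          cents <- cents + round(costs[["pbmc"]] * 100)
        }
      }
      m <- img[!is.na(link$img_pseudonym[i]) &
                 img$img_pseudonym == link$img_pseudonym[i], ]
      for (j in seq_len(nrow(m))) {
        if (m$uploaded[j] && m$modality[j] == "echo" &&
            m$series_count[j] >= 1) {
          cents <- cents + round(costs[["echo"]] * 100)
        }
      }
    }
    totals[link$case_id[i]] <- cents / 100
    reimb[link$case_id[i]] <- ok
  }
  data.frame(case_id = names(totals), reimbursable = unname(reimb),
             total_eur = unname(totals), stringsAsFactors = FALSE)
}
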