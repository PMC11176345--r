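---
title: "Performance-based reimbursement: model, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Performance-based reimbursement: model, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pbrm)
```

## The problem

When many hospitals jointly run a prospective cohort — as the German
national COVID-19 cohort platforms did, with a deep-phenotyping inpatient
cohort (HAP), a population-based cohort with a single on-site visit (POP)
and a cross-sectoral cohort spanning academic (AMC) and non-academic
(non-AMC) centres — funding has to be divided among centres whose
recruitment can differ by two orders of magnitude and whose per-case
effort depends on disease severity, length of stay and follow-up
compliance. Fixed case fees and up-front staffing budgets both assume away
this heterogeneity. The performance-based reimbursement model (PBRM)
instead reconstructs, from the study's own data-management systems, which
protocol activities each centre actually performed and to which quality,
and pays a catalogue lump sum for each.

## The costing model

A *reimbursement item* is a lump sum for one study activity. Its total is

$$c = \Big(\sum_{r \in \{SP, PH, MS\}} \mathrm{round}_2(m_r \rho_r) + M\Big)(1 + o)$$

where $m_r$ are the estimated minutes of study personnel, physician and
medical specialist time, $\rho_r$ the €/min tariff rates, $M$ material
costs and $o$ an overhead fraction (0 by default; the packaged catalogue's
totals are plain sums). Components are rounded to whole cents *before*
summation, which is what makes the packaged totals reproduce exactly.

The packaged catalogue stores, for each of its eight exemplary items, the
explicit per-role component costs alongside the minutes and the tariff
rates (SP 0.5498, PH 0.8027, MS 1.2053 €/min). Explicit component costs
take precedence over rate derivation: the published costing table is not
globally rate-consistent for the specialist role (the ECG and
echocardiogram rows imply ≈1.117 €/min, spirometry 1.2053 €/min), so
storing the printed components is the only representation that reproduces
every row without inventing a reconciliation. Two rows are internally
inconsistent at the cent level (screening/baseline documentation:
components sum to 116.00 € against a printed 115.00 €; echocardiogram
83.53 vs 83.52). The catalogue keeps both values and
`catalogue_consistency()` flags the disagreement; computation always uses
the components:

```{r}
catalogue_consistency(default_catalogue())
```

Visit types are multisets of items per cohort and centre class; a visit
costs the multiplicity-weighted sum of its item totals. The *case fee* —
the expected mean reimbursement per case, severity- and
loss-to-follow-up-adjusted — is either a configured constant (the
negotiated values: HAP 12,871.70 €, POP 3,400.76 €, SUEP AMC 2,904.67 €,
SUEP non-AMC 1,071.23 €) or the expectation over a distribution of visit
paths. The configured constant always wins when present.

### Monetary arithmetic

All amounts pass through half-up rounding to 2 decimals at creation and
all sums accumulate integer cents, so totals are bit-stable and conserve
exactly from line to case to centre to cohort (doubles only ever hold
exact multiples of 0.01, which are exactly representable sums below
2^53 cents). Percentages are reported half-up to 1 decimal, matching
every published ratio we reproduce. Base R's banker's rounding is never
used for money.

## From exports to statements

Three pseudonymised system exports (eCRF clinical documentation,
biosampling registry, imaging upload metadata) are linked into
reimbursement cases through a trusted-third-party style pseudonym table;
the documented schemas ship in `inst/extdata/data_dictionary.md`. The
eCRF is the anchor system: a case with no eCRF records cannot satisfy the
minimum criteria, so it is never a dossier, and biosampling/imaging
records that cannot be linked are reported as orphans rather than failing
the run — partial uploads are a normal condition of multi-centre
operations, not an error.

A case is *recruited* when informed consent is registered and
*reimbursable* only when, additionally, all pages of the baseline and
discharge forms (POP: initial interview and on-site visit) were submitted
and — for the cross-sectoral cohort — every sub-form passed its local
case review. Verdicts are data with coded reasons, not exceptions. A
non-reimbursable case yields zero billable lines entirely; partial payment
of ineligible cases is deliberately not modelled, since the minimum
criteria are defined at case level.

Record-level gates then filter the surviving cases' records: eCRF items
must be submitted and pass the automated plausibility checks; biosamples
must be registered, of a ruled sample type, and meet the aliquot minimum;
imaging series must be uploaded with at least one series. A failing
biosampling or imaging record suppresses only its own fee, not the whole
visit's — the alternative (visit-level suppression) is not supported by
how the gates are defined per record. Every excluded record lands in
exactly one coded reason bucket so that
`survivors + Σ buckets = records` holds as a checked invariant; the coded
vocabulary extends the case-level reasons with record-level codes
(`NOT_SUBMITTED`, `NOT_REGISTERED`, `UNMAPPED_*`) so the partition is
total. eCRF items reach the catalogue through a reviewed mapping table
with per-row conditions (`always`, `value-present`, `plausibility-pass`);
unmapped items are counted and reported, never billed.

## Imputation of announced visits

Visits announced for the reimbursement period but falling after the
documentation freeze are reimbursed from *experience values*. The
experience value is the arithmetic mean of the realised cost of completed
visits of the same type, resolved at centre level first, then cohort
level, then a configured default — each imputed line records its
provenance, original lines are never altered, and disabling imputation
reproduces the pre-imputation totals exactly. The centre-first fallback
order is this package's choice: a centre's own case mix is the best
predictor of its future visit cost, and the hierarchy degrades gracefully
for centres without history.

## Run ledger and reports

Every run is content-addressed: MD5 digests of all inputs combine into a
run id, identical inputs give identical ids, and reports (CSV + Markdown,
scoped per audience so a centre sees only its own cases) regenerate
byte-identically from the same run. Wall-clock timestamps are recorded
only on request, precisely so that reproducibility is the default.
Correction loops are new runs with an incremented iteration counter, never
in-place edits. The audit step draws a seeded uniform sample of cases
(default 10) for item-by-item checks without touching the global RNG
state.

## Funding-model comparison

* **FRM**: `case_fee × n_reimbursed`, per cohort and centre class.
* **UFAM**: physician and nurse positions rounded to the nearest quarter
  FTE (ties away from zero) times their annual costs, plus consumables per
  case times the *target* number; a per-centre lump sum may be supplied
  instead when staffing inputs are unknown (which is how the published
  per-centre outcomes are reproduced, via the equal-share total implied by
  the lowest recruiter's published per-case allocation).
* **Reference**: PBRM funding, capped at the target for over-recruiters
  (`mean_per_case × min(n, target)`) — under an up-front model a centre
  would have stopped at target, so capping is applied to the comparison
  reference. FRM percentages are computed per case (uncapped), which is
  the form in which the published ratios (189.4% / 676.8% / 83.5% /
  127.9%) are exactly recovered; the capped UFAM ratios recover 192.4%
  and 337.4% for the two published over-recruiters. The published
  12,635.8% for the smallest centre recomputes to 12,635.7% from the
  published 2-decimal inputs — a ±0.005 € uncertainty on the published
  per-case mean propagates to ±0.33 percentage points on that ratio, so
  agreement at that precision is the attainable exactness.

Cost-efficiency is cases per 10,000 € budget unit: per centre,
`budget / cost_per_case` (PBRM: realised mean per case; FRM: the fee;
UFAM: funding over capped case count); per cohort, the mean of per-centre
ratios with a two-sided t-interval. The alternative definition — budget
divided by the cohort mean cost — gives the same published values at one
decimal; the mean of per-centre ratios is implemented because the CI and
ANOVA are defined over centre-level values. The ANOVA is the classical
one-way between/within F (computed via `stats::lm`), with the degenerate
all-equal-means case defined as F = 0, p = 1. Published cohort-level
confidence intervals for mean case reimbursement are not reproduced as
checks: their construction is not fully consistent with a centre-level
t-interval, so CIs are reported but not asserted. Cross-sectoral
non-academic centres are excluded from the comparison by default (their
financing structure differs).

## The synthetic cohort generator

Real study exports cannot be shipped, so the generator emulates their
structure: heterogeneous per-centre recruitment (explicit counts or a
uniform sampler; the `hap_like` preset mixes 4–164 cases around the
73.5-case target, matching the published extremes), severity via an ICU
probability and geometric (memoryless discharge; no published
length-of-stay law) or explicit-pmf stays, drop-out before discharge,
per-visit follow-up compliance, and the documentation noise the quality
gates exist for: unsubmitted forms, plausibility failures, missed case
reviews, missing biosampling/imaging participation, under-threshold
aliquot counts and failed uploads. Presets encode the four platform
shapes (`pop_like` generates exactly one on-site visit per case; targets
73.5 / 330 / 98.1). Each system draws pseudonyms from a disjoint
namespace (E-/B-/I- prefixes) so the linkage is genuinely exercised.

The generator emits a ground-truth table with the exact reimbursable
amount implied by its own records, computed record-by-record during
generation — oracle tests therefore never re-derive truth through the
engine they are checking. For configurations without record-level noise,
`implied_case_paths()` enumerates the exact visit-path distribution
(geometric stays truncated at tail mass 1e-10 and renormalised), which
`expected_case_fee()` prices in closed form; the test suite checks that
empirical mean reimbursement at n = 2000 cases falls within 3 Monte-Carlo
standard errors of that analytic value, and that follow-up fulfilment
tracks the compliance parameter among completers (drop-outs skip
follow-up by construction).

What the generator does **not** emulate: clinically meaningful values
inside eCRF items (values are opaque tokens), correlations between
severity and compliance, centre-specific documentation quality, or
epidemic-phase effects on case mix. Passing tests therefore demonstrate
the accounting, gating and comparison machinery — not that any particular
real cohort would yield these amounts. The packaged catalogue prices
eight exemplary items rather than a full study protocol, so simulated
per-case totals (~1,000 €) sit far below the negotiated case fees, which
incidentally mirrors the published finding that realised reimbursement
mostly fell short of expectations.

## Numerical choices and problem sizes

* Monetary rounding: half-up, 2 decimals, per component; integer-cent
  summation everywhere; percentages half-up to 1 decimal; quarter-FTE
  rounding ties away from zero.
* Half-up rounding guards against binary representation with a relative
  1e-12 plus absolute 1e-9 epsilon — inputs are parsed decimals, whose
  representation error is orders of magnitude below that.
* Geometric length-of-stay enumeration truncates at tail mass 1e-10.
* The study initiation fee for qualifying non-academic centres (≥ 5
  reimbursable cases) is configurable and defaults to 0, since no amount
  was published; it is reported separately from the line total so that
  line-level conservation stays exact.
* Default verification sizes: engine-vs-oracle agreement on 100 seeded
  small bundles, convergence checks at 2,000 cases, audit-sampling
  uniformity at 10,000 resamples — sizes at which Monte-Carlo error is
  far below the asserted tolerances while the whole suite stays
  interactive.
* Run digests use MD5 (`tools::md5sum`); the digest's role is content
  addressing for reproducibility, not cryptographic integrity.

## Known limitations

Contracts, fiscal-year booking, invoicing and the human correction-loop
negotiations around the published deployment are out of scope, as are
real trusted-third-party cryptography (linkage is exact pseudonym match)
and DICOM pixel data (imaging is metadata only). The plausibility-check
predicates shipped here (submitted/plausibility flags) stand in for a
study's own check catalogue, which is not public. Cohort-level confidence
intervals for mean case reimbursement are descriptive only.
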