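---
title: "Disproportionality screening for drug-induced coagulopathies"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality screening for drug-induced coagulopathies}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
library(dplyr)
```

## The surveillance problem

Spontaneous reporting systems such as FAERS collect voluntary adverse-event
reports without exposure denominators: we know how often a drug-event pair
was *reported*, never how often the drug was *taken*. Signal detection
therefore relies on disproportionality — comparing the share of coagulopathy
reports among a drug's reports with the same share among all other drugs'
reports. For each drug (or therapeutic class) the deduplicated database
collapses to a 2x2 table:

|              | coagulopathy PTs | other AEs |
|--------------|------------------|-----------|
| target drug (PS) | a            | b         |
| all other drugs  | c            | d         |

with N = a + b + c + d. `pvsignal` computes three statistics per table and
applies the standard positivity criteria:

* **ROR** = ad/bc, with Woolf 95% CI
  `exp(ln ROR ± 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`;
  flagged when a ≥ 3 and the lower bound exceeds 1.
* **PRR** = a(c+d)/(c(a+b)), with Pearson's chi-squared
  `(ad−bc)² N / ((a+b)(c+d)(a+c)(b+d))`;
  flagged when a ≥ 3, PRR ≥ 2 and chi-squared ≥ 4.
* **BCPNN IC** = log2(aN/((a+b)(a+c))), with credible bounds
  `E(IC) ± 2 sqrt(V(IC))`; flagged when IC025 > 0.

A drug is a **consensus positive** when any of the three criteria is met.
The three measures agree in sign (ROR > 1 ⇔ PRR > 1 ⇔ IC > 0 on
all-positive tables — an algebraic identity the test suite property-checks),
but their flags differ in conservatism: the IC credible bound shrinks small
counts toward independence, making BCPNN the most conservative at low a.

## The event definition

The event phenotype is impaired blood-clotting regulation, defined as the 26
MedDRA preferred terms grouped under the high-level term *coagulopathies*
(MedDRA 27.0, HLT 10064477). `coagulopathy_pts()` ships the dictionary with
each PT's numeric code and its published report frequency; matching is
case-insensitive after whitespace normalization, with a numeric-code
fallback so capitalization drift across MedDRA versions cannot drop
matches. Any two-column (`pt_name`, `pt_code`) file can replace the
dictionary to screen a different event.

One subtlety: the PT frequency table counts (case, PT) *pairs*, not cases —
a case reporting both "Coagulopathy" and "Heparin resistance" contributes to
two rows. That is why the published PT counts (42,013) exceed the case total
(40,545), and why `pt_distribution()` uses the pair total as its percentage
denominator.

## Deduplication

A case (`caseid`) accrues follow-up reports (`primaryid`). Following FDA
guidance, `dedup_cases()` keeps the report with the latest receipt date
(`fda_dt`); ties keep the numerically larger `primaryid`. A second pass
drops any residual exact `primaryid` duplicates, keeping the first
occurrence — the minimal reading of the auxiliary cleanup step that FAERS
processing pipelines apply after the main rule. Unparseable receipt dates
sort before all real dates, so a dated follow-up always supersedes an
undated one. The operation is idempotent and never invents records.

## Drug catalog decisions

The analysis unit is the canonical ingredient after normalization
(uppercase, whitespace collapse, trailing dose/form tokens stripped, synonym
lookup), with combination products kept as single entities — "etonogestrel
and ethinylestradiol vaginal ring" is one ranked drug, not two ingredients.
Only primary-suspect (PS) mentions enter the screen. Anticoagulants and
antiplatelets are removed *before* the top-N ranking: drugs given to treat
or prevent clotting disorders would otherwise dominate a coagulopathy screen
through confounding by indication. The exclusion list is a packaged,
editable text file, since no canonical membership exists.

The packaged therapeutic-class map follows pharmacovigilance reporting
practice rather than the strict ATC tree in one place: paracetamol and
ibuprofen both sit under "analgesics", although formal ATC places ibuprofen
under the anti-inflammatory class M01. Screens that need strict ATC can
supply their own map.

Class-level screening pools the case sets of the configured class members
among the screened (top-N, post-exclusion) entities; a case with two member
drugs counts once. Whether a published class analysis pools all members in
the database or only the ranked ones is generally ambiguous; we chose the
ranked-members reading and note that a single-member class therefore
reproduces its member's statistics exactly.

## The BCPNN credible interval

The published criterion is IC025 > 0 with bounds E(IC) ± 2 sqrt(V(IC)), but
V(IC) has several closed-form approximations in the literature. We define
E(IC) and V(IC) exactly: they are the posterior mean and variance of
log2(p11/(p1·p·1)) under a Dirichlet(1,1,1,1) prior on the four cell
probabilities updated with the observed cells, estimated by seeded
Monte-Carlo draws (default `n_draws = 1e5`; the screen records its seed in
the run metadata). This is well-defined, testable and faithful to the
"Bayesian confidence propagation" construction; the test suite checks that
the bounds are seeded-deterministic, converge at rate ~1/sqrt(n_draws)
(doubling the draws moves IC025 by under 0.02 bits on a moderate table) and
collapse onto the point IC as all cells scale up.

## Numerical choices

* **Zero cells.** When any cell is 0 the Haldane–Anscombe correction adds
  0.5 to all four cells for every statistic and sets `corrected = TRUE`;
  the *raw* a still governs the a ≥ 3 criterion. This keeps every entity
  reportable without inventing evidence.
* **Integer overflow.** Cell products such as (ad − bc)² exceed 32-bit
  integer range even at moderate database sizes; all cells are coerced to
  double before arithmetic.
* **Rounding.** Reported percentages and statistics round half away from
  zero (base R's `round()` rounds half to even), matching how published
  tables print 36.875 as 36.9.
* **Ranking ties.** Top-N ranking is by event-case count a, descending,
  ties broken alphabetically — deterministic across runs.
* **primaryid comparison.** Numeric when all ids parse as numbers (modern
  FAERS), lexicographic otherwise (legacy ISRs).

## What the synthetic generator emulates

`simulate_srs()` produces FAERS-format quarterly packages with known ground
truth. Each case draws its PS drug directly from the catalog's marginal use
probabilities, so the probability that drug D is primary suspect equals its
configured `use_prob` exactly, and a case on drug D reports a coagulopathy
PT with probability `min(1, p0 · RR_D)`. This makes
`expected_contingency()` an analytic oracle: E(a) = n · p_D · min(1, p0 ·
RR_D) with no approximation. On top of the PS drug, 0–2 secondary-suspect
or concomitant drugs are drawn (exercising the PS-only filter), verbatim
drug names are randomly decorated with dose/form suffixes (exercising
normalization), and a configurable fraction of cases is emitted twice under
one caseid — half the pairs 30 days apart in receipt date, half with equal
dates — exercising both deduplication branches.

Default study conditions, chosen once: baseline event probability p0 = 0.01
(coagulopathy PTs are ~2 per mille of FAERS reports; 1% keeps event counts
workable at desk scale), 30 drugs with equal use probability 1/30, 3 planted
at RR = 8, duplicate fraction 0.05, eight quarters, demographics and PT
weights defaulting to the published report mix so descriptive outputs
resemble real ones. Event probability depends only on the PS drug; extras
are pure noise.

What the generator does **not** emulate — and hence what passing tests do
not establish about real data: reporting delays and time-varying reporting
rates (the annual trend is uniform by construction), drug-name misspellings
beyond suffix decoration, correlated polypharmacy (co-prescription
patterns), event-dependent reporting (stimulated reporting after media
coverage), and confounding by indication. The anticoagulant exclusion, for
instance, matters on real data precisely because of a mechanism the
generator does not create.

## Calibration under the study conditions

Two seeded simulation studies validate the pipeline end to end:

* `simulate_ror_coverage()` draws 10,000 multinomial tables (N = 2000,
  margins 0.1/0.1) at true odds ratios 1, 2 and 5 and checks the Woolf 95%
  interval covers the truth ~95% of the time.
* `planted_recovery_sim()` runs 50 replicate databases of 50,000 cases
  (30 drugs, 3 planted at RR = 8, p0 = 0.01) through the complete pipeline
  and records planted-signal recovery (all three algorithms flag every
  planted drug) and the null consensus false-positive fraction. The
  replicate screens use `n_draws = 2e4` for the IC Monte Carlo — at planted
  counts (a ≈ 130) the Monte-Carlo error on IC025 is far below the
  decision boundary, and the reduced draw count keeps 50 replicates to a
  few minutes on one core.

`scripts/acceptance.R` re-runs both studies from scratch, together with the
published-arithmetic checks and a determinism/dedup check, and writes the
results as JSON.

## A worked example

```{r example}
cfg <- srs_config(n_cases = 20000, seed = 42)
db <- simulate_srs(cfg)

sc <- pv_screen(db, screen_config(
  synonym_map = character(),
  exclusion_list = character(),
  atc_map = setNames(cfg$drug_catalog$atc_class, cfg$drug_catalog$ingredient),
  n_draws = 2e4, seed = 7
))
sc
glance(sc)
tidy(sc) %>%
  select(ingredient, a, ror, ror_lo, ror_hi, prr, chi2, ic025, positive) %>%
  head(5)
```

The three planted drugs (SIMDRUG-01..03) surface at the top with RORs near
the planted relative risk of 8 scaled by the odds-vs-risk distinction, and
flag positive by all three algorithms; null drugs cluster around ROR 1.

```{r plots, fig.width = 6, fig.height = 4}
autoplot(sc, "forest")
autoplot(sc, "trend")
```

## Limitations

Disproportionality quantifies reporting association, not causation or
incidence. The package deliberately does not implement secondary-suspect or
concomitant-drug analyses, dose-dependence, multiple-testing adjustment
across entities (the consensus rule applies none), or probabilistic
duplicate detection across different caseids. The packaged synonym and
class maps cover the drugs relevant to the coagulopathy screen, not the
full RxNorm/WHO-DD or ATC universe; production screens of other events
should supply their own maps.
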