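---
title: "Disproportionality signal detection on FAERS-style report data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection on FAERS-style report data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersignal)
```

## The problem

Spontaneous reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect safety reports without exposure denominators: we know how
often a drug–event pair was *reported*, never how often it *occurred*.
Disproportionality analysis works around this by asking whether a pair is
reported more often than expected under independence within the database
itself. A flagged pair is a hypothesis-generating *signal*, not evidence of
causation — confounding by indication, stimulated reporting and duplicate
submissions all distort the counts, which is why the pipeline devotes as much
machinery to deduplication, cohort restriction and indication-PT exclusion as
to the statistics.

`faersignal` implements this workflow end to end for FAERS quarterly ASCII
extracts, with a synthetic generator that emulates the same file layout and a
known reporting model, so that every stage is testable offline.

## Pipeline model and assumptions

1. **Ingestion** (`read_quarter`, `assemble_cases`). Quarterly tables are
   dollar-delimited text with a header and no escaping. Each DEMO row is one
   *report version* (PRIMARYID) of a *case* (CASEID); DRUG, REAC, OUTC and
   INDI rows join on PRIMARYID. Rows with the wrong field count, orphan rows
   and blank reaction PTs are dropped with logged counts — never silently.
   Ages are converted to years (`DEC`×10, `YR`×1, `MON`÷12, `WK`÷52,
   `DY`÷365.25, `HR`÷8766; anything else becomes missing) and weights to kg
   (`LBS`×0.453592, `GMS`÷1000). Reporter occupations collapse to three
   buckets (physician; other health professional = PH/OT/HP/RN; consumer =
   CN/LW) mirroring how report tables conventionally present them.
2. **Deduplication** (`deduplicate`). One report per CASEID: the version with
   the latest FDA receipt date, ties broken by the numerically highest
   PRIMARYID. This is the FDA-recommended rule; it is idempotent and
   order-independent, which the tests assert on permuted inputs.
   Deduplication runs *before* drug restriction, matching the usual screening
   flow.
3. **Cohort** (`build_cohort`). A case is a target-drug report when any of
   its drug rows matches the query (case-insensitive substring over the
   verbatim name and active-ingredient fields by default; exact matching and
   synonym lists are available) *and* carries role `PS`. Everything else is
   background. FAERS drug names are free text, so the matching rule is
   deliberately configurable rather than hard-coded.
4. **Indication exclusion** (`apply_pt_exclusion`). Reaction PTs equal to the
   target drug's own recorded indications (joined on drug sequence number,
   harvested only within the cohort) are removed from the cohort's reaction
   sets before counting, to limit confounding by indication — a stone-former
   treated with an alkalinizing agent will report flank pain regardless of
   the drug. Events are removed, not reports: a case whose only reaction was
   excluded stays in the denominator.
5. **Contingency tables** (`count_tables`, `filter_min_count`). Distinct-
   report counting: a report contributes at most once to an event's `a` (or
   `c`), margins are cohort sizes, and at SOC level a report counts once per
   SOC regardless of PT multiplicity. A pair-counting mode exists behind
   `counting_unit = "pairs"` for sensitivity analyses. Events with `a ≤ 3`
   are excluded (`min_a = 3`), the conventional minimum-case filter.
6. **Statistics and decision** (`compute_signal_stats`, `decide_signal`,
   `run_level`). Four algorithms per table, thresholds as in the README;
   a signal requires at least two methods. Output is ranked by descending
   ROR, ties by descending `a` then label.

## Numerical choices

- **EBGM as a closed form.** The MGPS-style estimate here is the plain
  observed/expected ratio `a·N/((a+c)(a+b))`, identical to `2^IC`; no
  gamma-Poisson mixture is fitted. This keeps the estimator deterministic
  and the IC/EBGM identity exact, at the cost of no small-count shrinkage —
  the `a > 3` filter and the two-method rule carry that burden instead.
  A true empirical-Bayes fit is deliberately out of scope.
- **BCPNN interval.** The information component uses a 2-standard-deviation
  interval (multiplier 2, not 1.96) with the delta-method variance
  `V(IC) = (1/ln 2)² (1/a − 1/(a+b) − 1/(a+c) + 1/N)`, taking the
  point IC as its own expectation. For extreme tables where `a` nearly
  exhausts both margins the approximation can turn (slightly) negative, so
  the variance is clamped at zero. A fully Bayesian closed form would differ
  mostly for very small `a`, which the minimum-count filter already removes.
- **Zero cells.** The Haldane–Anscombe correction (+0.5 to all four cells)
  is applied per table only when a zero cell occurs, only for computing the
  statistics, and flagged `corrected` in output. Setting
  `zero_cell_policy = "undefined"` instead marks the statistics `NA`; an
  undefined method counts as "not met" in the decision.
- **χ² without continuity correction**, matching the standard PRR pairing.
- **Rounding.** Report output uses half-up rounding (`round_half_up`):
  2 decimals in tables, 1 decimal in prose-style percentages. Internal
  computation is always at full precision.
- **Ties and determinism.** Ranking ties break by `a` then lexicographic
  label; identical configuration and seed produce byte-identical outputs.

## The synthetic generator

`faers_scenario()` / `generate_faers()` simulate a quarter with known ground
truth. Each case is a target-drug case with probability
`target_drug_fraction`; it draws `k ~` zero-truncated Poisson (mean
`events_per_case_mean`) reaction PTs without replacement from a 40-term
catalog with probabilities proportional to `background_prob`, multiplied by
the injected relative rate for target cases. Duplicate versions (probability
`duplicate_rate`) replicate a case's rows verbatim under a lower PRIMARYID
and strictly earlier FDA_DT, so deduplication can be checked exactly against
the generated duplicate map. Demographics carry per-field missingness;
target cases carry an indication INDI row (default `Nephrolithiasis`)
attached to the target drug's sequence number so the exclusion stage is
exercised.

Defaults are fixed at the study conditions the package is modeled on:
10,000 cases with a 4% target fraction gives a cohort of roughly 400 reports;
1.9 events per report reflects a 758-entries/408-reports ratio; the 14%
duplicate rate matches large-scale FAERS screening (2.36M duplicates in
16.96M reports); missingness mirrors typical demographic completeness (age
25%, sex 12%, weight 90%, country 5%); and the injected rates 50/20/5/2 span
strong product-quality signals down to a weak clinical signal at the
detection margin.

`expected_contingency()` gives the analytic expectation of each 2×2 cell:
the inclusion probability of a PT with renormalized weight `p` is
`E_k[1 − (1−p)^k]`, the independent-draw approximation to weighted sampling
without replacement. For the small per-term weights used here the
approximation error is far below the Monte-Carlo noise of any single run;
recovery tests therefore compare estimated RORs and their confidence
intervals against these analytic values across seeds.

What the generator does *not* emulate — and what passing tests therefore do
not establish about real FAERS data: free-text drug-name noise and
misspellings, coding variability and MedDRA versioning drift, fragmented or
partially conflicting duplicate submissions, co-prescription structure,
stimulated-reporting dynamics after safety communications, and non-stationary
reporting over quarters. Results on real extracts inherit all of those
limitations.

## Configuration schema

`run_pipeline()` accepts a YAML file or list:

```yaml
input:                     # or `synthetic:` with faers_scenario() fields
  directory: faers/
  quarters: [2014Q1, 2014Q2]
  pattern: "{TABLE}{YY}Q{Q}.txt"
drug_query:
  name: potassium citrate
  match: substring          # or exact
  synonyms: []
meddra:
  dictionary_path: meddra.tsv   # TSV: pt, soc; required for SOC level
  unknown_policy: unmapped      # or drop
exclusion:
  extra_pts: []
  disable: false
analysis:
  min_count: 3
  zero_cell_policy: haldane     # or undefined
  counting_unit: reports        # or pairs
  levels: [PT, SOC]
descriptives:
  top_k_countries: 5
output:
  directory: out/
```

Every stage logs its drop counts; the run ledger records retrieved /
duplicate / unique / cohort / event-entry counts and enforces their
arithmetic.

## Problem sizes in the test suite

The bundled tests run the generator at 100–4,000 cases and 20 seeds for the
recovery properties (a rate-8 PT with expected `a ≥ 20` must be flagged in at
least 19 of 20 seeds; the estimated ROR must cover its analytic value in at
least 18 of 20; under a null scenario fewer than 10% of filtered events may
be flagged). These sizes give stable pass/fail behavior for the stated
bounds while keeping the full suite in the low minutes on one CPU.

## Known limitations

- The MedDRA dictionary is user-supplied; only a toy fixture ships.
  Primary-SOC mapping only (no multi-axiality, no HLT/HLGT levels).
- No stratified or time-scan analyses; single target drug per run.
- The closed-form EBGM overstates disproportionality for small `a` relative
  to a shrinkage estimator; interpret `EBGM05` accordingly.
- Seriousness is read off FAERS outcome codes only; the "serious" tally
  excludes the `OT` (other serious) code from its subset definition, a
  documented package choice.
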