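# faersignal

Pharmacovigilance signal detection on FDA Adverse Event Reporting System
(FAERS) quarterly extracts, built around the disproportionality workflow used
to profile potassium citrate's real-world adverse-event reports: parse the
dollar-delimited quarterly tables, deduplicate case versions, restrict to
reports where the drug of interest is the primary suspect, aggregate MedDRA
Preferred Terms (PT) to System Organ Classes (SOC), and score every drug–event
pair with four disproportionality algorithms under a two-method signal rule.

It is aimed at drug-safety analysts and methods researchers who want a tested,
scriptable version of this pipeline — including a synthetic FAERS-like
generator with analytic ground truth, so every stage can be validated without
downloading the real database.

## The statistics

For each event (PT or SOC) a 2×2 table is formed over deduplicated reports:
`a` target-drug reports with the event, `b` target-drug reports without it,
`c` background reports with the event, `d` the rest, `N = a+b+c+d`. Events
with `a ≤ 3` are excluded. Then:

| Method | Estimate | Signal threshold |
|---|---|---|
| ROR | `(a·d)/(b·c)`, 95% CI `exp[ln ROR ± 1.96·√(1/a+1/b+1/c+1/d)]` | CI lower bound > 1 |
| PRR | `[a/(a+b)]/[c/(c+d)]`, with `χ² = (ad−bc)²·N / [(a+b)(c+d)(a+c)(b+d)]` | PRR ≥ 2 and χ² ≥ 4 |
| BCPNN | `IC = log₂[a·N/((a+c)(a+b))]`, `IC025 = IC − 2√V(IC)` | IC025 > 0 |
| MGPS-style | `EBGM = a·N/((a+c)(a+b))`, `EBGM05 = exp[ln EBGM − 1.96·√(1/a+1/b+1/c+1/d)]` | EBGM05 > 2 |

A pair is a **signal** when at least two methods meet their threshold. EBGM is
the closed observed/expected form (`EBGM = 2^IC` exactly); no gamma-Poisson
shrinkage is applied. Zero cells get the Haldane–Anscombe +0.5 correction,
flagged in the output.

## Worked example

```r
library(faersignal)

# a synthetic quarter: 10,000 cases, ~4% with the target drug as primary
# suspect, four PTs injected at elevated relative reporting rates
scn <- faers_scenario(seed = 1)
sim <- generate_faers(scn)

cases  <- assemble_cases(sim$raw)
dedup  <- deduplicate(cases)
cohort <- build_cohort(dedup, drug_query("potassium citrate"))
cohort <- apply_pt_exclusion(cohort)          # drop indication-linked PTs
tables <- count_tables(cohort, level = "PT")
signals <- run_level(filter_min_count(tables))

head(signals[signals$is_signal,
             c("event_label", "a", "ror", "ror_low", "ic025", "ebgm05")])
```

```
                  event_label   a   ror ror_low ic025 ebgm05
1     Product residue present  66 38.42   25.98 3.622   9.44
2 Product solubility abnormal  12 13.99    6.79 2.508   4.31
3            Drug ineffective 144  4.11    3.32 1.308   2.27
4                        Rash  62  1.57    1.19 0.215   1.10
```

All four injected PTs are flagged (`is_signal`), with ROR estimates tracking
the injected rates after catalog renormalization. The rate-2 `Rash` injection
sits just above the detection margin — it meets only the two most sensitive
criteria (ROR lower bound and IC025), exactly how a weak true signal should
behave under the two-method rule. (Numbers are from `seed = 1`; other seeds
vary stochastically.)

A single table can be scored directly:

```r
stats_2x2(20, 80, 100, 9800)
#> ror 24.5 (14.4–41.5), prr 19.8, chi2 301.1, ic 4.06, ebgm05 9.83 -> signal
```

`run_pipeline("config.yaml")` runs the whole chain (real quarter files or a
synthetic scenario) and writes signals, contingency, descriptives and ledger
TSVs; see the methods vignette for the configuration schema.

## Data notes

MedDRA is licensed and not redistributable: the package ships only a 40-term
toy PT→SOC dictionary (`inst/extdata/meddra_toy.tsv`) used by tests and the
generator. Real analyses require a user-supplied mapping file (TSV, columns
`pt`, `soc`). FAERS quarterly extracts are public at the FDA web site.
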