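# Generator determinism, ground truth, duplicate mechanics, and the analytic
# expected contingency tables.

test_that("generation is deterministic under the seed and varies across seeds", {
  scn <- faers_scenario(n_cases = 150, seed = 3)
  s1 <- suppressMessages(generate_faers(scn))
  s2 <- suppressMessages(generate_faers(scn))
  for (tab in c("demo", "drug", "reac", "outc", "indi", "ther")) {
    expect_identical(s1$raw[[tab]], s2$raw[[tab]])
  }
  s3 <- suppressMessages(generate_faers(faers_scenario(n_cases = 150, seed = 4)))
  expect_false(identical(s1$raw$reac, s3$raw$reac))
})

test_that("scenario validation names the offending field", {
  expect_error(faers_scenario(duplicate_rate = 1.5), "duplicate_rate")
  expect_error(faers_scenario(events_per_case_mean = 0.5),
               "events_per_case_mean")
  expect_error(faers_scenario(injected_signals = c("Not a PT" = 5)),
               "injected_signals")
  expect_error(faers_scenario(missingness = list(age = 2, sex = 0, weight = 0,
                                                 country = 0)),
               "missingness")
})

test_that("duplicates share CASEID with earlier FDA_DT and dedup removes them all", {
  scn <- faers_scenario(n_cases = 400, duplicate_rate = 0.2, seed = 8)
  sim <- suppressMessages(generate_faers(scn))
  dm <- sim$truth$duplicate_map
  expect_gt(nrow(dm), 40)  # ~80 expected at rate 0.2

  demo <- sim$raw$demo
  orig <- demo[match(dm$primaryid_retained, demo$primaryid), ]
  dup <- demo[match(dm$primaryid_duplicate, demo$primaryid), ]
  expect_true(all(dup$caseid == orig$caseid))
  expect_true(all(as.integer(dup$fda_dt) < as.integer(orig$fda_dt)))
  expect_true(all(as.numeric(dup$primaryid) < as.numeric(orig$primaryid)))

  cases <- suppressMessages(assemble_cases(sim$raw))
  dd <- suppressMessages(deduplicate(cases))
  expect_equal(nrow(dd$retained), scn$n_cases)
  expect_equal(dd$n_duplicates_removed, nrow(dm))
  expect_setequal(dd$retained$primaryid, sim$truth$assignment$primaryid)
})

test_that("expected_contingency is analytic and errors on unknown PTs", {
  scn <- faers_scenario(n_cases = 10000, target_drug_fraction = 0.1,
                        injected_signals = c("Flank pain" = 5), seed = 1)
  expect_error(expected_contingency(scn, "No such PT"), "No such PT")

  et <- expected_contingency(scn, "Flank pain")
  expect_equal(et$expected_a + et$expected_b, 1000)
  expect_equal(et$expected_c + et$expected_d, 9000)
  expect_gt(et$expected_ror, 1)

  # null scenario: every expected ROR is 1
  null_scn <- faers_scenario(n_cases = 1000,
                             injected_signals = stats::setNames(
                               numeric(0), character(0)), seed = 1)
  cat0 <- faersignal:::expected_catalog(null_scn)
  expect_equal(cat0$expected_ror, rep(1, nrow(cat0)), tolerance = 1e-9)
})

test_that("observed cells track the analytic expectation", {
  scn <- faers_scenario(n_cases = 3000, target_drug_fraction = 0.1,
                        duplicate_rate = 0,
                        injected_signals = c("Drug ineffective" = 5),
                        indication_pts = character(0), indication_rate = 0,
                        seed = 14)
  res <- quiet_sim_cohort(scn)
  tabs <- count_tables(res$cohort, level = "PT")
  obs <- tabs[tabs$event_label == "Drug ineffective", ]
  et <- expected_contingency(scn, "Drug ineffective")
  # binomial 3-sigma envelopes around the analytic means
  for (cell in c("a", "c")) {
    e <- et[[paste0("expected_", cell)]]
    n_arm <- if (cell == "a") 300 else 2700
    sd <- sqrt(e * (1 - e / n_arm))
    expect_lt(abs(obs[[cell]] - e), 3 * sd + 3)
  }
})

test_that("simulate_quarter writes files that round-trip plus ground truth", {
  dir <- withr::local_tempdir()
  scn <- faers_scenario(n_cases = 80, seed = 12)
  sim <- suppressMessages(simulate_quarter(scn, dir, quarter = "2015Q2"))
  expect_true(file.exists(file.path(dir, "DEMO15Q2.txt")))
  expect_true(file.exists(file.path(dir, "ground_truth.tsv")))
  expect_true(file.exists(file.path(dir, "duplicate_map.tsv")))
  rt <- suppressMessages(read_quarter(dir, "2015Q2"))
  expect_equal(as.data.frame(rt$demo), as.data.frame(sim$raw$demo),
               ignore_attr = TRUE)
  gt <- readr::read_tsv(file.path(dir, "ground_truth.tsv"),
                        show_col_types = FALSE)
  expect_true(all(c("pt", "expected_a", "expected_ror") %in% names(gt)))
})
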