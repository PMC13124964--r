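# Case deduplication (latest FDA_DT, ties to highest PRIMARYID), cohort
# split on the primary-suspect drug, and indication-PT exclusion.

test_that("deduplicate keeps the most recent FDA_DT version", {
  cases <- fixture_cases(
    fixture_case("555", primaryid = "5551", fda_dt = 20240101),
    fixture_case("555", primaryid = "5552", fda_dt = 20240301))
  dd <- suppressMessages(deduplicate(cases))
  expect_equal(dd$retained$fda_dt, 20240301L)
  expect_equal(dd$n_duplicates_removed, 1)
  expect_equal(dd$n_input, 2)
})

test_that("FDA_DT ties break to the numerically highest PRIMARYID", {
  cases <- fixture_cases(
    fixture_case("555", primaryid = "5552", fda_dt = 20240101),
    fixture_case("555", primaryid = "5551", fda_dt = 20240101))
  dd <- suppressMessages(deduplicate(cases))
  expect_equal(dd$retained$primaryid, "5552")
})

test_that("distinct CASEIDs pass through untouched", {
  cases <- fixture_cases(lapply(1:10, function(i) fixture_case(i)))
  dd <- suppressMessages(deduplicate(cases))
  expect_equal(nrow(dd$retained), 10)
  expect_equal(dd$n_duplicates_removed, 0)
})

test_that("deduplication is idempotent and order-independent", {
  base <- fixture_cases(
    fixture_case("1", primaryid = "11", fda_dt = 20200101),
    fixture_case("1", primaryid = "12", fda_dt = 20200301),
    fixture_case("2", primaryid = "21", fda_dt = 20210101),
    fixture_case("2", primaryid = "22", fda_dt = 20210101),
    fixture_case("3", primaryid = "31", fda_dt = 20220101))
  dd <- suppressMessages(deduplicate(base))
  again <- suppressMessages(deduplicate(dd$retained))
  expect_equal(again$n_duplicates_removed, 0)
  expect_equal(again$retained, dd$retained)

  withr::with_seed(99, {
    for (rep in 1:5) {
      perm <- base[sample(nrow(base)), ]
      ddp <- suppressMessages(deduplicate(perm))
      expect_equal(ddp$retained$primaryid, dd$retained$primaryid)
    }
  })
})

test_that("non-integer PRIMARYID is a hard error", {
  cases <- fixture_cases(fixture_case("1", primaryid = "12A"))
  expect_error(deduplicate(cases), "PRIMARYID")
})

test_that("build_cohort splits on primary-suspect role and matches names", {
  cases <- fixture_cases(
    fixture_case("1", reactions = "Rash"),                       # PS target
    fixture_case("2", drugs = list(c("Potassium  Citrate ER", "PS"))),
    fixture_case("3", drugs = list(c("POTASSIUM CITRATE", "C"),
                                   c("METFORMIN", "PS"))),       # role C only
    bg_case("4", reactions = "Rash"))
  dd <- suppressMessages(deduplicate(cases))
  coh <- suppressMessages(build_cohort(dd, drug_query("potassium citrate")))
  expect_setequal(coh$drug_cases$caseid, c("1", "2"))
  expect_setequal(coh$background_cases$caseid, c("3", "4"))
  expect_equal(nrow(coh$drug_cases) + nrow(coh$background_cases),
               nrow(dd$retained))

  # exact matching is stricter
  coh2 <- suppressMessages(build_cohort(
    dd, drug_query("POTASSIUM CITRATE", match = "exact")))
  expect_equal(coh2$drug_cases$caseid, "1")
})

test_that("indication PTs are harvested only from the target drug's own rows", {
  cases <- fixture_cases(
    fixture_case("1", reactions = c("Nephrolithiasis", "Rash"),
                 indications = "Nephrolithiasis"),
    fixture_case("2", drugs = list(c("METFORMIN", "PS"),
                                   c("POTASSIUM CITRATE", "PS"))),
    bg_case("3", indications = "Hypertension"))
  # case 2: indication row attached to drug_seq 1 (metformin), not the target
  cases$indications[[2]] <- tibble::tibble(drug_seq = "1", pt = "Diabetes mellitus")
  dd <- suppressMessages(deduplicate(cases))
  coh <- suppressMessages(build_cohort(dd, drug_query("potassium citrate")))
  expect_equal(coh$excluded_pts, "Nephrolithiasis")
})

test_that("apply_pt_exclusion removes PTs but keeps the reports", {
  cases <- fixture_cases(
    fixture_case("1", reactions = c("Nephrolithiasis", "Rash"),
                 indications = "Nephrolithiasis"),
    fixture_case("2", reactions = "Nephrolithiasis",
                 indications = "Nephrolithiasis"),
    bg_case("3", reactions = "Nephrolithiasis"),
    bg_case("4", reactions = "Rash"))
  dd <- suppressMessages(deduplicate(cases))
  coh <- suppressMessages(build_cohort(dd, drug_query("potassium citrate")))
  coh <- suppressMessages(apply_pt_exclusion(coh))

  expect_equal(coh$drug_cases$reactions[[1]], "Rash")
  expect_equal(coh$drug_cases$reactions[[2]], character(0))
  expect_equal(nrow(coh$drug_cases), 2)  # emptied case stays in denominator
  # background untouched
  expect_equal(coh$background_cases$reactions[[1]], "Nephrolithiasis")

  tabs <- count_tables(coh, level = "PT")
  rash <- tabs[tabs$event_label == "Rash", ]
  expect_equal(rash$a + rash$b, 2)  # margin includes the emptied report

  # disabled / empty exclusion leaves the cohort unchanged
  coh0 <- suppressMessages(build_cohort(dd, drug_query("potassium citrate")))
  coh_id <- suppressMessages(apply_pt_exclusion(coh0, disable = TRUE))
  expect_equal(coh_id$drug_cases$reactions, coh0$drug_cases$reactions)
})

test_that("empty drug cohort warns rather than fails", {
  cases <- fixture_cases(bg_case("1"), bg_case("2"))
  dd <- suppressMessages(deduplicate(cases))
  expect_warning(suppressMessages(build_cohort(dd, drug_query("no such drug"))),
                 "no case matches")
})
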