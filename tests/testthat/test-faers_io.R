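# Quarterly file dialect: parsing, malformed-row handling, write round trip,
# and case assembly with unit conversions.

write_lines_q <- function(dir, name, lines) {
  writeLines(lines, file.path(dir, name))
}

make_mini_quarter <- function(dir) {
  write_lines_q(dir, "DEMO20Q1.txt", c(
    "primaryid$caseid$fda_dt$age$age_cod$sex$wt$wt_cod$occp_cod$occr_country",
    "1000012$100001$20200115$54$YR$F$150$LBS$MD$US",
    "1000022$100002$20200116$6$MON$M$$$CN$",
    "1000032$100003$20200120$$$$$$OT$CA"))
  write_lines_q(dir, "DRUG20Q1.txt", c(
    "primaryid$caseid$drug_seq$role_cod$drugname$prod_ai",
    "1000012$100001$1$PS$POTASSIUM CITRATE$POTASSIUM CITRATE",
    "1000012$100001$2$C$LISINOPRIL$LISINOPRIL",
    "1000022$100002$1$PS$METFORMIN$METFORMIN",
    "1000032$100003$1$PS$POTASSIUM CITRATE ER$POTASSIUM CITRATE",
    "9999992$999999$1$PS$ORPHAN DRUG$ORPHAN DRUG"))
  write_lines_q(dir, "REAC20Q1.txt", c(
    "primaryid$caseid$pt",
    "1000012$100001$Rash",
    "1000012$100001$Nausea",
    "1000012$100001$Rash",
    "1000022$100002$Headache",
    "1000032$100003$",
    "1000032$100003$Flank pain"))
  write_lines_q(dir, "OUTC20Q1.txt", c(
    "primaryid$caseid$outc_cod",
    "1000012$100001$HO",
    "1000012$100001$DE"))
  write_lines_q(dir, "INDI20Q1.txt", c(
    "primaryid$caseid$indi_drug_seq$indi_pt",
    "1000012$100001$1$Nephrolithiasis",
    "1000012$100001$2$Hypertension"))
  write_lines_q(dir, "THER20Q1.txt", c(
    "primaryid$caseid$dsg_drug_seq$start_dt$end_dt",
    "1000012$100001$1$20190101$"))
}

test_that("read_quarter preserves rows and skips malformed ones with a count", {
  dir <- withr::local_tempdir()
  make_mini_quarter(dir)
  raw <- suppressMessages(read_quarter(dir, "2020Q1"))
  expect_s3_class(raw$demo, "tbl_df")
  expect_equal(nrow(raw$demo), 3)
  expect_equal(raw$demo$primaryid, c("1000012", "1000022", "1000032"))
  expect_equal(names(raw$reac), c("primaryid", "caseid", "pt"))

  # a row with too few fields is skipped, not silently truncated
  write_lines_q(dir, "DEMO20Q1.txt", c(
    "primaryid$caseid$fda_dt",
    "12$1$20200101",
    "13$2"))
  expect_message(raw2 <- read_quarter(dir, "2020Q1"),
                 "skipped 1 malformed")
  expect_equal(nrow(raw2$demo), 1)
  expect_equal(attr(raw2$demo, "n_malformed"), 1L)
})

test_that("missing mandatory tables are fatal, optional ones warn", {
  dir <- withr::local_tempdir()
  make_mini_quarter(dir)
  file.remove(file.path(dir, "OUTC20Q1.txt"))
  expect_warning(raw <- suppressMessages(read_quarter(dir, "2020Q1")),
                 "OUTC20Q1.txt")
  expect_equal(nrow(raw$outc), 0)
  file.remove(file.path(dir, "REAC20Q1.txt"))
  expect_error(suppressWarnings(read_quarter(dir, "2020Q1")), "REAC20Q1.txt")
})

test_that("write_quarter round-trips a synthetic record set exactly", {
  scn <- faers_scenario(n_cases = 120, seed = 7)
  raw <- suppressMessages(generate_faers(scn))$raw
  dir <- withr::local_tempdir()
  write_quarter(raw, dir, quarter = "2014Q1")
  rt <- suppressMessages(read_quarter(dir, "2014Q1"))
  for (tab in c("demo", "drug", "reac", "outc", "indi", "ther")) {
    expect_equal(as.data.frame(rt[[tab]]), as.data.frame(raw[[tab]]),
                 ignore_attr = TRUE)
  }
  expect_equal(rt$source_quarter, "2014Q1")
})

test_that("write_quarter emits header-only files for an empty set and rejects '$'", {
  empty <- faersignal:::new_faers_raw(
    faersignal:::empty_faers_table("DEMO"),
    faersignal:::empty_faers_table("DRUG"),
    faersignal:::empty_faers_table("REAC"))
  dir <- withr::local_tempdir()
  write_quarter(empty, dir, quarter = "2014Q1")
  expect_equal(length(readLines(file.path(dir, "DEMO14Q1.txt"))), 1)
  rt <- suppressMessages(read_quarter(dir, "2014Q1"))
  expect_equal(nrow(rt$demo), 0)
  expect_equal(names(rt$drug), names(empty$drug))

  bad <- empty
  bad$demo <- tibble::tibble(primaryid = "1", caseid = "1",
                             fda_dt = "20200101", age = "bad$value",
                             age_cod = "", sex = "", wt = "", wt_cod = "",
                             occp_cod = "", occr_country = "")
  expect_error(write_quarter(bad, dir, quarter = "2014Q1"), "DEMO/age")
})

test_that("assemble_cases joins per PRIMARYID and converts units", {
  dir <- withr::local_tempdir()
  make_mini_quarter(dir)
  raw <- suppressMessages(read_quarter(dir, "2020Q1"))
  cases <- suppressMessages(assemble_cases(raw))

  expect_equal(nrow(cases), 3)  # one per distinct DEMO primaryid
  c1 <- cases[cases$primaryid == "1000012", ]
  expect_equal(nrow(c1$drugs[[1]]), 2)
  expect_setequal(c1$reactions[[1]], c("Rash", "Nausea"))  # PT deduplicated
  expect_setequal(c1$outcomes[[1]], c("HO", "DE"))
  expect_equal(c1$age_years, 54)
  expect_equal(c1$weight_kg, 150 * 0.453592)
  expect_equal(c1$sex, "female")
  expect_equal(c1$reporter, "physician")

  c2 <- cases[cases$primaryid == "1000022", ]
  expect_equal(c2$age_years, 0.5)  # 6 months
  expect_equal(c2$reporter, "consumer")
  expect_equal(c2$country, "unknown")

  c3 <- cases[cases$primaryid == "1000032", ]
  expect_true(is.na(c3$age_years))
  expect_equal(c3$reactions[[1]], "Flank pain")  # blank PT dropped
  expect_equal(c3$reporter, "other_health_professional")

  # no reaction PT anywhere is empty
  expect_false(any(!nzchar(unlist(cases$reactions))))
})

test_that("assemble_cases drops and counts orphan rows", {
  dir <- withr::local_tempdir()
  make_mini_quarter(dir)
  raw <- suppressMessages(read_quarter(dir, "2020Q1"))
  msgs <- capture_messages(cases <- assemble_cases(raw))
  expect_match(paste(msgs, collapse = "\n"), "1 orphan DRUG")
  expect_false("9999992" %in% cases$primaryid)
})

test_that("age and weight codes convert per FAERS conventions", {
  expect_equal(faersignal:::convert_age("6", "MON"), 0.5)
  expect_equal(faersignal:::convert_age("3", "DEC"), 30)
  expect_equal(faersignal:::convert_age("730.5", "DY"), 2)
  expect_true(is.na(faersignal:::convert_age("54", "XX")))
  expect_true(is.na(faersignal:::convert_age("-4", "YR")))
  expect_equal(faersignal:::convert_weight("1500", "GMS"), 1.5)
  expect_true(is.na(faersignal:::convert_weight("0", "KG")))
})
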