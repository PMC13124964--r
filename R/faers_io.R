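# FAERS quarterly ASCII dialect: one file per table per quarter, "$" as the
# single-character field delimiter, first line a header, no quoting and no
# escaping (a field may therefore never contain "$").

FAERS_TABLES <- c("DEMO", "DRUG", "REAC", "OUTC", "INDI", "THER")
FAERS_MANDATORY <- c("DEMO", "DRUG", "REAC")

# canonical column sets used for empty optional tables and by the generator
faers_table_columns <- list(
  DEMO = c("primaryid", "caseid", "fda_dt", "age", "age_cod", "sex",
           "wt", "wt_cod", "occp_cod", "occr_country"),
  DRUG = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  REAC = c("primaryid", "caseid", "pt"),
  OUTC = c("primaryid", "caseid", "outc_cod"),
  INDI = c("primaryid", "caseid", "indi_drug_seq", "indi_pt"),
  THER = c("primaryid", "caseid", "dsg_drug_seq", "start_dt", "end_dt")
)

OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI", "OT")

empty_faers_table <- function(table) {
  cols <- faers_table_columns[[table]]
  out <- as_tibble(stats::setNames(
    rep(list(character(0)), length(cols)), cols))
  out
}

# "2014Q1" -> DEMO14Q1.txt under the default pattern
quarter_filename <- function(table, quarter, pattern = "{TABLE}{YY}Q{Q}.txt") {
  if (!grepl("^[0-9]{4}Q[1-4]$", quarter)) {
    stop("quarter label must look like '2014Q1', got: ", quarter, call. = FALSE)
  }
  out <- gsub("{TABLE}", table, pattern, fixed = TRUE)
  out <- gsub("{YY}", substr(quarter, 3, 4), out, fixed = TRUE)
  gsub("{Q}", substr(quarter, 6, 6), out, fixed = TRUE)
}

# Split one line of the dialect. strsplit() drops trailing empty fields, so a
# sentinel is appended first; blank trailing fields are common in FAERS.
split_dollar <- function(lines) {
  parts <- strsplit(paste0(lines, "$\x01"), "$", fixed = TRUE)
  lapply(parts, function(p) p[-length(p)])
}

read_faers_table <- function(path, table) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stop("table file has no header line: ", path, call. = FALSE)
  }
  header <- split_dollar(lines[1])[[1]]
  header <- tolower(trimws(header))
  if (length(lines) == 1) {
    out <- as_tibble(stats::setNames(
      rep(list(character(0)), length(header)), header))
    attr(out, "n_malformed") <- 0L
    return(out)
  }
  rows <- split_dollar(lines[-1])
  ok <- lengths(rows) == length(header)
  n_malformed <- sum(!ok)
  if (n_malformed > 0) {
    fs_log("read_quarter: skipped ", n_malformed, " malformed row(s) in ",
           basename(path))
  }
  mat <- matrix(unlist(rows[ok]), ncol = length(header), byrow = TRUE)
  out <- as_tibble(stats::setNames(
    lapply(seq_len(ncol(mat)), function(j) mat[, j]), header))
  attr(out, "n_malformed") <- n_malformed
  out
}

new_faers_raw <- function(demo, drug, reac,
                          outc = empty_faers_table("OUTC"),
                          indi = empty_faers_table("INDI"),
                          ther = empty_faers_table("THER"),
                          source_quarter = "synthetic") {
  structure(
    list(demo = demo, drug = drug, reac = reac,
         outc = outc, indi = indi, ther = ther,
         source_quarter = source_quarter),
    class = "faers_raw")
}

#' Read one FAERS-style quarter from disk
#'
#' Parses the dollar-delimited ASCII tables of a quarterly extract. DEMO, DRUG
#' and REAC are mandatory; OUTC, INDI and THER are optional (missing files give
#' an empty table and a warning). Rows whose field count disagrees with the
#' header are skipped with a logged count; all values are kept as character,
#' preserving field order.
#'
#' @param directory directory containing the quarter's table files.
#' @param quarter quarter label, e.g. `"2014Q1"`.
#' @param pattern file-name pattern with `{TABLE}`, `{YY}`, `{Q}` placeholders;
#'   the default matches FDA naming (`DEMO14Q1.txt`).
#' @return A `faers_raw` record set: a list with tibbles `demo`, `drug`,
#'   `reac`, `outc`, `indi`, `ther` and the `source_quarter` label.
#' @seealso [write_quarter()], [assemble_cases()]
#' @export
read_quarter <- function(directory, quarter, pattern = "{TABLE}{YY}Q{Q}.txt") {
  if (!dir.exists(directory)) {
    stop("directory not found: ", directory, call. = FALSE)
  }
  tabs <- list()
  for (table in FAERS_TABLES) {
    path <- file.path(directory, quarter_filename(table, quarter, pattern))
    if (file.exists(path)) {
      tabs[[table]] <- read_faers_table(path, table)
    } else if (table %in% FAERS_MANDATORY) {
      stop("missing mandatory table file: ", path, call. = FALSE)
    } else {
      warning("optional table file missing, using empty table: ", path,
              call. = FALSE)
      tabs[[table]] <- empty_faers_table(table)
    }
  }
  new_faers_raw(tabs$DEMO, tabs$DRUG, tabs$REAC, tabs$OUTC, tabs$INDI,
                tabs$THER, source_quarter = quarter)
}

#' Write a record set as FAERS-style quarter files
#'
#' Emits the six dollar-delimited table files so that
#' `read_quarter(write_quarter(x))` is an exact field-for-field round trip.
#' The dialect has no escaping, so any field containing `"$"` is rejected.
#'
#' @param raw a `faers_raw` record set (see [read_quarter()]).
#' @param directory output directory, created if needed.
#' @param quarter quarter label used for file naming; defaults to the record
#'   set's own `source_quarter` when that is a valid label.
#' @inheritParams read_quarter
#' @return Invisibly, a named character vector of the files written.
#' @export
write_quarter <- function(raw, directory, quarter = NULL,
                          pattern = "{TABLE}{YY}Q{Q}.txt") {
  stopifnot(inherits(raw, "faers_raw"))
  if (is.null(quarter)) {
    quarter <- if (grepl("^[0-9]{4}Q[1-4]$", raw$source_quarter))
      raw$source_quarter else "2014Q1"
  }
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create output directory: ", directory, call. = FALSE)
  }
  paths <- character(0)
  for (table in FAERS_TABLES) {
    df <- raw[[tolower(table)]]
    for (col in names(df)) {
      if (any(grepl("$", df[[col]], fixed = TRUE))) {
        stop("field contains the '$' delimiter and cannot be written: ",
             table, "/", col, call. = FALSE)
      }
    }
    path <- file.path(directory, quarter_filename(table, quarter, pattern))
    body <- if (nrow(df) > 0) do.call(paste, c(df, sep = "$")) else character(0)
    writeLines(c(paste(names(df), collapse = "$"), body), path)
    paths[[table]] <- path
  }
  invisible(paths)
}

# --- unit conversions used when assembling cases -----------------------------

AGE_FACTORS <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52,
                 DY = 1 / 365.25, HR = 1 / 8766)
WT_FACTORS <- c(LBS = 0.453592, KG = 1, GMS = 1 / 1000)

convert_age <- function(age, age_cod) {
  v <- suppressWarnings(as.numeric(age))
  f <- AGE_FACTORS[toupper(trimws(age_cod))]
  out <- unname(v * f)
  out[!is.finite(out) | out < 0] <- NA_real_
  out
}

convert_weight <- function(wt, wt_cod) {
  v <- suppressWarnings(as.numeric(wt))
  f <- WT_FACTORS[toupper(trimws(wt_cod))]
  out <- unname(v * f)
  out[!is.finite(out) | out <= 0] <- NA_real_
  out
}

map_sex <- function(sex) {
  s <- toupper(trimws(sex))
  dplyr::case_when(s == "M" ~ "male", s == "F" ~ "female", TRUE ~ "unknown")
}

# Standard reporter buckets: physician / other health professional /
# consumer, everything else unknown.
map_reporter <- function(occp_cod) {
  s <- toupper(trimws(occp_cod))
  dplyr::case_when(
    s == "MD" ~ "physician",
    s %in% c("PH", "OT", "HP", "RN") ~ "other_health_professional",
    s %in% c("CN", "LW") ~ "consumer",
    TRUE ~ "unknown")
}

# split rows of df by primaryid, restricted to pids (orphans counted, dropped)
split_by_pid <- function(df, pids, what) {
  n_orphan <- sum(!(df$primaryid %in% pids))
  if (n_orphan > 0) {
    fs_log("assemble_cases: dropped ", n_orphan, " orphan ", what,
           " row(s) with no matching DEMO report")
  }
  idx <- split(seq_len(nrow(df)), factor(df$primaryid, levels = pids))
  list(rows = idx, n_orphan = n_orphan)
}

#' Assemble joined safety-report cases from a raw record set
#'
#' Joins the DRUG, REAC, OUTC and INDI rows onto each DEMO report (keyed by
#' PRIMARYID, one report version per row), converts age and weight to years
#' and kilograms, and maps sex and reporter occupation onto the standard
#' buckets. Rows referencing a PRIMARYID absent from DEMO are dropped with a
#' logged count, as are blank reaction PT strings.
#'
#' @param raw a `faers_raw` record set from [read_quarter()] or
#'   [generate_faers()].
#' @return A `faers_cases` tibble with one row per report version: `caseid`,
#'   `primaryid`, `fda_dt` (integer `yyyymmdd`), `age_years`, `sex`,
#'   `weight_kg`, `reporter`, `country`, and list-columns `drugs` (tibble of
#'   `drug_seq`, `drugname`, `prod_ai`, `role_cod`), `reactions` (unique PT
#'   strings), `outcomes` (outcome codes) and `indications` (tibble of
#'   `drug_seq`, `pt`).
#' @export
assemble_cases <- function(raw) {
  stopifnot(inherits(raw, "faers_raw"))
  demo <- raw$demo
  need <- c("primaryid", "caseid", "fda_dt")
  if (!all(need %in% names(demo))) {
    stop("DEMO table lacks required column(s): ",
         paste(setdiff(need, names(demo)), collapse = ", "), call. = FALSE)
  }
  if (anyDuplicated(demo$primaryid)) {
    fs_log("assemble_cases: DEMO has duplicated PRIMARYIDs; keeping first occurrence")
    demo <- demo[!duplicated(demo$primaryid), ]
  }
  pids <- demo$primaryid

  col_or_blank <- function(df, col) {
    if (col %in% names(df)) df[[col]] else rep("", nrow(df))
  }

  drug <- raw$drug
  drug_tbl <- tibble(
    primaryid = col_or_blank(drug, "primaryid"),
    drug_seq = col_or_blank(drug, "drug_seq"),
    drugname = col_or_blank(drug, "drugname"),
    prod_ai = col_or_blank(drug, "prod_ai"),
    role_cod = toupper(trimws(col_or_blank(drug, "role_cod"))))
  dsp <- split_by_pid(drug_tbl, pids, "DRUG")
  drugs <- lapply(dsp$rows, function(i) drug_tbl[i, -1])

  reac <- raw$reac
  pt_raw <- trimws(col_or_blank(reac, "pt"))
  n_blank_pt <- sum(!nzchar(pt_raw) & reac$primaryid %in% pids)
  if (n_blank_pt > 0) {
    fs_log("assemble_cases: dropped ", n_blank_pt, " blank reaction PT(s)")
  }
  reac_tbl <- tibble(primaryid = col_or_blank(reac, "primaryid"), pt = pt_raw)
  reac_tbl <- reac_tbl[nzchar(reac_tbl$pt), ]
  rsp <- split_by_pid(reac_tbl, pids, "REAC")
  reactions <- lapply(rsp$rows, function(i) unique(reac_tbl$pt[i]))

  outc_tbl <- tibble(primaryid = col_or_blank(raw$outc, "primaryid"),
                     outc_cod = toupper(trimws(col_or_blank(raw$outc, "outc_cod"))))
  outc_tbl <- outc_tbl[nzchar(outc_tbl$outc_cod), ]
  osp <- split_by_pid(outc_tbl, pids, "OUTC")
  outcomes <- lapply(osp$rows, function(i) unique(outc_tbl$outc_cod[i]))

  indi_tbl <- tibble(primaryid = col_or_blank(raw$indi, "primaryid"),
                     drug_seq = col_or_blank(raw$indi, "indi_drug_seq"),
                     pt = trimws(col_or_blank(raw$indi, "indi_pt")))
  indi_tbl <- indi_tbl[nzchar(indi_tbl$pt), ]
  isp <- split_by_pid(indi_tbl, pids, "INDI")
  indications <- lapply(isp$rows, function(i) indi_tbl[i, -1])

  country <- trimws(col_or_blank(demo, "occr_country"))
  country[!nzchar(country)] <- "unknown"

  out <- tibble(
    caseid = demo$caseid,
    primaryid = demo$primaryid,
    fda_dt = suppressWarnings(as.integer(demo$fda_dt)),
    age_years = convert_age(col_or_blank(demo, "age"),
                            col_or_blank(demo, "age_cod")),
    sex = map_sex(col_or_blank(demo, "sex")),
    weight_kg = convert_weight(col_or_blank(demo, "wt"),
                               col_or_blank(demo, "wt_cod")),
    reporter = map_reporter(col_or_blank(demo, "occp_cod")),
    country = country,
    drugs = unname(drugs),
    reactions = unname(reactions),
    outcomes = unname(outcomes),
    indications = unname(indications))
  class(out) <- c("faers_cases", class(out))
  out
}

#' Coerce a data frame to a `faers_cases` tibble
#'
#' Validates the column contract of [assemble_cases()] output and fills any
#' missing optional columns with empty defaults. Intended for building small
#' case sets directly in examples and tests.
#'
#' @param df data frame with at least `caseid`, `primaryid`, `fda_dt`.
#' @return A `faers_cases` tibble.
#' @export
as_faers_cases <- function(df) {
  need <- c("caseid", "primaryid", "fda_dt")
  if (!all(need %in% names(df))) {
    stop("faers_cases requires column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "), call. = FALSE)
  }
  n <- nrow(df)
  defaults <- list(
    age_years = rep(NA_real_, n), sex = rep("unknown", n),
    weight_kg = rep(NA_real_, n), reporter = rep("unknown", n),
    country = rep("unknown", n),
    drugs = rep(list(tibble(drug_seq = character(0), drugname = character(0),
                            prod_ai = character(0), role_cod = character(0))), n),
    reactions = rep(list(character(0)), n),
    outcomes = rep(list(character(0)), n),
    indications = rep(list(tibble(drug_seq = character(0), pt = character(0))), n))
  out <- as_tibble(df)
  out$caseid <- as.character(out$caseid)
  out$primaryid <- as.character(out$primaryid)
  out$fda_dt <- as.integer(out$fda_dt)
  for (col in names(defaults)) {
    if (!col %in% names(out)) out[[col]] <- defaults[[col]]
  }
  class(out) <- c("faers_cases", setdiff(class(out), "faers_cases"))
  out
}
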