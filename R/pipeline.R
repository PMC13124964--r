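# Config-driven end-to-end pipeline with run accounting: ingestion ->
# deduplication -> cohort -> PT/SOC contingency tables -> disproportionality
# -> descriptives, every stage's drop counts echoed in a ledger.

#' Run accounting ledger
#'
#' Records the flow counts of one pipeline run and enforces their arithmetic:
#' `n_unique = n_retrieved - n_duplicates_removed`, and the target-drug cohort
#' can be no larger than the unique case count.
#'
#' @param n_retrieved report versions retrieved (assembled from DEMO).
#' @param n_duplicates_removed versions removed by [deduplicate()].
#' @param n_drug_reports unique reports in the target-drug cohort.
#' @param n_event_entries reaction PT entries across the cohort's reports.
#' @return A `faers_ledger` list with `n_unique` computed.
#' @examples
#' run_ledger(16964192, 2363307)$n_unique  # 14600885
#' @export
run_ledger <- function(n_retrieved, n_duplicates_removed,
                       n_drug_reports = NA_integer_,
                       n_event_entries = NA_integer_) {
  if (n_duplicates_removed > n_retrieved) {
    stop("ledger arithmetic violated: duplicates removed exceeds retrieved",
         call. = FALSE)
  }
  n_unique <- n_retrieved - n_duplicates_removed
  if (!is.na(n_drug_reports) && n_drug_reports > n_unique) {
    stop("ledger arithmetic violated: drug reports exceed unique cases",
         call. = FALSE)
  }
  structure(
    list(n_retrieved = n_retrieved,
         n_duplicates_removed = n_duplicates_removed,
         n_unique = n_unique,
         n_drug_reports = n_drug_reports,
         n_event_entries = n_event_entries,
         timestamps = c(created = Sys.time())),
    class = "faers_ledger")
}

#' @export
print.faers_ledger <- function(x, ...) {
  cat("FAERS run ledger\n",
      "  reports retrieved:   ", format(x$n_retrieved, big.mark = ","), "\n",
      "  duplicates removed:  ", format(x$n_duplicates_removed, big.mark = ","), "\n",
      "  unique cases:        ", format(x$n_unique, big.mark = ","), "\n",
      "  target-drug reports: ", x$n_drug_reports, "\n",
      "  event entries:       ", x$n_event_entries, "\n", sep = "")
  invisible(x)
}

ledger_tibble <- function(ledger) {
  tibble(quantity = c("n_retrieved", "n_duplicates_removed", "n_unique",
                      "n_drug_reports", "n_event_entries"),
         value = c(ledger$n_retrieved, ledger$n_duplicates_removed,
                   ledger$n_unique, ledger$n_drug_reports,
                   ledger$n_event_entries))
}

# recursively overlay user config onto defaults
merge_config <- function(defaults, user) {
  for (nm in names(user)) {
    if (is.list(defaults[[nm]]) && is.list(user[[nm]]) &&
        !is.null(names(user[[nm]]))) {
      defaults[[nm]] <- merge_config(defaults[[nm]], user[[nm]])
    } else {
      defaults[[nm]] <- user[[nm]]
    }
  }
  defaults
}

default_config <- function() {
  list(
    input = NULL,     # list(directory, quarters, pattern)
    synthetic = NULL, # scenario overrides incl. seed
    drug_query = list(name = "POTASSIUM CITRATE", match = "substring",
                      synonyms = list()),
    meddra = list(dictionary_path = NULL, unknown_policy = "unmapped"),
    exclusion = list(extra_pts = list(), disable = FALSE),
    analysis = list(min_count = 3, zero_cell_policy = "haldane",
                    counting_unit = "reports", levels = list("PT", "SOC")),
    descriptives = list(top_k_countries = 5),
    output = list(directory = NULL))
}

run_stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("[stage %s] %s", name, conditionMessage(e)), call. = FALSE)
  })
}

#' Run the full signal-detection pipeline from a configuration
#'
#' Executes ingestion (quarter files named in `input`, or the synthetic
#' generator configured under `synthetic`), deduplication, cohort
#' construction, indication-PT exclusion, contingency tables,
#' disproportionality with signal decisions, and cohort descriptives. With an
#' `output$directory` all result tables are written as TSV; errors in any
#' stage propagate with a stage-named message and remove partial outputs.
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Unset keys fall back to documented defaults; see the package
#'   vignette for the schema.
#' @return Invisibly, a list with `cases`, `dedup`, `cohort`, `tables` and
#'   `signals` (one element per requested level), `descriptives`, `ledger`,
#'   and `output_files`.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(default_config(), config)
  written <- character(0)
  on_error_cleanup <- function() unlink(written)

  sim <- NULL
  raw <- run_stage("faers_io", {
    if (!is.null(cfg$synthetic)) {
      scn <- do.call(faers_scenario, cfg$synthetic)
      sim <- generate_faers(scn)
      sim$raw
    } else if (!is.null(cfg$input)) {
      pattern <- cfg$input$pattern %||% "{TABLE}{YY}Q{Q}.txt"
      quarters <- unlist(cfg$input$quarters)
      raws <- lapply(quarters, function(q)
        read_quarter(cfg$input$directory, q, pattern))
      if (length(raws) == 1) raws[[1]] else {
        new_faers_raw(
          demo = bind_rows(lapply(raws, `[[`, "demo")),
          drug = bind_rows(lapply(raws, `[[`, "drug")),
          reac = bind_rows(lapply(raws, `[[`, "reac")),
          outc = bind_rows(lapply(raws, `[[`, "outc")),
          indi = bind_rows(lapply(raws, `[[`, "indi")),
          ther = bind_rows(lapply(raws, `[[`, "ther")),
          source_quarter = paste(quarters, collapse = "+"))
      }
    } else {
      stop("config must provide either 'input' or 'synthetic'")
    }
  })

  cases <- run_stage("faers_io", assemble_cases(raw))
  dedup <- run_stage("dedup_cohort", deduplicate(cases))
  cohort <- run_stage("dedup_cohort", {
    q <- drug_query(cfg$drug_query$name, cfg$drug_query$match,
                    unlist(cfg$drug_query$synonyms) %||% character(0))
    build_cohort(dedup, q)
  })
  n_event_entries <- sum(lengths(cohort$drug_cases$reactions))
  cohort <- run_stage("dedup_cohort", apply_pt_exclusion(
    cohort, extra_pts = unlist(cfg$exclusion$extra_pts) %||% character(0),
    disable = isTRUE(cfg$exclusion$disable)))

  levels <- toupper(unlist(cfg$analysis$levels))
  dict <- run_stage("meddra_map", {
    if ("SOC" %in% levels) {
      if (is.null(cfg$meddra$dictionary_path)) {
        stop("SOC-level analysis requested but meddra$dictionary_path is not set")
      }
      load_pt_soc(cfg$meddra$dictionary_path)
    } else NULL
  })

  tables <- list()
  signals <- list()
  for (lv in levels) {
    tabs <- run_stage("contingency", count_tables(
      cohort, dict = dict, level = lv,
      counting_unit = cfg$analysis$counting_unit,
      unknown_policy = cfg$meddra$unknown_policy))
    tables[[lv]] <- tabs
    signals[[lv]] <- run_stage("disproportionality", run_level(
      filter_min_count(tabs, cfg$analysis$min_count),
      zero_cell_policy = cfg$analysis$zero_cell_policy))
  }

  descr <- run_stage("descriptives", summarize_cases(
    cohort$drug_cases, top_k_countries = cfg$descriptives$top_k_countries))

  ledger <- run_ledger(
    n_retrieved = dedup$n_input,
    n_duplicates_removed = dedup$n_duplicates_removed,
    n_drug_reports = nrow(cohort$drug_cases),
    n_event_entries = n_event_entries)

  out_dir <- cfg$output$directory
  if (!is.null(out_dir)) {
    run_stage("cli_report", tryCatch({
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      for (lv in levels) {
        p1 <- file.path(out_dir, paste0("contingency_", tolower(lv), ".tsv"))
        readr::write_tsv(tables[[lv]], p1)
        written <- c(written, p1)
        p2 <- file.path(out_dir, paste0("signals_", tolower(lv), ".tsv"))
        readr::write_tsv(signals[[lv]], p2)
        written <- c(written, p2)
      }
      p3 <- file.path(out_dir, "descriptives.tsv")
      readr::write_tsv(descriptives_table(descr), p3)
      p4 <- file.path(out_dir, "ledger.tsv")
      readr::write_tsv(ledger_tibble(ledger), p4)
      written <- c(written, p3, p4)
    }, error = function(e) {
      on_error_cleanup()
      stop(e)
    }))
  }

  invisible(list(cases = cases, dedup = dedup, cohort = cohort,
                 tables = tables, signals = signals, descriptives = descr,
                 ledger = ledger, sim = sim, output_files = written))
}
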