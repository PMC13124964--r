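# Small case-set builders used across the module tests.

toy_dict_path <- function() {
  system.file("extdata", "meddra_toy.tsv", package = "faersignal",
              mustWork = TRUE)
}

toy_dict <- function() load_pt_soc(toy_dict_path())

# one assembled case row; drugs given as list(c(name, role), ...)
fixture_case <- function(caseid, primaryid = paste0(caseid, "2"),
                         fda_dt = 20200101L,
                         drugs = list(c("POTASSIUM CITRATE", "PS")),
                         reactions = character(0),
                         outcomes = character(0),
                         indications = character(0),
                         age_years = NA_real_, sex = "unknown",
                         weight_kg = NA_real_, reporter = "unknown",
                         country = "US") {
  dr <- tibble::tibble(
    drug_seq = as.character(seq_along(drugs)),
    drugname = vapply(drugs, `[[`, "", 1),
    prod_ai = vapply(drugs, `[[`, "", 1),
    role_cod = vapply(drugs, `[[`, "", 2))
  tibble::tibble(
    caseid = as.character(caseid), primaryid = as.character(primaryid),
    fda_dt = as.integer(fda_dt), age_years = age_years, sex = sex,
    weight_kg = weight_kg, reporter = reporter, country = country,
    drugs = list(dr), reactions = list(reactions), outcomes = list(outcomes),
    indications = list(tibble::tibble(
      drug_seq = rep("1", length(indications)), pt = indications)))
}

fixture_cases <- function(...) {
  as_faers_cases(dplyr::bind_rows(...))
}

# background case reporting given reactions under a non-target drug
bg_case <- function(caseid, reactions = character(0), ...) {
  fixture_case(caseid, drugs = list(c("METFORMIN", "PS")),
               reactions = reactions, ...)
}

# run dedup -> cohort -> exclusion -> PT tables -> decisions, quietly
quiet_signal_run <- function(cases, min_a = 3, level = "PT", dict = NULL) {
  suppressWarnings(suppressMessages({
    dd <- deduplicate(cases)
    coh <- build_cohort(dd, drug_query("potassium citrate"))
    coh <- apply_pt_exclusion(coh)
    tabs <- count_tables(coh, dict = dict, level = level)
    run_level(filter_min_count(tabs, min_a))
  }))
}

# generator -> assembled, deduplicated cohort with exclusions, quietly
quiet_sim_cohort <- function(scenario) {
  suppressWarnings(suppressMessages({
    sim <- generate_faers(scenario)
    cases <- assemble_cases(sim$raw)
    dd <- deduplicate(cases)
    coh <- build_cohort(dd, drug_query(scenario$target_drug))
    list(sim = sim, cohort = apply_pt_exclusion(coh))
  }))
}
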