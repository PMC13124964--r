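# Cohort descriptives: age / sex / weight bands, reporter occupation, top
# reporting countries and outcome-code tallies, each with percentages of the
# cohort size. Band edges follow the conventional reporting bands: age < 18,
# 18-64 (closed on both ends), > 64; weight < 80 kg, 80-100 kg (closed),
# > 100 kg; missing values fall into "unknown" so every banded category
# partitions the cohort.

SERIOUS_OUTCOME_CODES <- c("DE", "LT", "HO", "DS", "CA", "RI")

band_counts <- function(band, levels, n_total) {
  n <- as.integer(table(factor(band, levels = levels)))
  tibble(category = levels, n = n, pct = percent_of(n, n_total, 2))
}

#' Descriptive summary of a target-drug cohort
#'
#' @param cases a `faers_cases` tibble, normally `cohort$drug_cases`.
#' @param top_k_countries how many countries to list (default 5).
#' @return A `faers_descriptives` list of tibbles (`age_bands`, `sex`,
#'   `weight_bands`, `reporter`, `countries`, `outcomes`; each with `n` and
#'   `pct`, percentages of `n_total` rounded half-up to 2 decimals), plus
#'   `n_outcome_reports` (reports with at least one outcome code),
#'   `n_serious_reports` (at least one code in DE/LT/HO/DS/CA/RI) and
#'   `n_total`.
#' @details A report with several outcome codes counts once per code and once
#'   toward `n_outcome_reports`.
#' @export
summarize_cases <- function(cases, top_k_countries = 5) {
  stopifnot(inherits(cases, "faers_cases"))
  n_total <- nrow(cases)

  age <- cases$age_years
  age_band <- dplyr::case_when(
    is.na(age) ~ "unknown", age < 18 ~ "<18", age <= 64 ~ "18-64",
    TRUE ~ ">64")
  wt <- cases$weight_kg
  wt_band <- dplyr::case_when(
    is.na(wt) ~ "unknown", wt < 80 ~ "<80", wt <= 100 ~ "80-100",
    TRUE ~ ">100")

  country_n <- sort(table(cases$country), decreasing = TRUE)
  country_n <- utils::head(country_n, top_k_countries)
  countries <- tibble(category = names(country_n),
                      n = as.integer(country_n),
                      pct = percent_of(as.integer(country_n), n_total, 2))

  out_codes <- unlist(cases$outcomes)
  outcomes <- tibble(
    category = OUTCOME_CODES,
    n = as.integer(table(factor(out_codes, levels = OUTCOME_CODES))))
  outcomes$pct <- percent_of(outcomes$n, n_total, 2)

  structure(
    list(
      age_bands = band_counts(age_band, c("<18", "18-64", ">64", "unknown"),
                              n_total),
      sex = band_counts(cases$sex, c("male", "female", "unknown"), n_total),
      weight_bands = band_counts(wt_band, c("<80", "80-100", ">100", "unknown"),
                                 n_total),
      reporter = band_counts(
        cases$reporter,
        c("physician", "other_health_professional", "consumer", "unknown"),
        n_total),
      countries = countries,
      outcomes = outcomes,
      n_outcome_reports = sum(lengths(cases$outcomes) > 0),
      n_serious_reports = sum(vapply(
        cases$outcomes, function(o) any(o %in% SERIOUS_OUTCOME_CODES),
        logical(1))),
      n_total = n_total),
    class = "faers_descriptives")
}

#' Flatten a descriptive summary to one tidy table
#'
#' @param summary a `faers_descriptives` from [summarize_cases()].
#' @return Tibble with columns `section`, `category`, `n`, `pct`.
#' @export
descriptives_table <- function(summary) {
  stopifnot(inherits(summary, "faers_descriptives"))
  sections <- c("age_bands", "sex", "weight_bands", "reporter",
                "countries", "outcomes")
  parts <- lapply(sections, function(s) {
    dplyr::mutate(summary[[s]], section = s, .before = 1)
  })
  extra <- tibble(
    section = "totals",
    category = c("n_total", "n_outcome_reports", "n_serious_reports"),
    n = c(summary$n_total, summary$n_outcome_reports,
          summary$n_serious_reports),
    pct = c(100, percent_of(summary$n_outcome_reports, summary$n_total, 2),
            percent_of(summary$n_serious_reports, summary$n_total, 2)))
  bind_rows(c(parts, list(extra)))
}

#' @export
print.faers_descriptives <- function(x, ...) {
  pct1 <- function(n) round_half_up(100 * n / x$n_total, 1)
  cat("Cohort of", x$n_total, "reports\n")
  blocks <- list("Age (years)" = x$age_bands, "Sex" = x$sex,
                 "Weight (kg)" = x$weight_bands, "Reporter" = x$reporter,
                 "Country (top)" = x$countries)
  for (nm in names(blocks)) {
    b <- blocks[[nm]]
    cat(nm, ":\n", sep = "")
    for (i in seq_len(nrow(b))) {
      cat(sprintf("  %-28s %5d (%.1f%%)\n", b$category[i], b$n[i],
                  pct1(b$n[i])))
    }
  }
  cat(sprintf("Reports with outcome code(s):  %d (%.1f%%)\n",
              x$n_outcome_reports, pct1(x$n_outcome_reports)))
  cat(sprintf("Reports with serious code(s):  %d (%.1f%%)\n",
              x$n_serious_reports, pct1(x$n_serious_reports)))
  invisible(x)
}
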