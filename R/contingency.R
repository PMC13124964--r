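# 2x2 contingency tables per drug-event pair:
#   a  target-drug reports with the event     b  target-drug reports without it
#   c  background reports with the event      d  background reports without it
# Counting unit is distinct reports: a report contributes at most once to a
# given event label, and the margins a+b / c+d are the cohort sizes, constant
# across all tables of one run at one level.

#' Build contingency tables for every PT or SOC
#'
#' One table per event label observed anywhere in the data at the requested
#' level. At SOC level each case's reaction PTs are mapped through the
#' dictionary and a report counts once per SOC no matter how many of its PTs
#' map there.
#'
#' @param cohort a `faers_cohort`, deduplicated and (normally) after
#'   [apply_pt_exclusion()].
#' @param dict a `pt_soc_dict`; required for `level = "SOC"`.
#' @param level `"PT"` or `"SOC"`.
#' @param counting_unit `"reports"` (default; distinct-report counting) or
#'   `"pairs"` (each case-event pair counts, margins are pair totals) for
#'   sensitivity analyses.
#' @param unknown_policy passed to [soc_of()] at SOC level.
#' @return A tibble with columns `event_label`, `level`, `a`, `b`, `c`, `d`,
#'   `n_total`, ordered by decreasing `a`.
#' @export
count_tables <- function(cohort, dict = NULL, level = c("PT", "SOC"),
                         counting_unit = c("reports", "pairs"),
                         unknown_policy = "unmapped") {
  stopifnot(inherits(cohort, "faers_cohort"))
  level <- match.arg(level)
  counting_unit <- match.arg(counting_unit)
  if (level == "SOC" && is.null(dict)) {
    stop("SOC-level counting requires a PT -> SOC dictionary", call. = FALSE)
  }

  events_of <- function(reactions) {
    ev <- if (level == "PT") reactions
          else soc_of(reactions, dict, unknown_policy)
    ev <- ev[!is.na(ev)]
    if (counting_unit == "reports") unique(ev) else ev
  }

  drug_ev <- lapply(cohort$drug_cases$reactions, events_of)
  bg_ev <- lapply(cohort$background_cases$reactions, events_of)
  labels <- sort(unique(c(unlist(drug_ev), unlist(bg_ev))))
  if (length(labels) == 0) {
    warning("empty cohort or no events observed; no contingency tables",
            call. = FALSE)
    return(tibble(event_label = character(0), level = character(0),
                  a = integer(0), b = integer(0), c = integer(0),
                  d = integer(0), n_total = integer(0)))
  }
  a <- as.integer(table(factor(unlist(drug_ev), levels = labels)))
  cc <- as.integer(table(factor(unlist(bg_ev), levels = labels)))
  drug_margin <- if (counting_unit == "reports") nrow(cohort$drug_cases)
                 else length(unlist(drug_ev))
  bg_margin <- if (counting_unit == "reports") nrow(cohort$background_cases)
               else length(unlist(bg_ev))
  out <- tibble(
    event_label = labels, level = level,
    a = a, b = drug_margin - a, c = cc, d = bg_margin - cc,
    n_total = drug_margin + bg_margin)
  arrange(out, desc(.data$a), .data$event_label)
}

#' Apply the minimum-report-count inclusion filter
#'
#' Retains tables with `a > min_a`; the conventional filter keeps only events
#' with more than 3 target-drug reports (`a >= 4`).
#'
#' @param tables tibble from [count_tables()].
#' @param min_a strict lower bound on `a` (default 3).
#' @return The filtered tibble.
#' @export
filter_min_count <- function(tables, min_a = 3) {
  out <- filter(tables, .data$a > min_a)
  fs_log("filter_min_count: retained ", nrow(out), " of ", nrow(tables),
         " table(s) with a > ", min_a)
  out
}
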