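# Case-level deduplication and primary-suspect cohort construction.
#
# FAERS cases accumulate follow-up versions under one CASEID; the FDA-
# recommended rule keeps, per CASEID, the version with the most recent FDA
# receipt date, breaking date ties by the numerically highest PRIMARYID.

#' Deduplicate safety-report versions to one report per CASEID
#'
#' @param cases a `faers_cases` tibble (see [assemble_cases()]).
#' @return A `faers_dedup` list: `retained` (`faers_cases`, one row per
#'   CASEID, ordered by CASEID), `n_input`, `n_duplicates_removed`.
#' @details The retained set is invariant under permutation of the input, and
#'   deduplication is idempotent. A PRIMARYID that is not a digit string is
#'   treated as corrupt input and raises an error.
#' @export
deduplicate <- function(cases) {
  stopifnot(inherits(cases, "faers_cases"))
  bad <- !grepl("^[0-9]+$", cases$primaryid)
  if (any(bad)) {
    stop("PRIMARYID not parseable as an integer: ",
         paste(head(unique(cases$primaryid[bad]), 5), collapse = ", "),
         call. = FALSE)
  }
  pid_num <- as.numeric(cases$primaryid)
  fd <- ifelse(is.na(cases$fda_dt), -Inf, cases$fda_dt)
  ord <- order(cases$caseid, -fd, -pid_num)
  keep <- ord[!duplicated(cases$caseid[ord])]
  retained <- cases[keep[order(as.numeric(cases$caseid[keep]))], ]
  res <- structure(
    list(retained = retained,
         n_input = nrow(cases),
         n_duplicates_removed = nrow(cases) - nrow(retained)),
    class = "faers_dedup")
  fs_log("deduplicate: ", res$n_input, " report version(s) -> ",
         nrow(retained), " unique case(s) (",
         res$n_duplicates_removed, " duplicate(s) removed)")
  res
}

#' @export
print.faers_dedup <- function(x, ...) {
  cat("FAERS deduplication result\n",
      "  input report versions: ", x$n_input, "\n",
      "  duplicates removed:    ", x$n_duplicates_removed, "\n",
      "  unique cases retained: ", nrow(x$retained), "\n", sep = "")
  invisible(x)
}

#' Specify how the target drug is matched in free-text drug fields
#'
#' FAERS drug names are free text; matching is case-insensitive after trimming
#' and whitespace collapsing, against both the verbatim `drugname` and the
#' `prod_ai` active-ingredient field.
#'
#' @param name target drug name, e.g. `"potassium citrate"`.
#' @param match `"substring"` (default) or `"exact"`.
#' @param synonyms optional character vector of additional names to match.
#' @return A `drug_query` object.
#' @export
drug_query <- function(name, match = c("substring", "exact"),
                       synonyms = character(0)) {
  match <- match.arg(match)
  stopifnot(is.character(name), length(name) == 1, nzchar(name))
  structure(list(name = name, match = match, synonyms = synonyms),
            class = "drug_query")
}

# vectorized: does each element of x match the query?
matches_drug <- function(x, query) {
  nx <- normalize_name(x)
  targets <- normalize_name(c(query$name, query$synonyms))
  hit <- rep(FALSE, length(nx))
  for (t in targets) {
    hit <- hit | if (query$match == "substring") {
      grepl(t, nx, fixed = TRUE)
    } else {
      nx == t
    }
  }
  hit & nzchar(nx)
}

#' Split deduplicated cases into target-drug cohort and background
#'
#' A case enters `drug_cases` when at least one of its drug rows matches the
#' query with role code `PS` (primary suspect); all other retained cases form
#' the background. Indication PTs recorded for the matching target-drug rows
#' themselves (joined on drug sequence number) are collected as the
#' indication-linked exclusion set used by [apply_pt_exclusion()].
#'
#' @param dedup a `faers_dedup` result from [deduplicate()].
#' @param query a [drug_query()].
#' @return A `faers_cohort` list: `drug_cases`, `background_cases` (both
#'   `faers_cases`), `excluded_pts` (character), `query`.
#' @export
build_cohort <- function(dedup, query) {
  stopifnot(inherits(dedup, "faers_dedup"), inherits(query, "drug_query"))
  retained <- dedup$retained
  target_rows <- lapply(retained$drugs, function(d) {
    d$role_cod == "PS" & (matches_drug(d$drugname, query) |
                          matches_drug(d$prod_ai, query))
  })
  is_target <- vapply(target_rows, any, logical(1))
  drug_cases <- retained[is_target, ]
  background_cases <- retained[!is_target, ]
  if (nrow(drug_cases) == 0) {
    warning("no case matches the drug query with role PS; ",
            "downstream analysis will emit no signals", call. = FALSE)
  }

  # indication PTs of the target drug's own rows, across drug cases
  excluded_pts <- character(0)
  hit_rows <- target_rows[is_target]
  for (i in seq_len(nrow(drug_cases))) {
    seqs <- drug_cases$drugs[[i]]$drug_seq[hit_rows[[i]]]
    indi <- drug_cases$indications[[i]]
    excluded_pts <- c(excluded_pts, indi$pt[indi$drug_seq %in% seqs])
  }
  excluded_pts <- sort(unique(excluded_pts))
  fs_log("build_cohort: ", nrow(drug_cases), " target-drug case(s), ",
         nrow(background_cases), " background case(s), ",
         length(excluded_pts), " indication-linked PT(s)")
  structure(
    list(drug_cases = drug_cases, background_cases = background_cases,
         excluded_pts = excluded_pts, query = query),
    class = "faers_cohort")
}

#' @export
print.faers_cohort <- function(x, ...) {
  cat("FAERS cohort for drug query '", x$query$name, "' (", x$query$match,
      ")\n", "  target-drug cases: ", nrow(x$drug_cases), "\n",
      "  background cases:  ", nrow(x$background_cases), "\n",
      "  indication-linked PTs: ",
      if (length(x$excluded_pts)) paste(x$excluded_pts, collapse = ", ")
      else "(none)", "\n", sep = "")
  invisible(x)
}

#' Remove indication-linked PTs from the target cohort's reactions
#'
#' Reduces confounding by indication: reaction PTs that match the cohort's
#' exclusion set (or extra user-supplied PTs) are removed, case-insensitively,
#' from the target cases' reaction sets. Background cases are untouched, and
#' cases whose reaction set becomes empty stay in the cohort denominator
#' (events are removed, not reports).
#'
#' @param cohort a `faers_cohort` from [build_cohort()].
#' @param extra_pts additional PTs to exclude.
#' @param disable if `TRUE`, no exclusion is applied.
#' @return The cohort with filtered reactions and fields `excluded_applied`
#'   and `n_reactions_removed` added.
#' @export
apply_pt_exclusion <- function(cohort, extra_pts = character(0),
                               disable = FALSE) {
  stopifnot(inherits(cohort, "faers_cohort"))
  excl <- if (disable) character(0) else
    sort(unique(c(cohort$excluded_pts, extra_pts)))
  if (length(excl) > 0) {
    lex <- tolower(excl)
    removed <- character(0)
    cohort$drug_cases$reactions <- lapply(
      cohort$drug_cases$reactions,
      function(r) {
        drop <- tolower(r) %in% lex
        removed <<- c(removed, r[drop])
        r[!drop]
      })
    counts <- table(removed)
    for (pt in names(counts)) {
      fs_log("apply_pt_exclusion: removed PT '", pt, "' from ",
             counts[[pt]], " target case(s)")
    }
    cohort$n_reactions_removed <- length(removed)
  } else {
    cohort$n_reactions_removed <- 0L
  }
  cohort$excluded_applied <- excl
  cohort
}
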