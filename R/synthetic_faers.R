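# Synthetic FAERS-shaped data with known ground truth. Each simulated case
# draws k reaction PTs (zero-truncated Poisson, k >= 1) without replacement
# from a PT catalog with probabilities proportional to the background
# frequency, multiplied by an injected relative reporting rate when the case
# has the target drug as primary suspect. Duplicate report versions share the
# CASEID with a lower PRIMARYID and a strictly earlier FDA_DT and identical
# content, so deduplication correctness is checkable exactly.

BACKGROUND_DRUGS <- c(
  "LISINOPRIL", "METFORMIN", "ATORVASTATIN", "AMLODIPINE", "OMEPRAZOLE",
  "LEVOTHYROXINE", "IBUPROFEN", "SERTRALINE", "ALBUTEROL", "WARFARIN",
  "PREDNISONE", "GABAPENTIN")

BACKGROUND_INDICATIONS <- c("Hypertension", "Diabetes mellitus", "Pain")

#' Default synthetic PT catalog
#'
#' Forty PTs across twelve SOCs with background reporting frequencies, shipped
#' as a plain-text fixture. The terms mirror the vocabulary of spontaneous
#' reports on an alkalinizing agent (product-quality complaints, gastro-
#' intestinal symptoms, renal/urinary terms, laboratory investigations) on top
#' of common background reporting noise.
#'
#' @return Tibble with columns `pt`, `soc`, `background_prob`.
#' @export
default_pt_catalog <- function() {
  path <- system.file("extdata", "synthetic_pt_catalog.tsv",
                      package = "faersignal", mustWork = TRUE)
  readr::read_tsv(path, col_types = readr::cols(
    pt = readr::col_character(), soc = readr::col_character(),
    background_prob = readr::col_double()))
}

scenario_error <- function(field, msg) {
  stop("invalid scenario field '", field, "': ", msg, call. = FALSE)
}

#' Define a synthetic FAERS scenario
#'
#' The defaults emulate the study conditions of a potassium-citrate FAERS
#' cohort at a tractable background size: about 4% of 10,000 cases carry the
#' target drug as primary suspect (a cohort of roughly 400 reports), a mean of
#' 1.9 reaction PTs per report, a 14% duplicate-version rate, and per-field
#' missingness matching typical demographic completeness (age 25%, sex 12%,
#' weight 90%, country 5%). Injected relative reporting rates of 50/20/5/2
#' span strong product-quality signals down to a weak clinical signal.
#'
#' @param n_cases number of unique cases to simulate.
#' @param target_drug_fraction probability a case has the target drug as
#'   primary suspect.
#' @param pt_catalog tibble with `pt`, `soc`, `background_prob` (relative
#'   weights; they need not sum to 1).
#' @param injected_signals named numeric vector: PT name -> relative
#'   reporting rate (>= 0) applied in target-drug cases.
#' @param events_per_case_mean mean of the zero-truncated Poisson event count
#'   per case (>= 1).
#' @param duplicate_rate probability a case emits one extra earlier report
#'   version.
#' @param missingness named list of probabilities for `age`, `sex`, `weight`,
#'   `country`.
#' @param indication_pts PTs written as INDI rows for target-drug cases.
#' @param indication_rate probability a target-drug case carries an
#'   indication row.
#' @param target_drug drug name written in target cases' DRUG rows.
#' @param seed integer seed making [generate_faers()] reproducible.
#' @return A validated `faers_scenario` object.
#' @export
faers_scenario <- function(n_cases = 10000,
                           target_drug_fraction = 0.04,
                           pt_catalog = default_pt_catalog(),
                           injected_signals = c(
                             "Product residue present" = 50,
                             "Product solubility abnormal" = 20,
                             "Drug ineffective" = 5,
                             "Rash" = 2),
                           events_per_case_mean = 1.9,
                           duplicate_rate = 0.14,
                           missingness = list(age = 0.25, sex = 0.12,
                                              weight = 0.90, country = 0.05),
                           indication_pts = "Nephrolithiasis",
                           indication_rate = 0.6,
                           target_drug = "POTASSIUM CITRATE",
                           seed = 1L) {
  if (!is.numeric(n_cases) || n_cases < 1) {
    scenario_error("n_cases", "must be a positive count")
  }
  prob_fields <- list(target_drug_fraction = target_drug_fraction,
                      duplicate_rate = duplicate_rate,
                      indication_rate = indication_rate)
  for (f in names(prob_fields)) {
    v <- prob_fields[[f]]
    if (!is.numeric(v) || length(v) != 1 || v < 0 || v > 1) {
      scenario_error(f, "must be a probability in [0, 1]")
    }
  }
  need <- c("pt", "soc", "background_prob")
  if (!all(need %in% names(pt_catalog))) {
    scenario_error("pt_catalog", paste("must have columns",
                                       paste(need, collapse = ", ")))
  }
  if (anyDuplicated(pt_catalog$pt)) {
    scenario_error("pt_catalog", "PTs must be unique")
  }
  if (any(pt_catalog$background_prob < 0 | pt_catalog$background_prob > 1)) {
    scenario_error("pt_catalog", "background_prob must lie in [0, 1]")
  }
  if (length(injected_signals) > 0) {
    if (is.null(names(injected_signals)) || any(!nzchar(names(injected_signals)))) {
      scenario_error("injected_signals", "must be a named numeric vector")
    }
    if (any(injected_signals < 0)) {
      scenario_error("injected_signals", "relative rates must be >= 0")
    }
    missing_pts <- setdiff(names(injected_signals), pt_catalog$pt)
    if (length(missing_pts) > 0) {
      scenario_error("injected_signals", paste("PT(s) not in catalog:",
                                               paste(missing_pts, collapse = ", ")))
    }
  }
  if (!is.numeric(events_per_case_mean) || events_per_case_mean < 1) {
    scenario_error("events_per_case_mean", "must be >= 1")
  }
  for (f in c("age", "sex", "weight", "country")) {
    v <- missingness[[f]]
    if (is.null(v) || !is.numeric(v) || v < 0 || v > 1) {
      scenario_error("missingness", paste0("$", f,
                                           " must be a probability in [0, 1]"))
    }
  }
  structure(
    list(n_cases = as.integer(n_cases),
         target_drug_fraction = target_drug_fraction,
         pt_catalog = as_tibble(pt_catalog),
         injected_signals = injected_signals,
         events_per_case_mean = events_per_case_mean,
         duplicate_rate = duplicate_rate,
         missingness = missingness,
         indication_pts = indication_pts,
         indication_rate = indication_rate,
         target_drug = target_drug,
         seed = as.integer(seed)),
    class = "faers_scenario")
}

# zero-truncated Poisson: solve the rate from the target mean, then sample by
# inverse CDF conditioned on k >= 1
ztpois_lambda <- function(mean) {
  if (mean <= 1 + 1e-12) return(0)
  uniroot(function(l) l / (1 - exp(-l)) - mean,
          lower = 1e-9, upper = 2 * mean + 5)$root
}

rztpois <- function(n, lambda) {
  if (lambda <= 0) return(rep(1L, n))
  u <- runif(n, dpois(0, lambda), 1)
  pmax(1L, qpois(u, lambda))
}

dztpois <- function(k, lambda) {
  if (lambda <= 0) return(as.numeric(k == 1))
  dpois(k, lambda) / (1 - exp(-lambda))
}

# per-arm sampling weights over the catalog
arm_weights <- function(scenario, target) {
  w <- scenario$pt_catalog$background_prob
  names(w) <- scenario$pt_catalog$pt
  if (target && length(scenario$injected_signals) > 0) {
    w[names(scenario$injected_signals)] <-
      w[names(scenario$injected_signals)] * scenario$injected_signals
  }
  w
}

fmt_date <- function(d) format(d, "%Y%m%d")

#' Generate a synthetic FAERS-like record set with ground truth
#'
#' Reproducible given the scenario seed. Target-drug cases carry the target
#' drug as primary suspect (plus occasional concomitants); reaction PTs are
#' drawn from the catalog with the injected relative rates applied in target
#' cases; a fraction of cases emits an additional earlier report version with
#' identical content.
#'
#' @param scenario a [faers_scenario()].
#' @return A `faers_sim` list with `raw` (a `faers_raw` record set, all
#'   character columns, writable by [write_quarter()]) and `truth`: a
#'   `catalog` tibble with per-PT expected inclusion probabilities and
#'   expected contingency cells (see [expected_contingency()]), a
#'   `duplicate_map` tibble (`caseid`, `primaryid_retained`,
#'   `primaryid_duplicate`), a per-case `assignment` tibble (`caseid`,
#'   `primaryid`, `target`) and `n_target`.
#' @export
generate_faers <- function(scenario) {
  stopifnot(inherits(scenario, "faers_scenario"))
  withr::with_seed(scenario$seed, generate_faers_impl(scenario))
}

generate_faers_impl <- function(scenario) {
  n <- scenario$n_cases
  cat_pt <- scenario$pt_catalog$pt
  is_target <- runif(n) < scenario$target_drug_fraction

  caseid <- as.character(30000000 + seq_len(n))
  primaryid <- paste0(caseid, "2")
  date0 <- as.Date("2014-01-01")
  fda_date <- date0 + sample.int(4099, n, replace = TRUE)

  # demographics with per-field missingness
  age <- pmin(pmax(round(rnorm(n, 55, 18)), 1), 95)
  age_chr <- as.character(age)
  age_cod <- rep("YR", n)
  drop <- runif(n) < scenario$missingness$age
  age_chr[drop] <- ""
  age_cod[drop] <- ""

  sex <- sample(c("M", "F"), n, replace = TRUE, prob = c(0.52, 0.48))
  sex[runif(n) < scenario$missingness$sex] <- ""

  wt_kg <- round(pmax(rnorm(n, 80, 15), 35), 1)
  use_lbs <- runif(n) < 0.1
  wt_chr <- ifelse(use_lbs, as.character(round(wt_kg / 0.453592, 1)),
                   as.character(wt_kg))
  wt_cod <- ifelse(use_lbs, "LBS", "KG")
  drop <- runif(n) < scenario$missingness$weight
  wt_chr[drop] <- ""
  wt_cod[drop] <- ""

  country <- sample(c("US", "CA", "JP", "IN", "GB"), n, replace = TRUE,
                    prob = c(0.90, 0.03, 0.03, 0.02, 0.02))
  country[runif(n) < scenario$missingness$country] <- ""

  occp <- sample(c("MD", "OT", "RN", "CN"), n, replace = TRUE,
                 prob = c(0.73, 0.14, 0.065, 0.065))

  demo <- tibble(
    primaryid = primaryid, caseid = caseid, fda_dt = fmt_date(fda_date),
    age = age_chr, age_cod = age_cod, sex = sex, wt = wt_chr, wt_cod = wt_cod,
    occp_cod = occp, occr_country = country)

  # DRUG rows: primary suspect plus occasional concomitant
  bg_drug <- sample(BACKGROUND_DRUGS, n, replace = TRUE)
  ps_name <- ifelse(is_target, scenario$target_drug, bg_drug)
  extra <- runif(n) < 0.4
  extra_name <- sample(BACKGROUND_DRUGS, n, replace = TRUE)
  drug <- bind_rows(
    tibble(primaryid = primaryid, caseid = caseid, drug_seq = "1",
           role_cod = "PS", drugname = ps_name, prod_ai = ps_name),
    tibble(primaryid = primaryid[extra], caseid = caseid[extra],
           drug_seq = "2", role_cod = "C", drugname = extra_name[extra],
           prod_ai = extra_name[extra]))

  # reaction PTs: k ~ ZT-Poisson, weighted sampling without replacement
  lambda <- ztpois_lambda(scenario$events_per_case_mean)
  k <- pmin(rztpois(n, lambda), length(cat_pt))
  w_target <- arm_weights(scenario, TRUE)
  w_bg <- arm_weights(scenario, FALSE)
  pts_per_case <- vector("list", n)
  for (i in seq_len(n)) {
    w <- if (is_target[i]) w_target else w_bg
    pts_per_case[[i]] <- sample(cat_pt, k[i], replace = FALSE, prob = w)
  }
  reac <- tibble(
    primaryid = rep(primaryid, lengths(pts_per_case)),
    caseid = rep(caseid, lengths(pts_per_case)),
    pt = unlist(pts_per_case))

  # OUTC: about a quarter of reports carry outcome codes
  has_outc <- runif(n) < 0.25
  n_codes <- 1 + rbinom(n, 1, 0.2)
  outc_list <- lapply(which(has_outc), function(i) {
    sample(OUTCOME_CODES, n_codes[i], replace = FALSE,
           prob = c(0.12, 0.08, 0.30, 0.08, 0.04, 0.03, 0.35))
  })
  outc_idx <- rep(which(has_outc), lengths(outc_list))
  outc <- tibble(primaryid = primaryid[outc_idx], caseid = caseid[outc_idx],
                 outc_cod = unlist(outc_list, use.names = FALSE) %||% character(0))

  # INDI: target cases carry the target indication; background cases a
  # background indication, both attached to the primary-suspect drug row
  indi_target <- is_target & runif(n) < scenario$indication_rate
  indi_bg <- !is_target & runif(n) < 0.5
  indi <- bind_rows(
    tibble(primaryid = primaryid[indi_target], caseid = caseid[indi_target],
           indi_drug_seq = "1",
           indi_pt = sample(scenario$indication_pts, sum(indi_target),
                            replace = TRUE)),
    tibble(primaryid = primaryid[indi_bg], caseid = caseid[indi_bg],
           indi_drug_seq = "1",
           indi_pt = sample(BACKGROUND_INDICATIONS, sum(indi_bg),
                            replace = TRUE)))

  has_ther <- runif(n) < 0.6
  ther <- tibble(
    primaryid = primaryid[has_ther], caseid = caseid[has_ther],
    dsg_drug_seq = "1",
    start_dt = fmt_date(fda_date[has_ther] - sample(10:300, sum(has_ther),
                                                    replace = TRUE)),
    end_dt = "")

  # duplicate earlier versions: identical content, lower PRIMARYID, earlier date
  dup <- runif(n) < scenario$duplicate_rate
  dup_pid <- paste0(caseid[dup], "1")
  dup_map <- tibble(caseid = caseid[dup],
                    primaryid_retained = primaryid[dup],
                    primaryid_duplicate = dup_pid)
  add_dups <- function(df, dup_dates = NULL) {
    rows <- df[df$primaryid %in% primaryid[dup], ]
    if (nrow(rows) == 0) return(df)
    rows$primaryid <- paste0(rows$caseid, "1")
    if (!is.null(dup_dates) && "fda_dt" %in% names(rows)) {
      rows$fda_dt <- dup_dates[match(rows$caseid, caseid[dup])]
    }
    out <- bind_rows(df, rows)
    out[order(as.numeric(out$primaryid)), ]
  }
  dup_dates <- fmt_date(fda_date[dup] - sample(30:400, sum(dup), replace = TRUE))
  demo <- add_dups(demo, dup_dates)
  drug <- add_dups(drug)
  reac <- add_dups(reac)
  outc <- add_dups(outc)
  indi <- add_dups(indi)
  ther <- add_dups(ther)

  truth_catalog <- expected_catalog(scenario)
  structure(
    list(raw = new_faers_raw(demo, drug, reac, outc, indi, ther,
                             source_quarter = "2014Q1"),
         truth = list(catalog = truth_catalog,
                      duplicate_map = dup_map,
                      assignment = tibble(caseid = caseid,
                                          primaryid = primaryid,
                                          target = is_target),
                      n_target = sum(is_target))),
    class = "faers_sim")
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# P(PT included in one case's event set): expectation over the event-count
# distribution of 1 - (1 - p)^k, with p the PT's renormalized weight. This is
# the independent-draw approximation to weighted sampling without replacement;
# it is accurate for the small per-term weights the generator uses.
inclusion_prob <- function(p, lambda, kmax) {
  k <- seq_len(kmax)
  pk <- dztpois(k, lambda)
  pk <- pk / sum(pk)
  sum(pk * (1 - (1 - p)^k))
}

expected_catalog <- function(scenario) {
  cat_tbl <- scenario$pt_catalog
  w_t <- arm_weights(scenario, TRUE)
  w_b <- arm_weights(scenario, FALSE)
  lambda <- ztpois_lambda(scenario$events_per_case_mean)
  kmax <- min(nrow(cat_tbl), max(10, qpois(1 - 1e-12, lambda) + 1))
  p_t <- unname(vapply(cat_tbl$pt, function(pt)
    inclusion_prob(w_t[[pt]] / sum(w_t), lambda, kmax), numeric(1)))
  p_b <- unname(vapply(cat_tbl$pt, function(pt)
    inclusion_prob(w_b[[pt]] / sum(w_b), lambda, kmax), numeric(1)))
  n_t <- scenario$n_cases * scenario$target_drug_fraction
  n_b <- scenario$n_cases - n_t
  rate <- rep(1, nrow(cat_tbl))
  names(rate) <- cat_tbl$pt
  rate[names(scenario$injected_signals)] <- scenario$injected_signals
  dplyr::mutate(
    cat_tbl,
    injected_rate = unname(rate),
    p_target = unname(p_t), p_background = unname(p_b),
    expected_a = n_t * p_t, expected_b = n_t * (1 - p_t),
    expected_c = n_b * p_b, expected_d = n_b * (1 - p_b),
    expected_ror = (.data$expected_a * .data$expected_d) /
      (.data$expected_b * .data$expected_c))
}

#' Analytic expected contingency table for one PT
#'
#' Real-valued expectation of the 2x2 cells under the generator's reporting
#' model, for use in recovery tests: expected target/background inclusion
#' probabilities times the expected arm sizes.
#'
#' @param scenario a [faers_scenario()].
#' @param pt a PT present in the scenario's catalog.
#' @return One-row tibble with `pt`, `expected_a` .. `expected_d` and
#'   `expected_ror`.
#' @export
expected_contingency <- function(scenario, pt) {
  stopifnot(inherits(scenario, "faers_scenario"))
  if (!pt %in% scenario$pt_catalog$pt) {
    stop("PT not in scenario catalog: ", pt, call. = FALSE)
  }
  cat_tbl <- expected_catalog(scenario)
  cat_tbl[cat_tbl$pt == pt,
          c("pt", "expected_a", "expected_b", "expected_c", "expected_d",
            "expected_ror")]
}

#' Write a synthetic quarter to disk, with its ground truth
#'
#' Generates a scenario and writes the six quarterly table files (readable by
#' [read_quarter()]) plus `ground_truth.tsv` (per-PT expected cells and ROR)
#' and `duplicate_map.tsv`.
#'
#' @param scenario a [faers_scenario()].
#' @param directory output directory.
#' @param quarter quarter label used in file names.
#' @return Invisibly, the `faers_sim` object.
#' @export
simulate_quarter <- function(scenario, directory, quarter = "2014Q1") {
  sim <- generate_faers(scenario)
  sim$raw$source_quarter <- quarter
  write_quarter(sim$raw, directory, quarter = quarter)
  readr::write_tsv(sim$truth$catalog, file.path(directory, "ground_truth.tsv"))
  readr::write_tsv(sim$truth$duplicate_map,
                   file.path(directory, "duplicate_map.tsv"))
  invisible(sim)
}
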