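# Four disproportionality algorithms on 2x2 report counts, with the
# conventional thresholds and the two-method signal rule:
#
#   ROR   = (a d)/(b c), Wald 95% CI on the log scale      signal: lower > 1
#   PRR   = [a/(a+b)] / [c/(c+d)], with uncorrected chi2   signal: PRR >= 2 and chi2 >= 4
#   IC    = log2[ a N / ((a+c)(a+b)) ], CI = IC +/- 2 sqrt(V(IC))   signal: IC025 > 0
#   EBGM  = a N / ((a+c)(a+b)) = 2^IC, approximate 95% CI
#           exp[ ln EBGM +/- 1.96 sqrt(1/a+1/b+1/c+1/d) ]  signal: EBGM05 > 2
#
# EBGM here is the closed observed/expected form (no gamma-Poisson mixture
# shrinkage), so IC = log2(EBGM) holds exactly. V(IC) uses the delta-method
# approximation (1/ln2)^2 (1/a - 1/(a+b) - 1/(a+c) + 1/N).

# Zero-cell handling shared by all four methods: Haldane-Anscombe (+0.5 to all
# four cells) when any cell is zero, flagged `corrected`; or "undefined",
# which flags the table and yields NA statistics.
adjust_cells <- function(tables, zero_cell_policy = c("haldane", "undefined")) {
  zero_cell_policy <- match.arg(zero_cell_policy)
  a <- as.numeric(tables$a); b <- as.numeric(tables$b)
  cc <- as.numeric(tables$c); d <- as.numeric(tables$d)
  zero <- a == 0 | b == 0 | cc == 0 | d == 0
  if (zero_cell_policy == "haldane") {
    corr <- zero
    undef <- rep(FALSE, length(a))
    a[zero] <- a[zero] + 0.5; b[zero] <- b[zero] + 0.5
    cc[zero] <- cc[zero] + 0.5; d[zero] <- d[zero] + 0.5
  } else {
    corr <- rep(FALSE, length(a))
    undef <- zero
  }
  list(a = a, b = b, c = cc, d = d, corrected = corr, undefined = undef)
}

#' Reporting odds ratio with Wald 95% confidence interval
#'
#' @param tables data frame with integer columns `a`, `b`, `c`, `d` (one row
#'   per 2x2 table).
#' @param zero_cell_policy `"haldane"` (default; add 0.5 to every cell of a
#'   table containing a zero, flagged in `corrected`) or `"undefined"`
#'   (statistics of such tables are `NA`, flagged in `undefined`).
#' @return Tibble with `ror`, `ror_low`, `ror_high`, `corrected`, `undefined`.
#' @examples
#' compute_ror(data.frame(a = 20, b = 80, c = 100, d = 9800))
#' @export
compute_ror <- function(tables, zero_cell_policy = "haldane") {
  z <- adjust_cells(tables, zero_cell_policy)
  se <- sqrt(1 / z$a + 1 / z$b + 1 / z$c + 1 / z$d)
  ror <- (z$a * z$d) / (z$b * z$c)
  out <- tibble(ror = ror,
                ror_low = ror * exp(-1.96 * se),
                ror_high = ror * exp(1.96 * se),
                corrected = z$corrected, undefined = z$undefined)
  out[z$undefined, c("ror", "ror_low", "ror_high")] <- NA_real_
  out
}

#' Proportional reporting ratio and uncorrected chi-squared
#'
#' The chi-squared statistic is the plain Pearson form
#' \eqn{(ad-bc)^2 N / [(a+b)(c+d)(a+c)(b+d)]} with no continuity correction.
#'
#' @inheritParams compute_ror
#' @return Tibble with `prr`, `chi2`, `corrected`, `undefined`.
#' @export
compute_prr_chi2 <- function(tables, zero_cell_policy = "haldane") {
  z <- adjust_cells(tables, zero_cell_policy)
  n <- z$a + z$b + z$c + z$d
  prr <- (z$a / (z$a + z$b)) / (z$c / (z$c + z$d))
  chi2 <- ((z$a * z$d - z$b * z$c)^2 * n) /
    ((z$a + z$b) * (z$c + z$d) * (z$a + z$c) * (z$b + z$d))
  out <- tibble(prr = prr, chi2 = chi2,
                corrected = z$corrected, undefined = z$undefined)
  out[z$undefined, c("prr", "chi2")] <- NA_real_
  out
}

#' BCPNN information component with delta-method interval
#'
#' IC is the base-2 log of the observed-to-expected reporting ratio; its lower
#' bound uses the 2-standard-deviation interval \eqn{IC - 2\sqrt{V(IC)}} with
#' the delta-method variance
#' \eqn{V(IC) = (1/\ln 2)^2 (1/a - 1/(a+b) - 1/(a+c) + 1/N)} (clamped at zero
#' for degenerate tables where the approximation turns negative).
#'
#' @inheritParams compute_ror
#' @return Tibble with `ic`, `ic025`, `ic_variance`, `corrected`, `undefined`.
#' @export
compute_bcpnn <- function(tables, zero_cell_policy = "haldane") {
  z <- adjust_cells(tables, zero_cell_policy)
  n <- z$a + z$b + z$c + z$d
  ic <- log2(z$a * n / ((z$a + z$c) * (z$a + z$b)))
  vic <- (1 / log(2))^2 *
    (1 / z$a - 1 / (z$a + z$b) - 1 / (z$a + z$c) + 1 / n)
  vic <- pmax(vic, 0)
  out <- tibble(ic = ic, ic025 = ic - 2 * sqrt(vic), ic_variance = vic,
                corrected = z$corrected, undefined = z$undefined)
  out[z$undefined, c("ic", "ic025", "ic_variance")] <- NA_real_
  out
}

#' Empirical Bayes geometric mean (closed form) with approximate interval
#'
#' The closed observed/expected form \eqn{EBGM = a N / ((a+c)(a+b))}, identical
#' to \eqn{2^{IC}}; no gamma-Poisson mixture shrinkage is applied. The lower
#' bound is \eqn{\exp(\ln EBGM - 1.96\sqrt{1/a + 1/b + 1/c + 1/d})}.
#'
#' @inheritParams compute_ror
#' @return Tibble with `ebgm`, `ebgm05`, `corrected`, `undefined`.
#' @export
compute_ebgm <- function(tables, zero_cell_policy = "haldane") {
  z <- adjust_cells(tables, zero_cell_policy)
  n <- z$a + z$b + z$c + z$d
  ebgm <- z$a * n / ((z$a + z$c) * (z$a + z$b))
  se <- sqrt(1 / z$a + 1 / z$b + 1 / z$c + 1 / z$d)
  out <- tibble(ebgm = ebgm, ebgm05 = exp(log(ebgm) - 1.96 * se),
                corrected = z$corrected, undefined = z$undefined)
  out[z$undefined, c("ebgm", "ebgm05")] <- NA_real_
  out
}

#' Compute all four disproportionality statistics for a set of tables
#'
#' @inheritParams compute_ror
#' @return The input tibble with columns `ror`, `ror_low`, `ror_high`, `prr`,
#'   `chi2`, `ic`, `ic025`, `ic_variance`, `ebgm`, `ebgm05`, `corrected`,
#'   `undefined` appended.
#' @export
compute_signal_stats <- function(tables, zero_cell_policy = "haldane") {
  ror <- compute_ror(tables, zero_cell_policy)
  prr <- compute_prr_chi2(tables, zero_cell_policy)
  bcpnn <- compute_bcpnn(tables, zero_cell_policy)
  ebgm <- compute_ebgm(tables, zero_cell_policy)
  dplyr::bind_cols(
    as_tibble(tables),
    ror[c("ror", "ror_low", "ror_high")],
    prr[c("prr", "chi2")],
    bcpnn[c("ic", "ic025", "ic_variance")],
    ebgm[c("ebgm", "ebgm05")],
    ror[c("corrected", "undefined")])
}

#' One-shot statistics for a single 2x2 table
#'
#' Convenience wrapper for teaching and spot checks: all four statistics on
#' one table given as four counts.
#'
#' @param a,b,c,d the 2x2 cell counts (see [count_tables()]).
#' @inheritParams compute_ror
#' @return A one-row tibble from [compute_signal_stats()] plus the decision
#'   columns of [decide_signal()].
#' @examples
#' stats_2x2(20, 80, 100, 9800)
#' @export
stats_2x2 <- function(a, b, c, d, zero_cell_policy = "haldane") {
  decide_signal(compute_signal_stats(
    tibble(event_label = "table", level = "PT",
           a = a, b = b, c = c, d = d, n_total = a + b + c + d),
    zero_cell_policy))
}

#' Evaluate per-method thresholds and the two-method signal rule
#'
#' A drug-event pair is a signal when it meets the threshold in at least two
#' of the four methods: `ror_low > 1`; `prr >= 2` together with `chi2 >= 4`;
#' `ic025 > 0`; `ebgm05 > 2`. Methods whose statistics are undefined (`NA`)
#' count as not met.
#'
#' @param stats data frame containing at least `ror_low`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (e.g. from [compute_signal_stats()], or threshold
#'   fixtures with just those columns).
#' @return The input with logical columns `ror_met`, `prr_met`, `bcpnn_met`,
#'   `mgps_met`, integer `n_methods_met` and logical `is_signal` appended.
#' @export
decide_signal <- function(stats) {
  need <- c("ror_low", "prr", "chi2", "ic025", "ebgm05")
  if (!all(need %in% names(stats))) {
    stop("decide_signal requires column(s): ",
         paste(setdiff(need, names(stats)), collapse = ", "), call. = FALSE)
  }
  met <- function(x) !is.na(x) & x
  out <- as_tibble(stats)
  out$ror_met <- met(out$ror_low > 1)
  out$prr_met <- met(out$prr >= 2) & met(out$chi2 >= 4)
  out$bcpnn_met <- met(out$ic025 > 0)
  out$mgps_met <- met(out$ebgm05 > 2)
  out$n_methods_met <- out$ror_met + out$prr_met + out$bcpnn_met + out$mgps_met
  out$is_signal <- out$n_methods_met >= 2
  out
}

#' Run the full disproportionality analysis for one level
#'
#' Computes statistics and signal decisions for every table and ranks the
#' result by decreasing ROR (ties: decreasing `a`, then event label).
#'
#' @param tables tibble from [count_tables()], normally after
#'   [filter_min_count()].
#' @inheritParams compute_ror
#' @return Ranked decision tibble (see [decide_signal()]).
#' @export
run_level <- function(tables, zero_cell_policy = "haldane") {
  if (nrow(tables) == 0) {
    return(decide_signal(compute_signal_stats(tables, zero_cell_policy)))
  }
  out <- decide_signal(compute_signal_stats(tables, zero_cell_policy))
  arrange(out, desc(.data$ror), desc(.data$a), .data$event_label)
}
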