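# MedDRA PT -> primary SOC mapping. MedDRA itself is licensed and cannot be
# redistributed; the package ships only a ~40-term toy dictionary
# (inst/extdata/meddra_toy.tsv) for tests and the synthetic generator. Real
# analyses require a user-supplied two-column mapping file.

#' Load a PT-to-SOC dictionary from a tab-delimited file
#'
#' The file has two columns, PT and SOC (a `pt`/`soc` header line is optional).
#' Lookups are case-insensitive on PT; duplicate PT rows are merged when they
#' agree on the SOC and are an error when they conflict, since a PT must map
#' to exactly one primary SOC.
#'
#' @param path path to the dictionary file (UTF-8 TSV).
#' @param version_label label stored with the dictionary (defaults to the
#'   file name).
#' @return A `pt_soc_dict` object.
#' @export
load_pt_soc <- function(path, version_label = basename(path)) {
  if (!file.exists(path)) {
    stop("dictionary file not found: ", path, call. = FALSE)
  }
  lines <- readLines(path, warn = FALSE, encoding = "UTF-8")
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("dictionary file is empty: ", path, call. = FALSE)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 2)) {
    stop("dictionary rows must have two tab-separated columns (pt, soc): ",
         path, call. = FALSE)
  }
  pt <- trimws(vapply(parts, `[[`, "", 1))
  soc <- trimws(vapply(parts, `[[`, "", 2))
  if (tolower(pt[1]) == "pt" && tolower(soc[1]) == "soc") {
    pt <- pt[-1]
    soc <- soc[-1]
  }
  key <- tolower(pt)
  n_soc <- tapply(soc, key, function(s) length(unique(s)))
  conflicts <- names(n_soc)[n_soc > 1]
  if (length(conflicts) > 0) {
    stop("conflicting SOC assignments for PT(s): ",
         paste(conflicts, collapse = ", "), call. = FALSE)
  }
  keep <- !duplicated(key)
  structure(
    list(entries = stats::setNames(soc[keep], key[keep]),
         display_pt = stats::setNames(pt[keep], key[keep]),
         version_label = version_label),
    class = "pt_soc_dict")
}

#' @export
print.pt_soc_dict <- function(x, ...) {
  cat("PT -> SOC dictionary '", x$version_label, "': ",
      length(x$entries), " PT(s), ", length(unique(x$entries)),
      " SOC(s)\n", sep = "")
  invisible(x)
}

#' Look up the primary SOC of one or more PTs
#'
#' @param pt character vector of Preferred Terms.
#' @param dict a `pt_soc_dict` from [load_pt_soc()].
#' @param unknown_policy how to handle PTs absent from the dictionary:
#'   `"unmapped"` (default) assigns the sentinel SOC `"UNMAPPED"`;
#'   `"drop"` returns `NA` so the PT is excluded from SOC-level counting,
#'   with a logged count.
#' @return Character vector of SOC names (with `NA` for dropped PTs).
#' @export
soc_of <- function(pt, dict, unknown_policy = c("unmapped", "drop")) {
  stopifnot(inherits(dict, "pt_soc_dict"))
  unknown_policy <- match.arg(unknown_policy)
  out <- unname(dict$entries[tolower(trimws(pt))])
  miss <- is.na(out)
  if (any(miss)) {
    if (unknown_policy == "unmapped") {
      out[miss] <- "UNMAPPED"
    } else {
      fs_log("soc_of: dropped ", sum(miss), " PT(s) absent from dictionary")
    }
  }
  out
}
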