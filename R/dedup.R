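#' Deduplicate follow-up reports into cases
#'
#' A spontaneous-reporting case (`caseid`) accrues follow-up reports
#' (`primaryid`) over time; analyses keep one report per case. The rule,
#' following FDA guidance for FAERS: keep the report with the latest receipt
#' date `fda_dt`; when receipt dates tie, keep the larger `primaryid`. A
#' second pass removes any remaining exact `primaryid` duplicates, keeping
#' the first occurrence.
#'
#' Records whose `fda_dt` does not parse as an 8-digit `YYYYMMDD` date sort
#' before all parseable dates, so a dated follow-up always supersedes an
#' undated one. `primaryid` is compared numerically when every id parses as
#' a number (modern FAERS ids), and lexicographically otherwise (legacy
#' ISRs).
#'
#' The operation is idempotent, never invents records, and leaves `caseid`
#' unique in its output.
#'
#' @param cases Tibble with columns `primaryid`, `caseid`, `fda_dt` (other
#'   columns pass through untouched).
#' @return The kept rows, with a dedup report in attribute `dedup_report`
#'   (retrieve with [dedup_report()]).
#' @examples
#' x <- tibble::tibble(
#'   primaryid = c("1001", "1002", "1003", "1004"),
#'   caseid    = c("500", "500", "501", "501"),
#'   fda_dt    = c("20200101", "20200315", "20210601", "20210601")
#' )
#' dedup_cases(x) # keeps 1002 (later date) and 1004 (tie -> larger id)
#' @export
dedup_cases <- function(cases) {
  stopifnot(all(c("primaryid", "caseid") %in% names(cases)))
  n_input <- nrow(cases)
  if (!"fda_dt" %in% names(cases)) cases$fda_dt <- NA_character_

  date_key <- parse_fda_dt(cases$fda_dt)
  date_key[is.na(date_key)] <- -Inf
  pid_key <- primaryid_key(cases$primaryid)

  ord <- order(date_key, pid_key, decreasing = TRUE)
  kept <- cases[ord, , drop = FALSE]
  kept <- kept[!duplicated(kept$caseid), , drop = FALSE]
  n_after_case <- nrow(kept)

  # auxiliary pass: exact primaryid duplicates, keep first occurrence
  kept <- kept[!duplicated(kept$primaryid), , drop = FALSE]
  kept <- kept[order(match(kept$primaryid, cases$primaryid)), , drop = FALSE]

  attr(kept, "dedup_report") <- tibble(
    n_input = n_input,
    n_kept = nrow(kept),
    n_dropped_followup = n_input - n_after_case,
    n_dropped_primaryid = n_after_case - nrow(kept)
  )
  kept
}

#' Retrieve the dedup report attached by [dedup_cases()]
#'
#' @param x Output of [dedup_cases()].
#' @return One-row tibble with input/kept/dropped counts.
#' @export
dedup_report <- function(x) {
  rep <- attr(x, "dedup_report")
  if (is.null(rep)) abort("No dedup report attached; was this produced by dedup_cases()?")
  rep
}
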