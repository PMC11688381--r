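#' @name faers_io
#' @title Reading and writing FAERS-style quarterly ASCII tables
#'
#' @description
#' FAERS quarterly data packages distribute each table (DEMO, DRUG, REAC,
#' OUTC, THER, INDI, RPSR) as a "$"-delimited text file with a header line
#' and no quoting. `faers_read_table()` and `faers_write_table()` implement
#' that dialect; `assemble_cases()` joins the per-kind tables into typed
#' case, drug-mention and reaction records keyed by report (`primaryid`).
#'
#' Legacy packages (pre-2012Q4) name the report and case identifiers
#' `ISR`/`CASE` and the sex column `GNDR_COD`; the reader maps these onto the
#' modern schema through a built-in alias table so both eras parse
#' identically.
NULL

FAERS_TABLE_KINDS <- c("DEMO", "DRUG", "REAC", "OUTC", "THER", "INDI", "RPSR")

# legacy -> modern column aliases
FAERS_COLUMN_ALIASES <- c(
  isr = "primaryid",
  "case" = "caseid",
  gndr_cod = "sex"
)

check_table_kind <- function(kind) {
  kind <- toupper(kind)
  if (!kind %in% FAERS_TABLE_KINDS) {
    abort(paste0("Unknown FAERS table kind '", kind, "'; expected one of ",
                 paste(FAERS_TABLE_KINDS, collapse = ", "), "."))
  }
  kind
}

#' Read one FAERS ASCII table
#'
#' Fields are mapped by header name (column order is irrelevant), every
#' field is read as character, and empty fields become `NA`. Unknown columns
#' are preserved as-is. Lines whose field count disagrees with the header
#' are a parse error in strict mode, or skipped with a warning otherwise.
#'
#' @param path Path to a "$"-delimited text file with a header line.
#' @param kind Table kind, one of DEMO, DRUG, REAC, OUTC, THER, INDI, RPSR.
#' @param strict If `TRUE` (default) malformed lines abort with line
#'   numbers; if `FALSE` they are dropped with a warning.
#' @return A tibble of character columns, one row per data line, with the
#'   table kind in attribute `table_kind`.
#' @export
faers_read_table <- function(path, kind, strict = TRUE) {
  kind <- check_table_kind(kind)
  if (!file.exists(path)) abort(paste0("No such file: ", path))
  d <- suppressWarnings(readr::read_delim(
    path,
    delim = "$", quote = "", na = "",
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  probs <- readr::problems(d)
  if (nrow(probs) > 0) {
    bad_lines <- sort(unique(probs$row)) # file lines; line 1 is the header
    msg <- paste0("Malformed line(s) in ", path, " at line(s) ",
                  paste(head(bad_lines, 10), collapse = ", "),
                  if (length(bad_lines) > 10) ", ..." else "", ".")
    if (strict) abort(msg)
    warn(paste(msg, "Rows dropped."))
    d <- d[-(bad_lines - 1L), , drop = FALSE]
  }
  names(d) <- tolower(names(d))
  hit <- names(d) %in% names(FAERS_COLUMN_ALIASES)
  names(d)[hit] <- unname(FAERS_COLUMN_ALIASES[names(d)[hit]])
  if (!"primaryid" %in% names(d)) {
    abort(paste0("Schema error in ", path, ": mandatory column 'primaryid' ",
                 "(or legacy 'ISR') is missing."))
  }
  d <- tibble::as_tibble(d)
  attr(d, "table_kind") <- kind
  d
}

#' Write one FAERS ASCII table
#'
#' Inverse of [faers_read_table()]: "$"-delimited, header line, no quoting,
#' `NA` written as the empty field. Because the dialect has no quoting
#' mechanism, any field containing the delimiter is rejected.
#'
#' @param x Tibble of rows to write; all columns are coerced to character.
#' @param path Output file path.
#' @param kind Table kind (validated; recorded for symmetry with the reader).
#' @return `path`, invisibly.
#' @export
faers_write_table <- function(x, path, kind) {
  kind <- check_table_kind(kind)
  x <- dplyr::mutate(x, dplyr::across(dplyr::everything(), as.character))
  has_delim <- vapply(x, function(col) any(grepl("$", col, fixed = TRUE), na.rm = TRUE),
                      logical(1))
  if (any(has_delim)) {
    abort(paste0("Field(s) in column(s) ", paste(names(x)[has_delim], collapse = ", "),
                 " contain the '$' delimiter; the FAERS dialect has no quoting."))
  }
  readr::write_delim(x, path, delim = "$", na = "", quote = "none",
                     escape = "none", eol = "\n", progress = FALSE)
  invisible(path)
}

# Age in years from FAERS age + age_cod unit codes.
age_in_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  unit <- toupper(ifelse(is.na(age_cod) | age_cod == "", "YR", age_cod))
  mult <- c(YR = 1, DEC = 10, MON = 1 / 12, WK = 7 / 365.25,
            DY = 1 / 365.25, HR = 1 / 8766)[unit]
  a * ifelse(is.na(mult), NA_real_, mult)
}

# Age bands used in the descriptive summary.
age_band_of <- function(years) {
  dplyr::case_when(
    is.na(years) ~ "Unknown",
    years < 18 ~ "<18",
    years < 65 ~ "18-64.9",
    years <= 85 ~ "65-85",
    TRUE ~ ">85"
  )
}

normalize_sex <- function(sex) {
  s <- toupper(ifelse(is.na(sex), "", sex))
  dplyr::case_when(
    s %in% c("M", "MALE") ~ "Male",
    s %in% c("F", "FEMALE") ~ "Female",
    TRUE ~ "Unknown"
  )
}

#' Assemble per-kind FAERS tables into typed case records
#'
#' Joins DRUG/REAC/OUTC rows onto DEMO by `primaryid`. Cases lacking any
#' drug or any reaction row are retained but flagged incomplete; rows in
#' non-DEMO tables whose `primaryid` does not appear in DEMO are reported in
#' the unmatched summary, so row counts are conserved
#' (attached + unmatched = input).
#'
#' Demographic fields are normalized on the way in: sex to
#' Male/Female/Unknown, age to the age bands `<18`, `18-64.9`, `65-85`,
#' `>85`, `Unknown`, country from `occr_country` (falling back to
#' `reporter_country`), and the event year from `event_dt`.
#'
#' @param tables Named list of tibbles as returned by [faers_read_table()];
#'   names are table kinds (case-insensitive). `DEMO` is mandatory.
#' @return A list of class `faers_case_set`:
#'   \describe{
#'     \item{cases}{one row per report: `primaryid`, `caseid`, `fda_dt`,
#'       `sex`, `age_band`, `country`, `event_year`, `incomplete`}
#'     \item{drugs}{drug mentions: `primaryid`, `caseid`, `drug_seq`,
#'       `role_cod`, `drugname`, `prod_ai`}
#'     \item{reactions}{reaction mentions: `primaryid`, `caseid`, `pt`}
#'     \item{outcomes}{outcome rows: `primaryid`, `caseid`, `outc_cod`}
#'     \item{unmatched}{per-kind counts of rows with unknown `primaryid`}
#'   }
#' @export
assemble_cases <- function(tables) {
  names(tables) <- toupper(names(tables))
  if (!"DEMO" %in% names(tables)) abort("assemble_cases() requires a DEMO table.")
  demo <- tables$DEMO
  need <- function(d, cols) {
    for (cc in setdiff(cols, names(d))) d[[cc]] <- NA_character_
    d
  }
  demo <- need(demo, c("primaryid", "caseid", "fda_dt", "age", "age_cod",
                       "sex", "occr_country", "reporter_country", "event_dt"))
  cases <- demo %>%
    dplyr::transmute(
      primaryid = as.character(.data$primaryid),
      caseid = as.character(.data$caseid),
      fda_dt = as.character(.data$fda_dt),
      sex = normalize_sex(.data$sex),
      age_band = age_band_of(age_in_years(.data$age, .data$age_cod)),
      country = dplyr::coalesce(.data$occr_country, .data$reporter_country,
                                "Unknown"),
      event_year = suppressWarnings(as.integer(substr(.data$event_dt, 1, 4)))
    )

  known_ids <- cases$primaryid
  split_known <- function(kind, cols) {
    d <- tables[[kind]]
    if (is.null(d)) {
      return(list(rows = tibble(!!!setNames(rep(list(character()), length(cols)), cols)),
                  n_unmatched = 0L, n_input = 0L))
    }
    d <- need(d, cols)
    d <- dplyr::mutate(d, primaryid = as.character(.data$primaryid))
    ok <- d$primaryid %in% known_ids
    list(rows = dplyr::select(d[ok, , drop = FALSE], dplyr::all_of(cols)),
         n_unmatched = sum(!ok), n_input = nrow(d))
  }

  dr <- split_known("DRUG", c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"))
  rx <- split_known("REAC", c("primaryid", "pt"))
  oc <- split_known("OUTC", c("primaryid", "outc_cod"))

  id_map <- dplyr::select(cases, "primaryid", "caseid")
  drugs <- dplyr::left_join(dr$rows, id_map, by = "primaryid")
  reactions <- dplyr::left_join(rx$rows, id_map, by = "primaryid")
  outcomes <- dplyr::left_join(oc$rows, id_map, by = "primaryid")

  cases <- cases %>%
    dplyr::mutate(
      incomplete = !(.data$primaryid %in% drugs$primaryid) |
        !(.data$primaryid %in% reactions$primaryid)
    )

  unmatched <- tibble(
    table_kind = c("DRUG", "REAC", "OUTC"),
    n_input = c(dr$n_input, rx$n_input, oc$n_input),
    n_attached = c(nrow(dr$rows), nrow(rx$rows), nrow(oc$rows)),
    n_unmatched = c(dr$n_unmatched, rx$n_unmatched, oc$n_unmatched)
  )

  structure(
    list(cases = cases, drugs = drugs, reactions = reactions,
         outcomes = outcomes, unmatched = unmatched),
    class = "faers_case_set"
  )
}

#' Read a directory tree of quarterly FAERS packages
#'
#' Each subdirectory of `dir` is treated as one quarter and must contain the
#' per-kind ASCII files named `<KIND>.txt`; all quarters are concatenated
#' before assembly.
#'
#' @param dir Directory containing one subdirectory per quarter.
#' @param strict Passed to [faers_read_table()].
#' @return A `faers_case_set`, see [assemble_cases()].
#' @export
read_faers_package <- function(dir, strict = TRUE) {
  quarters <- list.dirs(dir, recursive = FALSE)
  if (length(quarters) == 0) abort(paste0("No quarterly subdirectories under ", dir))
  tables <- lapply(setNames(nm = FAERS_TABLE_KINDS), function(kind) {
    paths <- file.path(quarters, paste0(kind, ".txt"))
    paths <- paths[file.exists(paths)]
    if (length(paths) == 0) return(NULL)
    dplyr::bind_rows(lapply(paths, faers_read_table, kind = kind, strict = strict))
  })
  assemble_cases(tables[!vapply(tables, is.null, logical(1))])
}
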