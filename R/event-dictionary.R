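#' The coagulopathies preferred-term dictionary
#'
#' The event phenotype under surveillance — impaired blood-clotting
#' regulation — is defined as the 26 MedDRA preferred terms (PTs) grouped
#' under the high-level term "coagulopathies" (MedDRA 27.0, HLT 10064477).
#' Each entry carries the PT name, its numeric MedDRA code, and the number
#' of (case, PT) pairs observed for it in the FAERS 2004Q1-2024Q2 window,
#' which the synthetic generator uses as default sampling weights.
#'
#' A user-supplied dictionary (any tibble with `pt_name` and `pt_code`
#' columns) can replace it throughout the pipeline.
#'
#' @return A tibble with columns `pt_name` (character), `pt_code` (integer)
#'   and `reference_count` (integer), sorted by `reference_count` descending.
#' @examples
#' coagulopathy_pts()
#' @export
coagulopathy_pts <- function() {
  tibble::tribble(
    ~pt_name, ~pt_code, ~reference_count,
    "Coagulopathy", 10009802L, 15057L,
    "Disseminated intravascular coagulation", 10013442L, 12954L,
    "Thrombotic microangiopathy", 10079988L, 8050L,
    "Hypercoagulation", 10020608L, 1771L,
    "Antiphospholipid syndrome", 10002817L, 1395L,
    "Factor VIII inhibition", 10048619L, 1007L,
    "Hypocoagulable state", 10020973L, 861L,
    "Abnormal clotting factor", 10049862L, 198L,
    "Factor V inhibition", 10056335L, 180L,
    "Factor IX inhibition", 10051778L, 127L,
    "Heparin resistance", 10059598L, 93L,
    "Hyperfibrinogenaemia", 10051124L, 61L,
    "Coagulation disorder neonatal", 10009732L, 55L,
    "Hyperfibrinolysis", 10074737L, 52L,
    "Activated protein C resistance", 10067648L, 33L,
    "Von Willebrand's factor inhibition", 10070690L, 30L,
    "Factor XIII inhibition", 10059608L, 27L,
    "Disseminated intravascular coagulation in newborn", 10013443L, 25L,
    "Factor VII inhibition", 10075240L, 16L,
    "Acquired dysfibrinogenaemia", 10051122L, 7L,
    "Lupus anticoagulant hypoprothrombinaemia syndrome", 10085219L, 4L,
    "Hyperprothrombinaemia", 10067920L, 3L,
    "Hyperthrombinaemia", 10058516L, 3L,
    "Factor II inhibition", 10075242L, 2L,
    "Factor X inhibition", 10075241L, 1L,
    "Pseudo-heparin resistance", 10088924L, 1L
  )
}

#' Read a preferred-term dictionary from a delimited text file
#'
#' Expects at least two columns, `pt_name` and `pt_code`; extra columns are
#' kept. Used to swap in a different event definition via configuration.
#'
#' @param path Path to a tab- or comma-delimited text file with a header.
#' @return A tibble with `pt_name` (character) and `pt_code` (integer).
#' @export
read_pt_dictionary <- function(path) {
  d <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  if (!all(c("pt_name", "pt_code") %in% names(d))) {
    abort("PT dictionary must have columns 'pt_name' and 'pt_code'.")
  }
  d <- dplyr::mutate(d,
    pt_name = as.character(.data$pt_name),
    pt_code = as.integer(.data$pt_code)
  )
  if (anyDuplicated(d$pt_code) > 0) abort("Duplicate pt_code in dictionary.")
  tibble::as_tibble(d)
}

#' Flag event cases by matching reaction PTs against a dictionary
#'
#' A case is an event case iff at least one of its reported PTs matches the
#' dictionary. Matching is case-insensitive after whitespace normalization,
#' with a fallback on the numeric PT code (when the reactions carry a
#' `pt_code` column) so that capitalization drift across MedDRA versions
#' cannot silently drop matches. A case may match several dictionary PTs;
#' every (case, matched PT) pair is returned.
#'
#' @param reactions Tibble of reaction mentions with columns `caseid` and
#'   `pt` (verbatim PT text); an optional `pt_code` column enables code
#'   matching.
#' @param dictionary PT dictionary tibble (`pt_name`, `pt_code`); defaults
#'   to [coagulopathy_pts()].
#' @return Tibble with one row per (case, matched PT) pair: `caseid`,
#'   `pt_name` (canonical dictionary spelling), `pt_code`.
#' @examples
#' rx <- tibble::tibble(caseid = c("1", "1", "2"),
#'                      pt = c("COAGULOPATHY", "Pyrexia", "Nausea"))
#' flag_event_cases(rx) # case 1 matched, case 2 not
#' @export
flag_event_cases <- function(reactions, dictionary = coagulopathy_pts()) {
  stopifnot(all(c("caseid", "pt") %in% names(reactions)))
  dict <- dplyr::mutate(dictionary,
    .name_key = clean_string(.data$pt_name),
    pt_code = as.integer(.data$pt_code)
  )
  rx <- dplyr::mutate(reactions, .name_key = clean_string(.data$pt))

  matched <- rx %>%
    dplyr::select("caseid", ".name_key") %>%
    dplyr::inner_join(
      dplyr::select(dict, ".name_key", "pt_name", "pt_code"),
      by = ".name_key"
    ) %>%
    dplyr::select("caseid", "pt_name", "pt_code")

  if ("pt_code" %in% names(reactions)) {
    leftover <- dplyr::anti_join(rx, dict, by = ".name_key") %>%
      dplyr::transmute(.data$caseid, pt_code = as.integer(.data$pt_code)) %>%
      dplyr::inner_join(
        dplyr::select(dict, "pt_name", "pt_code"),
        by = "pt_code"
      ) %>%
      dplyr::select("caseid", "pt_name", "pt_code")
    matched <- dplyr::bind_rows(matched, leftover)
  }

  dplyr::distinct(matched, .data$caseid, .data$pt_name, .data$pt_code)
}

#' Distribution of matched event PTs
#'
#' Counts (case, matched PT) pairs per dictionary PT — a case matching k PTs
#' contributes to k rows, so the counts sum to the number of pairs, not the
#' number of cases. Percentages use the pair total as denominator and are
#' rounded half away from zero to 2 decimals.
#'
#' @param flags Output of [flag_event_cases()].
#' @return Tibble with columns `pt_name`, `pt_code`, `count`, `percent`,
#'   sorted by `count` descending.
#' @export
pt_distribution <- function(flags) {
  if (nrow(flags) == 0) {
    return(tibble(pt_name = character(), pt_code = integer(),
                  count = integer(), percent = numeric()))
  }
  flags %>%
    dplyr::count(.data$pt_name, .data$pt_code, name = "count") %>%
    dplyr::mutate(percent = percent(.data$count, sum(.data$count), digits = 2)) %>%
    dplyr::arrange(dplyr::desc(.data$count), .data$pt_name)
}
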