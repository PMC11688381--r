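#' @name drug_catalog
#' @title Drug-name normalization, role filtering, exclusions and classes
#'
#' @description
#' Verbatim drug names in spontaneous reports mix brand names, salt forms,
#' dosage strings and misspellings. The analysis unit downstream is the
#' canonical ingredient (combination products kept as single combination
#' entities), restricted to primary-suspect (PS) mentions, with
#' anticoagulants/antiplatelets removed before ranking — drugs given to
#' treat or prevent clotting disorders would otherwise dominate a
#' coagulopathy screen through confounding by indication.
NULL

default_form_suffixes <- function() {
  c("TABLET", "TABLETS", "TAB", "TABS", "CAPSULE", "CAPSULES", "CAP", "CAPS",
    "INJECTION", "INJ", "INFUSION", "SOLUTION", "SUSPENSION", "SYRUP",
    "CREAM", "OINTMENT", "GEL", "PATCH", "SPRAY", "DROPS", "VIAL", "VIALS",
    "KIT", "ORAL", "INTRAVENOUS", "IV", "MG", "G", "MCG", "UG", "ML", "IU", "%")
}

default_ambiguous_names <- function() {
  c("UNKNOWN", "UNKNOWN DRUG", "UNSPECIFIED", "UNSPECIFIED INGREDIENT",
    "DRUG", "MULTIPLE DRUGS", "ALL OTHER THERAPEUTIC PRODUCTS")
}

# read a two-column delimited map file (tab or comma) into a named vector
read_name_map <- function(path) {
  delim <- if (grepl("\t", readr::read_lines(path, n_max = 1))) "\t" else ","
  d <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                         trim_ws = TRUE, comment = "#")
  if (ncol(d) < 2) abort(paste0("Expected two columns in ", path))
  setNames(clean_string(d[[2]]), clean_string(d[[1]]))
}

#' Packaged drug-name synonym map
#'
#' Maps cleaned verbatim variants (brand names, salt forms) to canonical
#' ingredients. Editable: ship your own file and load it with
#' [read_name_map()].
#' @return Named character vector (variant -> ingredient), uppercase.
#' @export
default_synonyms <- function() {
  read_name_map(system.file("extdata", "drug_synonyms.txt", package = "pvsignal"))
}

#' Packaged anticoagulant/antiplatelet exclusion list
#'
#' Drugs prescribed to alter coagulation are removed before the top-N
#' ranking: their association with coagulopathy reports reflects indication,
#' not a safety signal. Membership is a packaged, editable config file
#' (heparins, vitamin-K antagonists, direct oral anticoagulants, direct
#' thrombin inhibitors, P2Y12 inhibitors, glycoprotein IIb/IIIa inhibitors,
#' aspirin and other antiplatelets).
#' @return Character vector of canonical ingredient names, uppercase.
#' @export
default_exclusion_list <- function() {
  x <- readr::read_lines(system.file("extdata", "anticoagulant_exclusions.txt",
                                     package = "pvsignal"))
  x <- clean_string(x[!grepl("^\\s*(#|$)", x)])
  unique(x)
}

#' Packaged therapeutic-class (ATC-style) map
#'
#' Maps canonical ingredients to the eight therapeutic class labels used in
#' the class-level screen (antineoplastic agents, immunosuppressants,
#' analgesics, corticosteroids for systemic use, sex hormones and modulators
#' of the genital system, antiepileptics, drugs used in diabetes,
#' antibacterials for systemic use). Editable via [read_name_map()] on your
#' own file. Note the map's "analgesics" label covers both paracetamol and
#' ibuprofen, matching common pharmacovigilance grouping rather than the
#' strict ATC tree (which places ibuprofen under M01).
#' @return Named character vector (ingredient -> class label), uppercase keys.
#' @export
default_atc_map <- function() {
  d <- readr::read_delim(system.file("extdata", "atc_classes.txt", package = "pvsignal"),
                         delim = "\t", show_col_types = FALSE, trim_ws = TRUE,
                         comment = "#")
  setNames(as.character(d[[2]]), clean_string(d[[1]]))
}

#' Normalize verbatim drug names to canonical ingredients
#'
#' Deterministic cleaning — uppercase, trim, collapse internal whitespace,
#' strip trailing dosage/form tokens (from a configurable suffix list, plus
#' pure dose tokens like "1G" or "100 MG") — followed by exact lookup in the
#' synonym map. Unmapped names pass through as their cleaned form, flagged
#' `unmapped`; names on the ambiguity blocklist are `unresolved` and get
#' `NA` as ingredient. Combination products ("X AND Y") are kept as single
#' combination entities. The operation is idempotent.
#'
#' @param verbatim Character vector of verbatim drug names.
#' @param synonym_map Named character vector, variant -> ingredient
#'   (uppercase); defaults to the packaged map.
#' @param suffixes Trailing form/dose tokens to strip.
#' @param blocklist Cleaned names treated as unresolvable.
#' @return Tibble with columns `verbatim`, `ingredient` (`NA` when
#'   unresolved) and `status` (`mapped` / `unmapped` / `unresolved`).
#' @examples
#' normalize_drug_name("  Gemzar 1g vial ", synonym_map = c(GEMZAR = "GEMCITABINE"))
#' @export
normalize_drug_name <- function(verbatim,
                                synonym_map = default_synonyms(),
                                suffixes = default_form_suffixes(),
                                blocklist = default_ambiguous_names()) {
  cleaned <- clean_string(verbatim)
  dose_rx <- "^[0-9][0-9.,/]*(MG|G|MCG|UG|ML|IU|%|MG/ML|MG/G)?$"
  strip_tail <- function(s) {
    if (is.na(s) || s == "") return(s)
    toks <- strsplit(s, " ", fixed = TRUE)[[1]]
    while (length(toks) > 1 &&
           (toks[length(toks)] %in% suffixes ||
            grepl(dose_rx, toks[length(toks)]))) {
      toks <- toks[-length(toks)]
    }
    paste(toks, collapse = " ")
  }
  cleaned <- vapply(cleaned, strip_tail, character(1), USE.NAMES = FALSE)

  mapped <- unname(synonym_map[cleaned])
  status <- dplyr::case_when(
    cleaned %in% blocklist ~ "unresolved",
    !is.na(mapped) ~ "mapped",
    TRUE ~ "unmapped"
  )
  ingredient <- dplyr::case_when(
    status == "unresolved" ~ NA_character_,
    status == "mapped" ~ mapped,
    TRUE ~ cleaned
  )
  tibble(verbatim = as.character(verbatim), ingredient = ingredient, status = status)
}

#' Keep drug mentions with a given role code
#'
#' FAERS role codes: PS primary suspect, SS secondary suspect, C
#' concomitant, I interacting. The screen uses PS only — the drug the
#' reporter considered most responsible for the event.
#'
#' @param mentions Tibble with a `role_cod` column.
#' @param role Role code to keep (default `"PS"`).
#' @return The subset, with kept/dropped counts in attribute `role_report`.
#' @export
filter_role <- function(mentions, role = "PS") {
  stopifnot("role_cod" %in% names(mentions))
  out <- dplyr::filter(mentions, .data$role_cod == role)
  attr(out, "role_report") <- tibble(
    role = role, n_input = nrow(mentions), n_kept = nrow(out)
  )
  out
}

#' Remove excluded ingredients (anticoagulants/antiplatelets by default)
#'
#' Applied before top-N ranking so that drugs indicated for clotting
#' disorders do not crowd out the screen.
#'
#' @param entities Character vector of canonical ingredient names.
#' @param exclusion_list Ingredients to drop; defaults to the packaged
#'   anticoagulant/antiplatelet list.
#' @return The kept entities, with the dropped ones in attribute
#'   `exclusion_report`.
#' @export
apply_exclusions <- function(entities, exclusion_list = default_exclusion_list()) {
  key <- clean_string(entities)
  drop <- key %in% clean_string(exclusion_list)
  out <- entities[!drop]
  attr(out, "exclusion_report") <- tibble(
    ingredient = entities[drop],
    reason = "on exclusion list"
  )
  out
}

#' Assign therapeutic class labels to ingredients
#'
#' @param ingredient Character vector of canonical ingredient names.
#' @param atc_map Named character vector (ingredient -> class label);
#'   defaults to the packaged map.
#' @return Character vector of class labels, `"Unknown"` where unmapped
#'   (unknown entities remain analyzable as single drugs).
#' @export
assign_group <- function(ingredient, atc_map = default_atc_map()) {
  lab <- unname(atc_map[clean_string(ingredient)])
  ifelse(is.na(lab), "Unknown", lab)
}
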