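#' Reference demographic strata for coagulopathy reports
#'
#' Stratified case counts for the 40,545 deduplicated coagulopathy cases in
#' the public FAERS window 2004Q1-2024Q2: sex, age band, top reporting
#' countries, and patient outcome. These counts serve two purposes: they are
#' the default categorical distributions of the synthetic reporting-system
#' generator (so simulated databases resemble real report mixes), and they
#' let `percent()` reproduce the published stratum percentages (e.g. female
#' 46.2%, death 32.5%, United States 36.9%).
#'
#' Outcome strata use FAERS outcome codes: DE death, HO hospitalization,
#' LT life-threatening, DS disability, CA congenital anomaly, OT other or
#' unknown.
#'
#' @return Tibble with columns `dimension` (sex / age_band / country /
#'   outcome), `stratum`, and `count`. Within each dimension the counts sum
#'   to the same case total.
#' @examples
#' ref <- coagulopathy_demographics()
#' sum(ref$count[ref$dimension == "age_band"]) # total case count
#' @export
coagulopathy_demographics <- function() {
  tibble::tribble(
    ~dimension, ~stratum, ~count,
    "age_band", "<18", 3675L,
    "age_band", "18-64.9", 16547L,
    "age_band", "65-85", 10419L,
    "age_band", ">85", 974L,
    "age_band", "Unknown", 8930L,
    "sex", "Male", 17893L,
    "sex", "Female", 18734L,
    "sex", "Unknown", 3918L,
    "country", "United States", 14951L,
    "country", "Japan", 7310L,
    "country", "France", 1876L,
    "country", "Germany", 1225L,
    "country", "Spain", 1151L,
    "country", "Others or unknown", 14032L,
    "outcome", "DE", 13183L,
    "outcome", "HO", 12511L,
    "outcome", "LT", 4558L,
    "outcome", "DS", 180L,
    "outcome", "CA", 28L,
    "outcome", "OT", 10085L
  )
}

# Named probability vector for one dimension of the reference table.
reference_probs <- function(dimension) {
  ref <- coagulopathy_demographics()
  ref <- ref[ref$dimension == dimension, ]
  setNames(ref$count / sum(ref$count), ref$stratum)
}
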