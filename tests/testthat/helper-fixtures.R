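# Small in-code fixtures shared across test files.

# a tiny catalog: one planted drug, two nulls, background absorbs the rest
tiny_catalog <- function(planted_rr = 10) {
  tibble::tibble(
    ingredient = c("SIMDRUG-01", "SIMDRUG-02", "SIMDRUG-03"),
    use_prob = c(0.02, 0.05, 0.05),
    rr = c(planted_rr, 1, 1),
    atc_class = c("synthetic class 1", "synthetic class 1", "synthetic class 2")
  )
}

# synthetic class map matching default_srs_drug_catalog()
srs_atc_map <- function(catalog = default_srs_drug_catalog()) {
  stats::setNames(catalog$atc_class, catalog$ingredient)
}

# screen config suited to synthetic databases (no packaged drug lists)
srs_screen_config <- function(catalog = default_srs_drug_catalog(), ...) {
  screen_config(
    synonym_map = c(DUMMY = "DUMMY"),
    exclusion_list = character(),
    atc_map = srs_atc_map(catalog),
    ...
  )
}

# hand-built case records exercising both dedup branches
dedup_fixture <- function() {
  tibble::tibble(
    primaryid = c("1001", "1002", "1003", "1004", "2001"),
    caseid    = c("500", "500", "501", "501", "502"),
    fda_dt    = c("20200101", "20200315", "20210601", "20210601", "20190401")
  )
}

# random strictly-positive 2x2 tables for property tests
random_tables <- function(n, seed, max_cell = 500) {
  withr::with_seed(seed, {
    tibble::tibble(
      a = sample.int(max_cell, n, replace = TRUE),
      b = sample.int(max_cell, n, replace = TRUE),
      c = sample.int(max_cell, n, replace = TRUE),
      d = sample.int(max_cell * 10, n, replace = TRUE)
    )
  })
}
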