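#' @name synthetic_srs
#' @title Synthetic spontaneous-reporting-system generator
#'
#' @description
#' Generates FAERS-format quarterly data packages with known ground truth so
#' every pipeline stage is testable without the multi-GB public snapshot.
#' Each simulated case draws one primary-suspect (PS) drug directly from the
#' catalog's marginal use probabilities (an explicit null background entity
#' absorbs any remaining probability mass), plus up to two
#' secondary-suspect/concomitant drugs. The case reports a coagulopathy PT
#' with probability `min(1, p0 * RR)` where `p0` is the baseline reporting
#' probability and `RR` the planted relative risk of its PS drug — so the
#' per-drug event count has an exact binomial expectation
#' `n_cases * use_prob * min(1, p0 * RR)` and [expected_contingency()] is an
#' analytic oracle, not an approximation.
#'
#' A configurable fraction of cases is emitted twice under one `caseid` with
#' distinct `primaryid`s — half the pairs 30 days apart in `fda_dt`, half
#' with equal `fda_dt` — to exercise both deduplication branches.
#' Demographics default to the published coagulopathy report mix (see
#' [coagulopathy_demographics()]); event PTs are sampled with weights
#' proportional to the published PT frequencies.
NULL

#' Default synthetic drug catalog
#'
#' `n_drugs` ingredients with equal marginal use probability `1/n_drugs`
#' (summing to 1, so there is no background mass), the first `n_planted`
#' carrying a planted relative risk and the rest null (RR = 1). Class labels
#' cycle over six synthetic therapeutic classes so the class-level screen is
#' exercised.
#'
#' @param n_drugs Number of ingredients (default 30).
#' @param n_planted Number of drugs with a planted signal (default 3).
#' @param planted_rr Relative risk planted on those drugs (default 8).
#' @return Tibble with columns `ingredient`, `use_prob`, `rr`, `atc_class`.
#' @export
default_srs_drug_catalog <- function(n_drugs = 30, n_planted = 3, planted_rr = 8) {
  stopifnot(n_planted <= n_drugs)
  tibble(
    ingredient = sprintf("SIMDRUG-%02d", seq_len(n_drugs)),
    use_prob = rep(1 / n_drugs, n_drugs),
    rr = c(rep(planted_rr, n_planted), rep(1, n_drugs - n_planted)),
    atc_class = paste("synthetic class", (seq_len(n_drugs) - 1) %% 6 + 1)
  )
}

default_noise_pts <- function(n) {
  base <- c("Nausea", "Headache", "Dizziness", "Fatigue", "Rash", "Vomiting",
            "Diarrhoea", "Pyrexia", "Pruritus", "Dyspnoea", "Arthralgia",
            "Insomnia", "Cough", "Oedema peripheral", "Anaemia")
  if (n <= length(base)) return(base[seq_len(n)])
  c(base, sprintf("Synthetic filler reaction %03d", seq_len(n - length(base))))
}

#' Configuration for the synthetic reporting-system generator
#'
#' @param n_cases Number of distinct cases to simulate.
#' @param quarters Year-quarter labels, e.g. `"2020Q1"`; cases are assigned
#'   uniformly.
#' @param drug_catalog Tibble with `ingredient`, `use_prob`, `rr`,
#'   `atc_class`; use probabilities must lie in \[0,1\] and sum to at most 1
#'   (any remainder becomes an explicit null background entity).
#' @param baseline_event_prob Probability `p0` in (0,1) that a case on a
#'   null drug reports a coagulopathy PT.
#' @param pt_weights Named weights over event PT names used when an event is
#'   reported; defaults to the published PT frequencies.
#' @param n_noise_pts Number of non-event filler PTs.
#' @param duplicate_fraction Fraction of cases emitted twice under one
#'   `caseid` (in \[0, 1)).
#' @param demographics Named list of categorical probability vectors for
#'   `sex`, `age_band`, `country`, `outcome`; defaults mirror the published
#'   report mix.
#' @param name_noise_prob Probability that a drug's verbatim name is
#'   decorated with a dosage/form suffix (exercises name normalization).
#' @param seed Integer seed; identical (config, seed) gives byte-identical
#'   output files.
#' @return A validated list of class `srs_config`.
#' @export
srs_config <- function(n_cases,
                       quarters = paste0(rep(2020:2021, each = 4), "Q", 1:4),
                       drug_catalog = default_srs_drug_catalog(),
                       baseline_event_prob = 0.01,
                       pt_weights = NULL,
                       n_noise_pts = 50,
                       duplicate_fraction = 0.05,
                       demographics = NULL,
                       name_noise_prob = 0.15,
                       seed = 20240101) {
  if (length(n_cases) != 1 || n_cases < 1 || n_cases != floor(n_cases)) {
    abort("n_cases must be a positive integer.")
  }
  req <- c("ingredient", "use_prob", "rr", "atc_class")
  if (!all(req %in% names(drug_catalog))) {
    abort(paste("drug_catalog needs columns:", paste(req, collapse = ", ")))
  }
  if (any(drug_catalog$use_prob < 0) || any(drug_catalog$use_prob > 1) ||
      sum(drug_catalog$use_prob) > 1 + 1e-12) {
    abort("Drug use probabilities must be in [0,1] and sum to at most 1.")
  }
  if (any(drug_catalog$rr < 0)) abort("Planted relative risks must be >= 0.")
  if (baseline_event_prob <= 0 || baseline_event_prob >= 1) {
    abort("baseline_event_prob must be in (0,1).")
  }
  if (duplicate_fraction < 0 || duplicate_fraction >= 1) {
    abort("duplicate_fraction must be in [0,1).")
  }
  if (is.null(pt_weights)) {
    dict <- coagulopathy_pts()
    pt_weights <- setNames(dict$reference_count / sum(dict$reference_count),
                           dict$pt_name)
  }
  if (any(pt_weights < 0) || sum(pt_weights) <= 0) {
    abort("pt_weights must be non-negative and not all zero.")
  }
  defaults <- list(
    sex = reference_probs("sex"),
    age_band = reference_probs("age_band"),
    country = reference_probs("country"),
    outcome = reference_probs("outcome")
  )
  if (is.null(demographics)) demographics <- defaults
  for (dim in names(defaults)) {
    if (is.null(demographics[[dim]])) demographics[[dim]] <- defaults[[dim]]
    p <- demographics[[dim]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      abort(paste0("demographics$", dim, " must be a probability vector summing to 1."))
    }
  }
  structure(
    list(n_cases = as.integer(n_cases), quarters = quarters,
         drug_catalog = tibble::as_tibble(drug_catalog),
         baseline_event_prob = baseline_event_prob,
         pt_weights = pt_weights, n_noise_pts = as.integer(n_noise_pts),
         duplicate_fraction = duplicate_fraction,
         demographics = demographics,
         name_noise_prob = name_noise_prob,
         seed = as.integer(seed)),
    class = "srs_config"
  )
}

quarter_start <- function(q) {
  as.Date(paste0(substr(q, 1, 4), "-",
                 sprintf("%02d", (as.integer(substr(q, 6, 6)) - 1) * 3 + 1), "-01"))
}

sample_cat <- function(n, probs) {
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# draw an age (in years, as character) inside a band; Unknown -> NA
age_within_band <- function(band) {
  lo <- c("<18" = 0, "18-64.9" = 18, "65-85" = 65, ">85" = 86)[band]
  hi <- c("<18" = 17, "18-64.9" = 64, "65-85" = 85, ">85" = 99)[band]
  out <- rep(NA_character_, length(band))
  known <- !is.na(lo)
  out[known] <- as.character(floor(runif(sum(known), lo[known], hi[known] + 1)))
  out
}

#' Simulate a spontaneous-reporting database in memory
#'
#' @param config An [srs_config()].
#' @return A list of class `srs_db` with the seven FAERS tables (`demo`,
#'   `drug`, `reac`, `outc`, `ther`, `indi`, `rpsr`, all character tibbles),
#'   a per-case ground-truth `manifest` (`caseid`, `quarter`,
#'   `ps_ingredient`, `is_event`, `event_pt`, demographics, `duplicated`),
#'   the `drug_truth` catalog, and the `config`.
#' @export
simulate_srs <- function(config) {
  stopifnot(inherits(config, "srs_config"))
  with_local_seed(config$seed, simulate_srs_impl(config))
}

simulate_srs_impl <- function(config) {
  n <- config$n_cases
  cat <- config$drug_catalog
  p0 <- config$baseline_event_prob

  bg_mass <- 1 - sum(cat$use_prob)
  probs <- cat$use_prob
  ingredients <- cat$ingredient
  rrs <- cat$rr
  if (bg_mass > 1e-12) {
    ingredients <- c(ingredients, "SIMULATED BACKGROUND MEDICATION")
    probs <- c(probs, bg_mass)
    rrs <- c(rrs, 1)
  }
  k <- length(ingredients)

  caseid <- as.character(10000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")
  quarter <- sample(config$quarters, n, replace = TRUE)
  fda_date <- quarter_start(quarter) + sample(0:85, n, replace = TRUE)
  fda_dt <- format(fda_date, "%Y%m%d")
  event_dt <- format(fda_date - sample(0:90, n, replace = TRUE), "%Y%m%d")

  sex_band <- sample_cat(n, config$demographics$sex)
  sex <- c(Male = "M", Female = "F", Unknown = NA)[sex_band]
  age_band <- sample_cat(n, config$demographics$age_band)
  age <- age_within_band(age_band)
  country_band <- sample_cat(n, config$demographics$country)
  country_code <- c("United States" = "US", Japan = "JP", France = "FR",
                    Germany = "DE", Spain = "ES")[country_band]
  other <- is.na(country_code) & country_band == "Others or unknown"
  country_code[other] <- sample(c("IT", "GB", "CA", "BR", NA), sum(other),
                                replace = TRUE)
  outcome <- sample_cat(n, config$demographics$outcome)

  # primary-suspect drug and event status
  ps_idx <- sample.int(k, n, replace = TRUE, prob = probs)
  event_prob <- pmin(1, p0 * rrs[ps_idx])
  is_event <- runif(n) < event_prob
  event_pt <- rep(NA_character_, n)
  event_pt[is_event] <- sample(names(config$pt_weights), sum(is_event),
                               replace = TRUE, prob = config$pt_weights)

  # secondary-suspect / concomitant drugs (0-2 extras, distinct from PS)
  n_extra <- sample(0:2, n, replace = TRUE, prob = c(0.6, 0.3, 0.1))
  extra1 <- sample.int(k, n, replace = TRUE, prob = probs)
  extra2 <- sample.int(k, n, replace = TRUE, prob = probs)
  keep1 <- n_extra >= 1 & extra1 != ps_idx
  keep2 <- n_extra >= 2 & extra2 != ps_idx & extra2 != extra1

  decorate <- function(name) {
    deco <- runif(length(name)) < config$name_noise_prob
    suffix <- sample(c(" 100 MG", " TABLETS", " INJECTION", " 1G VIAL"),
                     length(name), replace = TRUE)
    ifelse(deco, paste0(name, suffix), name)
  }
  drug <- dplyr::bind_rows(
    tibble(primaryid = primaryid, case_row = seq_len(n),
           role_cod = "PS", ingredient = ingredients[ps_idx]),
    tibble(primaryid = primaryid[keep1], case_row = which(keep1),
           role_cod = sample(c("SS", "C"), sum(keep1), replace = TRUE),
           ingredient = ingredients[extra1[keep1]]),
    tibble(primaryid = primaryid[keep2], case_row = which(keep2),
           role_cod = sample(c("SS", "C"), sum(keep2), replace = TRUE),
           ingredient = ingredients[extra2[keep2]])
  ) %>%
    dplyr::arrange(.data$case_row, .data$role_cod) %>%
    dplyr::group_by(.data$case_row) %>%
    dplyr::mutate(drug_seq = as.character(dplyr::row_number())) %>%
    dplyr::ungroup() %>%
    dplyr::mutate(drugname = decorate(.data$ingredient),
                  prod_ai = .data$ingredient) %>%
    dplyr::select("primaryid", "case_row", "drug_seq", "role_cod",
                  "drugname", "prod_ai")

  # reactions: 1-3 filler PTs per case, plus the event PT for event cases
  noise_pts <- default_noise_pts(config$n_noise_pts)
  n_filler <- sample(1:3, n, replace = TRUE)
  reac <- dplyr::bind_rows(
    tibble(primaryid = rep(primaryid, n_filler),
           case_row = rep(seq_len(n), n_filler)) %>%
      dplyr::mutate(pt = sample(noise_pts, dplyr::n(), replace = TRUE)),
    tibble(primaryid = primaryid[is_event], case_row = which(is_event),
           pt = event_pt[is_event])
  ) %>%
    dplyr::arrange(.data$case_row, .data$pt) %>%
    dplyr::select("primaryid", "case_row", "pt")

  demo <- tibble(
    primaryid = primaryid, caseid = caseid, case_row = seq_len(n),
    fda_dt = fda_dt, age = age,
    age_cod = ifelse(is.na(age), NA_character_, "YR"),
    sex = unname(sex), occr_country = unname(country_code),
    event_dt = event_dt
  )
  outc <- tibble(primaryid = primaryid, case_row = seq_len(n), outc_cod = outcome)
  ther <- drug %>%
    dplyr::transmute(.data$primaryid, .data$case_row, dsg_drug_seq = .data$drug_seq,
                     start_dt = event_dt[.data$case_row])
  indi <- drug %>%
    dplyr::transmute(.data$primaryid, .data$case_row,
                     indi_drug_seq = .data$drug_seq,
                     indi_pt = "Product used for unknown indication")
  rpsr <- tibble(primaryid = primaryid, case_row = seq_len(n),
                 rpsr_cod = sample(c("FGN", "HP", "CSM"), n, replace = TRUE))

  # duplicate injection: same caseid, larger primaryid; half +30 days,
  # half equal fda_dt (covers both dedup branches)
  n_dup <- floor(config$duplicate_fraction * n)
  dup_rows <- if (n_dup > 0) sort(sample.int(n, n_dup)) else integer(0)
  dup_of <- function(d) {
    dd <- d[d$case_row %in% dup_rows, , drop = FALSE]
    dd$primaryid <- sub("1$", "2", dd$primaryid)
    dd
  }
  if (n_dup > 0) {
    demo2 <- dup_of(demo)
    shift <- seq_len(n_dup) %% 2 == 0
    d2 <- as.Date(demo2$fda_dt, "%Y%m%d")
    d2[shift] <- d2[shift] + 30
    demo2$fda_dt <- format(d2, "%Y%m%d")
    demo <- dplyr::bind_rows(demo, demo2)
    drug <- dplyr::bind_rows(drug, dup_of(drug))
    reac <- dplyr::bind_rows(reac, dup_of(reac))
    outc <- dplyr::bind_rows(outc, dup_of(outc))
    ther <- dplyr::bind_rows(ther, dup_of(ther))
    indi <- dplyr::bind_rows(indi, dup_of(indi))
    rpsr <- dplyr::bind_rows(rpsr, dup_of(rpsr))
  }

  manifest <- tibble(
    caseid = caseid, quarter = quarter,
    ps_ingredient = ingredients[ps_idx],
    is_event = is_event, event_pt = event_pt,
    sex = sex_band, age_band = age_band, country = country_band,
    outcome = outcome, fda_dt = fda_dt,
    duplicated = seq_len(n) %in% dup_rows
  )

  finalize <- function(d) {
    d <- d[order(d$case_row, as.numeric(d$primaryid)), , drop = FALSE]
    quarter_of <- quarter[d$case_row]
    d$case_row <- NULL
    d <- dplyr::mutate(d, dplyr::across(dplyr::everything(), as.character))
    d$.quarter <- quarter_of
    d
  }

  structure(
    list(demo = finalize(demo), drug = finalize(drug), reac = finalize(reac),
         outc = finalize(outc), ther = finalize(ther), indi = finalize(indi),
         rpsr = finalize(rpsr), manifest = manifest,
         drug_truth = tibble(ingredient = ingredients, use_prob = probs, rr = rrs),
         config = config),
    class = "srs_db"
  )
}

#' Write a simulated database as FAERS-format quarterly packages
#'
#' One subdirectory per quarter, each holding "$"-delimited
#' DEMO/DRUG/REAC/OUTC/THER/INDI/RPSR tables, plus `manifest.txt` and
#' `drug_truth.txt` (tab-delimited ground truth) at the top level.
#'
#' @param db An `srs_db` from [simulate_srs()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_srs <- function(db, dir) {
  stopifnot(inherits(db, "srs_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  kinds <- c(demo = "DEMO", drug = "DRUG", reac = "REAC", outc = "OUTC",
             ther = "THER", indi = "INDI", rpsr = "RPSR")
  for (q in sort(unique(db$demo$.quarter))) {
    qdir <- file.path(dir, q)
    dir.create(qdir, showWarnings = FALSE)
    for (nm in names(kinds)) {
      d <- db[[nm]]
      d <- d[d$.quarter == q, setdiff(names(d), ".quarter"), drop = FALSE]
      faers_write_table(d, file.path(qdir, paste0(kinds[nm], ".txt")), kinds[nm])
    }
  }
  readr::write_tsv(db$manifest, file.path(dir, "manifest.txt"), progress = FALSE)
  readr::write_tsv(db$drug_truth, file.path(dir, "drug_truth.txt"), progress = FALSE)
  invisible(dir)
}

#' Simulate and write a FAERS-format package in one step
#'
#' @inheritParams simulate_srs
#' @inheritParams write_srs
#' @return `dir`, invisibly; the in-memory `srs_db` is attached as attribute
#'   `db`.
#' @export
simulate_faers_package <- function(config, dir) {
  db <- simulate_srs(config)
  write_srs(db, dir)
  invisible(structure(dir, db = db))
}

#' Expected 2x2 cell counts under the generative model
#'
#' Analytic oracle for tests: with PS drug D drawn with probability `p_D`
#' and event probability `min(1, p0 * RR_D)` given D,
#' `E(a) = n p_D min(1, p0 RR_D)`, `E(a+b) = n p_D`, and the remaining cells
#' follow from the event totals over the other catalog entries (plus the
#' null background entity when use probabilities sum to < 1).
#'
#' @param config An [srs_config()].
#' @param ingredient One catalog ingredient name.
#' @return One-row tibble with real-valued `a`, `b`, `c`, `d`, `n`.
#' @export
expected_contingency <- function(config, ingredient) {
  stopifnot(inherits(config, "srs_config"))
  cat <- config$drug_catalog
  probs <- cat$use_prob
  rrs <- cat$rr
  names <- cat$ingredient
  bg <- 1 - sum(probs)
  if (bg > 1e-12) {
    names <- c(names, "SIMULATED BACKGROUND MEDICATION")
    probs <- c(probs, bg)
    rrs <- c(rrs, 1)
  }
  i <- match(ingredient, names)
  if (is.na(i)) abort(paste0("Unknown ingredient: ", ingredient))
  n <- config$n_cases
  pe <- pmin(1, config$baseline_event_prob * rrs)
  a <- n * probs[i] * pe[i]
  b <- n * probs[i] * (1 - pe[i])
  total_events <- n * sum(probs * pe)
  c <- total_events - a
  d <- n - a - b - c
  tibble(a = a, b = b, c = c, d = d, n = n)
}
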