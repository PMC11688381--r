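#' @name calibration
#' @title Simulation-based calibration of the signal-detection pipeline
#'
#' @description
#' Two seeded simulation studies validate the pipeline against known truth:
#' [simulate_ror_coverage()] checks that the Woolf 95% interval for the
#' reporting odds ratio attains its nominal coverage on multinomial 2x2
#' tables with a known true odds ratio, and [planted_recovery_sim()] runs
#' the full screen on replicated synthetic databases to measure how often
#' planted signals are flagged by all three algorithms and how often null
#' drugs are falsely flagged.
NULL

# multinomial cell probabilities with given margins and odds ratio
cells_for_odds_ratio <- function(odds_ratio, row_prob, col_prob) {
  if (odds_ratio == 1) {
    p11 <- row_prob * col_prob
  } else {
    s <- 1 + (row_prob + col_prob) * (odds_ratio - 1)
    p11 <- (s - sqrt(s^2 - 4 * odds_ratio * (odds_ratio - 1) * row_prob * col_prob)) /
      (2 * (odds_ratio - 1))
  }
  c(p11 = p11, p12 = row_prob - p11, p21 = col_prob - p11,
    p22 = 1 - row_prob - col_prob + p11)
}

#' Empirical coverage of the ROR 95% confidence interval
#'
#' Draws `n_tables` multinomial 2x2 tables of size `n` whose cell
#' probabilities have margins `row_prob`/`col_prob` and true odds ratio
#' `odds_ratio`, computes the Woolf interval for each, and reports the
#' fraction covering the truth. A calibrated interval should cover close to
#' 95% of the time.
#'
#' @param odds_ratio True odds ratio of the generating table.
#' @param n_tables Number of replicate tables.
#' @param n Reports per table.
#' @param row_prob,col_prob Margins of the generating probabilities.
#' @param seed Integer seed.
#' @return A list: `coverage` (proportion in \[0,1\]), `n_tables`, and the
#'   generating `cells`.
#' @export
simulate_ror_coverage <- function(odds_ratio, n_tables = 1e4, n = 2000,
                                  row_prob = 0.1, col_prob = 0.1,
                                  seed = 20240101) {
  p <- cells_for_odds_ratio(odds_ratio, row_prob, col_prob)
  stopifnot(all(p >= 0))
  draws <- with_local_seed(seed, rmultinom(n_tables, n, p))
  tabs <- tibble(a = draws[1, ], b = draws[2, ], c = draws[3, ], d = draws[4, ])
  ci <- ror_ci(tabs)
  list(coverage = mean(ci$ror_lo <= odds_ratio & odds_ratio <= ci$ror_hi),
       n_tables = n_tables, cells = p)
}

#' Planted-signal recovery and null false-positive rates of the full screen
#'
#' Runs `n_reps` independent synthetic databases through the complete
#' pipeline (simulate, assemble, deduplicate, flag events, normalize,
#' screen) and records, per replicate, whether every planted drug was
#' flagged by all three algorithms and how many null drugs were flagged
#' positive by the consensus rule.
#'
#' @param n_reps Number of replicates.
#' @param n_cases Cases per replicate database.
#' @param n_drugs,n_planted,planted_rr Catalog shape, see
#'   [default_srs_drug_catalog()].
#' @param baseline_event_prob Baseline event probability `p0`.
#' @param n_draws Monte-Carlo draws for the IC bounds inside each screen.
#' @param seed Integer seed; replicate r uses `seed + r`.
#' @return Tibble with one row per replicate: `rep`, `all_planted_flagged`
#'   (all planted drugs positive by all three algorithms), `n_null_positive`
#'   (null drugs with a consensus positive), `n_null` (null drugs screened).
#' @export
planted_recovery_sim <- function(n_reps = 50, n_cases = 5e4, n_drugs = 30,
                                 n_planted = 3, planted_rr = 8,
                                 baseline_event_prob = 0.01,
                                 n_draws = 2e4, seed = 20240101) {
  catalog <- default_srs_drug_catalog(n_drugs, n_planted, planted_rr)
  planted <- catalog$ingredient[seq_len(n_planted)]
  cfg_screen <- screen_config(
    top_n = n_drugs,
    synonym_map = character(),
    exclusion_list = character(),
    atc_map = setNames(catalog$atc_class, catalog$ingredient),
    n_draws = n_draws
  )
  rows <- lapply(seq_len(n_reps), function(r) {
    cfg <- srs_config(n_cases, drug_catalog = catalog,
                      baseline_event_prob = baseline_event_prob,
                      seed = seed + r)
    cfg_screen$seed <- seed + r
    db <- simulate_srs(cfg)
    s <- pv_screen(db, cfg_screen)$signals
    is_planted <- s$ingredient %in% planted
    tibble(
      rep = r,
      all_planted_flagged = sum(is_planted) == n_planted &&
        all(s$flag_ror[is_planted] & s$flag_prr[is_planted] &
              s$flag_bcpnn[is_planted]),
      n_null_positive = sum(s$positive[!is_planted], na.rm = TRUE),
      n_null = sum(!is_planted)
    )
  })
  dplyr::bind_rows(rows)
}
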