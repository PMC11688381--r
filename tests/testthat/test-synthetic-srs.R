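test_that("config validation rejects invalid probabilities", {
  expect_error(srs_config(0), "positive integer")
  expect_error(srs_config(10, baseline_event_prob = 0), "baseline_event_prob")
  expect_error(srs_config(10, duplicate_fraction = 1), "duplicate_fraction")
  bad <- default_srs_drug_catalog()
  bad$use_prob <- rep(0.2, nrow(bad)) # sums to 6
  expect_error(srs_config(10, drug_catalog = bad), "sum to at most 1")
})

test_that("no duplicates injected means one DEMO row per case", {
  db <- simulate_srs(srs_config(100, duplicate_fraction = 0, seed = 1))
  expect_equal(nrow(db$demo), 100)
  expect_equal(dplyr::n_distinct(db$demo$caseid), 100)
  expect_equal(dplyr::n_distinct(db$demo$primaryid), 100)
})

test_that("every case has a PS drug and at least one reaction", {
  db <- simulate_srs(srs_config(300, seed = 2))
  ps <- db$drug[db$drug$role_cod == "PS", ]
  expect_setequal(unique(ps$primaryid), unique(db$demo$primaryid))
  expect_setequal(unique(db$reac$primaryid), unique(db$demo$primaryid))
  expect_true(all(db$drug$role_cod %in% c("PS", "SS", "C")))
  # exactly one PS mention per report
  expect_equal(max(table(ps$primaryid)), 1)
})

test_that("identical config and seed give byte-identical packages", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_faers_package(srs_config(400, seed = 9), d1)
  simulate_faers_package(srs_config(400, seed = 9), d2)
  files <- list.files(d1, recursive = TRUE)
  expect_identical(files, list.files(d2, recursive = TRUE))
  for (f in files) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }
})

test_that("planted event counts match the binomial expectation", {
  cfg <- srs_config(1e5, drug_catalog = tiny_catalog(planted_rr = 10),
                    duplicate_fraction = 0, seed = 31)
  db <- simulate_srs(cfg)
  # E = n * p_use * min(1, p0 * RR) = 1e5 * 0.02 * 0.10 = 200
  hits <- sum(db$manifest$ps_ingredient == "SIMDRUG-01" & db$manifest$is_event)
  p <- 0.02 * 0.10
  expect_lt(abs(hits - 1e5 * p), 3 * sqrt(1e5 * p * (1 - p)))
})

test_that("expected_contingency is the analytic oracle of the generator", {
  cfg <- srs_config(1e5, drug_catalog = tiny_catalog(planted_rr = 10),
                    duplicate_fraction = 0, seed = 31)
  e <- expected_contingency(cfg, "SIMDRUG-01")
  expect_equal(e$a, 200)
  expect_equal(e$a + e$b, 1e5 * 0.02) # marginal identity
  expect_equal(e$a + e$b + e$c + e$d, 1e5)

  # all-null catalog: expected cells give ROR exactly 1
  null_cat <- tiny_catalog(planted_rr = 1)
  cfg0 <- srs_config(1e5, drug_catalog = null_cat, seed = 1)
  e0 <- expected_contingency(cfg0, "SIMDRUG-01")
  expect_equal((e0$a * e0$d) / (e0$b * e0$c), 1)

  expect_error(expected_contingency(cfg, "NOT A DRUG"), "Unknown ingredient")
})

test_that("empirical cells and ROR converge to the planted values", {
  cfg <- srs_config(1e5, drug_catalog = tiny_catalog(planted_rr = 10),
                    duplicate_fraction = 0, seed = 8)
  db <- simulate_srs(cfg)
  m <- db$manifest
  a <- sum(m$ps_ingredient == "SIMDRUG-01" & m$is_event)
  b <- sum(m$ps_ingredient == "SIMDRUG-01" & !m$is_event)
  c <- sum(m$ps_ingredient != "SIMDRUG-01" & m$is_event)
  d <- sum(m$ps_ingredient != "SIMDRUG-01" & !m$is_event)
  e <- expected_contingency(cfg, "SIMDRUG-01")
  ror_emp <- (a * d) / (b * c)
  ror_exp <- (e$a * e$d) / (e$b * e$c)
  # Monte-Carlo tolerance: ln ROR is approximately normal with
  # sd = sqrt(sum of reciprocal expected cells)
  sd_log <- sqrt(1 / e$a + 1 / e$b + 1 / e$c + 1 / e$d)
  expect_lt(abs(log(ror_emp) - log(ror_exp)), 3 * sd_log)
})

test_that("duplicate injection produces both dedup branches", {
  db <- simulate_srs(srs_config(1000, duplicate_fraction = 0.2, seed = 12))
  expect_equal(nrow(db$demo), 1200)
  dups <- db$demo %>%
    dplyr::group_by(caseid) %>%
    dplyr::filter(dplyr::n() == 2) %>%
    dplyr::summarise(same_dt = dplyr::n_distinct(fda_dt) == 1)
  expect_equal(nrow(dups), 200)
  expect_true(any(dups$same_dt))   # equal fda_dt -> primaryid tie-break
  expect_true(any(!dups$same_dt))  # later fda_dt wins
})

test_that("written packages round-trip through ingestion with counts conserved", {
  dir <- withr::local_tempdir()
  cfg <- srs_config(500, duplicate_fraction = 0.1, seed = 21)
  simulate_faers_package(cfg, dir)
  cs <- read_faers_package(dir)
  expect_equal(nrow(cs$cases), 550) # 500 cases + 50 duplicate reports
  expect_true(all(cs$unmatched$n_unmatched == 0))
  kept <- dedup_cases(cs$cases)
  expect_equal(nrow(kept), 500)

  # manifest event set equals the REAC-derived event set after dedup
  rx <- dplyr::semi_join(cs$reactions, kept, by = "primaryid")
  flagged <- flag_event_cases(rx)
  manifest <- readr::read_tsv(file.path(dir, "manifest.txt"),
                              show_col_types = FALSE)
  truth <- as.character(manifest$caseid[manifest$is_event])
  expect_setequal(unique(flagged$caseid), truth)
})
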