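test_that("ranking orders by event-case count, ties alphabetically", {
  drug_cases <- tibble::tibble(
    caseid = as.character(c(1:5, 6:8, 9, 10:12)),
    ingredient = c(rep("ZETA", 5), rep("ALPHA", 3), "GAMMA", rep("BETA", 3))
  )
  events <- as.character(c(1:5, 6:8, 9, 10:12))
  ranked <- rank_top_drugs(drug_cases, events, top_n = 2)
  expect_equal(ranked$ingredient, c("ZETA", "ALPHA"))
  expect_equal(ranked$a, c(5, 3))

  # tie on a: alphabetical order breaks it
  tied <- rank_top_drugs(drug_cases, events, top_n = 4)
  expect_equal(tied$ingredient[3:4], c("BETA", "GAMMA"))

  # fewer entities than top_n: all returned with a notice
  expect_message(all4 <- rank_top_drugs(drug_cases, events, top_n = 10),
                 "Only 4")
  expect_equal(nrow(all4), 4)
})

test_that("an excluded drug never reaches the ranking", {
  db <- simulate_srs(srs_config(2000, seed = 51))
  cfg <- srs_screen_config(top_n = 30)
  cfg$exclusion_list <- "SIMDRUG-01"
  sc <- pv_screen(db, cfg)
  expect_false("SIMDRUG-01" %in% sc$signals$ingredient)
  expect_equal(nrow(sc$signals), 29)
})

test_that("every screened entity shares the same universe and event margin", {
  db <- simulate_srs(srs_config(3000, seed = 52))
  sc <- pv_screen(db, srs_screen_config(n_draws = 1e4, seed = 5))
  s <- sc$signals
  expect_true(all(s$a + s$c == sc$n_event_cases))
  expect_true(all(s$a + s$b + s$c + s$d == sc$n_cases))
  expect_equal(nrow(s), min(30, length(unique(db$manifest$ps_ingredient))))
  # ranking matches manifest-derived counts
  m <- db$manifest
  truth <- sort(table(m$ps_ingredient[m$is_event]), decreasing = TRUE)
  expect_equal(s$a[1], unname(truth[1]))
})

test_that("a single-member class reproduces its drug's statistics", {
  db <- simulate_srs(srs_config(3000, seed = 53))
  cfg <- srs_screen_config(n_draws = 1e4, seed = 5)
  # put SIMDRUG-01 alone in its own class
  cfg$atc_map <- c("SIMDRUG-01" = "lone class")
  sc <- pv_screen(db, cfg)
  g <- sc$groups[sc$groups$atc_class == "lone class", ]
  s <- sc$signals[sc$signals$ingredient == "SIMDRUG-01", ]
  expect_equal(g$a, s$a)
  expect_equal(g$ror, s$ror)
  expect_equal(g$prr, s$prr)
  expect_equal(g$chi2, s$chi2)
})

test_that("a class unions member case sets without double counting", {
  drug_cases <- tibble::tibble(
    caseid = c("1", "2", "3", "3", "4"),
    ingredient = c("A", "A", "A", "B", "B")
  )
  cfg <- screen_config(synonym_map = character(), exclusion_list = character(),
                       atc_map = c(A = "cls", B = "cls"), n_draws = 1e4)
  g <- screen_groups(drug_cases, event_cases = c("1", "3", "4"),
                     universe = as.character(1:100), cfg)
  # case 3 has both members: counted once -> a = |{1,3,4}| = 3, margin 4
  expect_equal(g$a, 3)
  expect_equal(g$a + g$b, 4)

  # disjoint member drugs: class a is the sum of member a's
  disjoint <- tibble::tibble(caseid = c("1", "2"), ingredient = c("A", "B"))
  g2 <- screen_groups(disjoint, event_cases = c("1", "2"),
                      universe = as.character(1:100), cfg)
  expect_equal(g2$a, 2)
})

test_that("demographic summary partitions the event cases in every dimension", {
  cases <- tibble::tibble(
    caseid = as.character(1:8),
    sex = c("Male", "Male", "Female", "Female", "Female", "Unknown", "Male", "Female"),
    age_band = c("<18", "18-64.9", "18-64.9", "65-85", ">85", "Unknown", "18-64.9", "65-85"),
    country = c("US", "US", "JP", NA, "FR", "US", "DE", "ES"),
    fda_dt = "20200101"
  )
  outcomes <- tibble::tibble(
    caseid = c("1", "1", "2", "3"),
    outc_cod = c("HO", "DE", "LT", "OT") # case 1: DE outranks HO
  )
  d <- demographic_summary(cases, outcomes)
  for (dim in unique(d$dimension)) {
    expect_equal(sum(d$count[d$dimension == dim]), 8)
  }
  expect_equal(d$count[d$dimension == "sex" & d$stratum == "Female"], 4)
  expect_equal(d$percent[d$dimension == "sex" & d$stratum == "Female"], 50)
  expect_equal(d$count[d$dimension == "outcome" & d$stratum == "DE"], 1)
  # case 3 (OT) plus the five cases without any outcome row
  expect_equal(d$count[d$dimension == "outcome" & d$stratum == "Others or unknown"], 6)

  expect_equal(nrow(demographic_summary(cases[0, ])), 0)
})

test_that("annual trend zero-fills gaps and conserves the case total", {
  cases <- tibble::tibble(
    caseid = as.character(1:3),
    fda_dt = c("20040115", "20060301", "20060401")
  )
  tr <- annual_trend(cases)
  expect_equal(tr$year, 2004:2006)
  expect_equal(tr$n_cases, c(1L, 0L, 2L))
  expect_equal(sum(tr$n_cases), nrow(cases))
})

test_that("the end-to-end screen is deterministic for fixed input and seed", {
  db <- simulate_srs(srs_config(2000, seed = 55))
  cfg <- srs_screen_config(n_draws = 1e4, seed = 99)
  s1 <- pv_screen(db, cfg)
  s2 <- pv_screen(db, cfg)
  expect_identical(s1$signals, s2$signals)
  expect_identical(s1$groups, s2$groups)
  expect_identical(s1$demographics, s2$demographics)
  expect_identical(s1$trend, s2$trend)
})

test_that("tidy, glance and autoplot expose the screen results", {
  db <- simulate_srs(srs_config(1500, seed = 57))
  sc <- pv_screen(db, srs_screen_config(n_draws = 1e4, seed = 3))
  expect_identical(tidy(sc), sc$signals)
  expect_identical(tidy(sc, "class"), sc$groups)
  g <- glance(sc)
  expect_equal(g$n_cases, 1500)
  expect_s3_class(autoplot(sc), "ggplot")
  expect_s3_class(autoplot(sc, "classes"), "ggplot")
  expect_s3_class(autoplot(sc, "trend"), "ggplot")
})

test_that("write_screen emits the output tables and run metadata", {
  db <- simulate_srs(srs_config(1000, seed = 58))
  sc <- pv_screen(db, srs_screen_config(n_draws = 1e4, seed = 3))
  dir <- withr::local_tempdir()
  write_screen(sc, dir)
  expect_setequal(
    list.files(dir),
    c("signals.csv", "groups.csv", "demographics.csv", "pt_distribution.csv",
      "trend.csv", "run_metadata.txt")
  )
  sig <- readr::read_csv(file.path(dir, "signals.csv"), show_col_types = FALSE)
  expect_equal(nrow(sig), nrow(sc$signals))
  expect_equal(sig$ror, round_half_up(sc$signals$ror, 2))
})
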