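test_that("contingency_table performs the set arithmetic", {
  t <- contingency_table(as.character(1:10), as.character(c(1:5, 11:15)),
                         as.character(1:100))
  expect_equal(unlist(t), c(a = 5, b = 5, c = 5, d = 85, n = 100))

  # entity = universe: c and d margins collapse
  t2 <- contingency_table(as.character(1:10), as.character(1:100),
                          as.character(1:100))
  expect_equal(t2$c, 0)
  expect_equal(t2$d, 0)

  expect_error(contingency_table("1", "1", character()), "Empty")
  expect_error(contingency_table("999", "1", as.character(1:10)), "subset")
})

test_that("ROR and its Woolf interval match hand-evaluated values", {
  sym <- ror_ci(tibble::tibble(a = 10, b = 10, c = 10, d = 10))
  expect_equal(sym$ror, 1)
  # exp(+/- 1.96 * sqrt(4/10)) evaluated by hand
  expect_equal(sym$ror_lo, exp(-1.96 * sqrt(0.4)), tolerance = 1e-12)
  expect_equal(sym$ror_lo, 0.2895, tolerance = 1e-3)
  expect_equal(sym$ror_hi, 3.4541, tolerance = 1e-3)

  r <- ror_ci(tibble::tibble(a = 20, b = 80, c = 100, d = 9800))
  expect_equal(r$ror, 24.5)
  expect_false(r$corrected)
})

test_that("PRR matches direct evaluation and chi2 equals Pearson's statistic", {
  p <- prr_chi2(tibble::tibble(a = 10, b = 10, c = 10, d = 10))
  expect_equal(p$prr, 1)
  expect_equal(p$chi2, 0)

  p2 <- prr_chi2(tibble::tibble(a = 20, b = 80, c = 100, d = 9800))
  expect_equal(p2$prr, 20 * 9900 / (100 * 100))

  # independent oracle: stats::chisq.test without continuity correction
  m <- matrix(c(20, 80, 100, 9800), 2, byrow = TRUE)
  oracle <- unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic)
  expect_equal(p2$chi2, oracle, tolerance = 1e-6)
})

test_that("closed-form chi2 equals Pearson's chi-squared on random tables", {
  tabs <- random_tables(500, seed = 101)
  ours <- prr_chi2(tabs)$chi2
  oracle <- vapply(seq_len(nrow(tabs)), function(i) {
    m <- matrix(c(tabs$a[i], tabs$b[i], tabs$c[i], tabs$d[i]), 2, byrow = TRUE)
    unname(suppressWarnings(stats::chisq.test(m, correct = FALSE))$statistic)
  }, numeric(1))
  expect_lt(max(abs(ours - oracle) / oracle), 1e-10)
})

test_that("IC point estimate follows the log2 observed-to-expected formula", {
  flat <- ic_ci(tibble::tibble(a = 1000, b = 1000, c = 1000, d = 1000),
                n_draws = 1e4, seed = 3)
  expect_equal(flat$ic, 0)
  expect_lt(flat$ic025, 0)
  expect_gt(flat$ic975, 0)

  r <- ic_ci(tibble::tibble(a = 20, b = 80, c = 100, d = 9800),
             n_draws = 1e4, seed = 3)
  expect_equal(r$ic, log2(20 * 10000 / (100 * 120)), tolerance = 1e-12)
  expect_equal(r$ic, 4.0589, tolerance = 1e-4)
  expect_lt(r$ic025, r$ic)
  expect_lt(r$ic, r$ic975)
})

test_that("IC bounds are seeded-deterministic and converge in n_draws", {
  tbl <- tibble::tibble(a = 20, b = 80, c = 100, d = 9800)
  r1 <- ic_ci(tbl, n_draws = 2e4, seed = 11)
  r2 <- ic_ci(tbl, n_draws = 2e4, seed = 11)
  expect_identical(r1$ic025, r2$ic025)
  expect_identical(r1$ic975, r2$ic975)

  r4 <- ic_ci(tbl, n_draws = 4e4, seed = 11)
  expect_lt(abs(r4$ic025 - r1$ic025), 0.02)

  expect_error(ic_ci(tbl, n_draws = 100, seed = 1), "n_draws")
})

test_that("E(IC) approaches the point IC as cells scale up", {
  small <- ic_ci(tibble::tibble(a = 4, b = 16, c = 20, d = 1960),
                 n_draws = 5e4, seed = 5)
  big <- ic_ci(tibble::tibble(a = 400, b = 1600, c = 2000, d = 196000),
               n_draws = 5e4, seed = 5)
  mid_small <- (small$ic025 + small$ic975) / 2 # = E(IC)
  mid_big <- (big$ic025 + big$ic975) / 2
  expect_lt(abs(mid_big - big$ic), abs(mid_small - small$ic))
  expect_lt(abs(mid_big - big$ic), 0.02)
})

test_that("positivity criteria follow the published thresholds", {
  # a >= 3 gate: two cases never flag ROR/PRR however extreme the ratio
  low_a <- signal_stats(tibble::tibble(a = 2, b = 1, c = 10, d = 10000),
                        n_draws = 1e4, seed = 2)
  expect_false(low_a$flag_ror)
  expect_false(low_a$flag_prr)

  strong <- signal_stats(tibble::tibble(a = 20, b = 80, c = 100, d = 9800),
                         n_draws = 1e4, seed = 2)
  expect_true(all(strong$flag_ror, strong$flag_prr, strong$flag_bcpnn,
                  strong$positive))

  null <- signal_stats(tibble::tibble(a = 10, b = 10, c = 10, d = 10),
                       n_draws = 1e4, seed = 2)
  expect_false(null$positive)
})

test_that("sign equivalence: ror > 1 iff prr > 1 iff ic > 0 on positive tables", {
  tabs <- random_tables(2000, seed = 77)
  r <- prr_chi2(ror_ci(tabs))
  ic <- log2(r$a * (r$a + r$b + r$c + r$d) / ((r$a + r$b) * (r$a + r$c)))
  expect_identical(r$ror > 1, r$prr > 1)
  expect_identical(r$ror > 1, ic > 0)
})

test_that("increasing a with b, c, d fixed strictly increases all statistics", {
  tabs <- tibble::tibble(a = c(5, 10, 20, 40), b = 100, c = 50, d = 5000)
  s <- ic_ci(prr_chi2(ror_ci(tabs)), n_draws = 1e4, seed = 4)
  expect_true(all(diff(s$ror) > 0))
  expect_true(all(diff(s$prr) > 0))
  expect_true(all(diff(s$ic) > 0))
})

test_that("zero cells trigger the continuity correction, flagged as corrected", {
  z <- signal_stats(tibble::tibble(a = 0, b = 50, c = 100, d = 5000),
                    n_draws = 1e4, seed = 6)
  expect_true(z$corrected)
  expect_true(is.finite(z$ror) && is.finite(z$prr) &&
                is.finite(z$chi2) && is.finite(z$ic))
  # raw a = 0 still fails the a >= 3 gate regardless of corrected statistics
  expect_false(z$flag_ror)
  expect_false(z$flag_prr)

  expect_error(ror_ci(tibble::tibble(a = 0, b = 0, c = 0, d = 0)), "All-zero")
  expect_error(ror_ci(tibble::tibble(a = -1, b = 1, c = 1, d = 1)),
               "non-negative")
})
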