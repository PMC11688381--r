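#' @name dma
#' @title Disproportionality statistics on 2x2 contingency tables
#'
#' @description
#' For one drug (or drug class) against one event set, the whole database
#' reduces to a 2x2 table of case counts:
#' \preformatted{
#'                  event     other AEs
#'   target drug      a          b
#'   other drugs      c          d        N = a+b+c+d
#' }
#' Three statistics quantify how disproportionately the drug-event pair is
#' reported:
#' \itemize{
#'   \item ROR = ad/bc, with Woolf 95\% CI
#'     exp(ln ROR +/- 1.96 sqrt(1/a+1/b+1/c+1/d));
#'   \item PRR = a(c+d)/(c(a+b)), with Pearson chi-squared
#'     (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d));
#'   \item the BCPNN information component IC = log2(aN/((a+b)(a+c))),
#'     with credible bounds E(IC) +/- 2 sqrt(V(IC)) where E and V are the
#'     posterior moments of log2(p11/(p1. p.1)) under a Dirichlet(1,1,1,1)
#'     prior on the cell probabilities, estimated by seeded Monte Carlo.
#' }
#' Positivity criteria: ROR flags when a >= 3 and the CI lower bound
#' exceeds 1; PRR flags when a >= 3, PRR >= 2 and chi-squared >= 4; BCPNN
#' flags when IC025 > 0. The consensus signal is positive when any method
#' flags.
#'
#' Zero-cell policy: when any cell is 0, all four cells get the
#' Haldane-Anscombe +0.5 continuity correction for the statistics (the
#' `corrected` flag records this); the raw `a` still governs the a >= 3
#' criterion.
NULL

# validate and optionally continuity-correct a table of cell counts
correct_cells <- function(tbl) {
  stopifnot(all(c("a", "b", "c", "d") %in% names(tbl)))
  # double precision: products like (ad - bc)^2 overflow 32-bit integers
  cells <- cbind(as.double(tbl$a), as.double(tbl$b),
                 as.double(tbl$c), as.double(tbl$d))
  if (any(cells < 0) || any(cells != floor(cells))) {
    abort("Cells a, b, c, d must be non-negative integers.")
  }
  if (any(rowSums(cells) == 0)) abort("All-zero contingency table.")
  corrected <- rowSums(cells == 0) > 0
  cells[corrected, ] <- cells[corrected, , drop = FALSE] + 0.5
  list(a = cells[, 1], b = cells[, 2], c = cells[, 3], d = cells[, 4],
       corrected = corrected)
}

#' Build a 2x2 contingency table from case-id sets
#'
#' @param event_cases Case ids reporting the event.
#' @param entity_cases Case ids with the target entity as primary suspect.
#' @param universe All deduplicated case ids (both arguments must be
#'   subsets).
#' @return One-row tibble with columns `a`, `b`, `c`, `d`, `n`.
#' @examples
#' contingency_table(as.character(1:10),
#'                   as.character(c(1:5, 11:15)),
#'                   as.character(1:100)) # a=5 b=5 c=5 d=85
#' @export
contingency_table <- function(event_cases, entity_cases, universe) {
  universe <- unique(universe)
  if (length(universe) == 0) abort("Empty case universe.")
  event_cases <- unique(event_cases)
  entity_cases <- unique(entity_cases)
  if (!all(event_cases %in% universe) || !all(entity_cases %in% universe)) {
    abort("event_cases and entity_cases must be subsets of the universe.")
  }
  a <- length(intersect(event_cases, entity_cases))
  b <- length(entity_cases) - a
  c <- length(event_cases) - a
  d <- length(universe) - a - b - c
  tibble(a = a, b = b, c = c, d = d, n = length(universe))
}

#' Reporting odds ratio with Woolf 95% confidence interval
#'
#' @param tbl Tibble with integer columns `a`, `b`, `c`, `d` (one row per
#'   entity; vectorized).
#' @return `tbl` with columns `ror`, `ror_lo`, `ror_hi`, `corrected` added.
#' @examples
#' ror_ci(tibble::tibble(a = 20, b = 80, c = 100, d = 9800)) # ROR 24.5
#' @export
ror_ci <- function(tbl) {
  cc <- correct_cells(tbl)
  ror <- (cc$a * cc$d) / (cc$b * cc$c)
  se <- sqrt(1 / cc$a + 1 / cc$b + 1 / cc$c + 1 / cc$d)
  dplyr::mutate(tbl,
    ror = ror,
    ror_lo = exp(log(ror) - 1.96 * se),
    ror_hi = exp(log(ror) + 1.96 * se),
    corrected = cc$corrected
  )
}

#' Proportional reporting ratio with Pearson chi-squared
#'
#' The chi-squared statistic is the closed form
#' (ad-bc)^2 N / ((a+b)(c+d)(a+c)(b+d)), algebraically equal to Pearson's
#' chi-squared without continuity correction.
#'
#' @inheritParams ror_ci
#' @return `tbl` with columns `prr`, `chi2`, `corrected` added.
#' @export
prr_chi2 <- function(tbl) {
  cc <- correct_cells(tbl)
  a <- cc$a; b <- cc$b; c <- cc$c; d <- cc$d
  nn <- a + b + c + d
  prr_val <- (a * (c + d)) / (c * (a + b))
  chi2_val <- (a * d - b * c)^2 * nn / ((a + b) * (c + d) * (a + c) * (b + d))
  dplyr::mutate(tbl, prr = prr_val, chi2 = chi2_val, corrected = cc$corrected)
}

# run expr with the RNG seeded, restoring the caller's RNG state afterwards
with_local_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# posterior draws of IC for one table under Dirichlet(1,1,1,1) prior
ic_posterior_moments <- function(a, b, c, d, n_draws) {
  g <- matrix(rgamma(4L * n_draws, shape = c(a, b, c, d) + 1), nrow = 4L)
  p <- sweep(g, 2L, colSums(g), "/")
  ic_draws <- log2(p[1L, ]) - log2((p[1L, ] + p[2L, ]) * (p[1L, ] + p[3L, ]))
  c(mean = mean(ic_draws), var = var(ic_draws))
}

#' BCPNN information component with Monte-Carlo credible bounds
#'
#' The point IC is `log2(a N / ((a+b)(a+c)))`. E(IC) and V(IC) are the
#' posterior mean and variance of `log2(p11 / (p1. p.1))` under a
#' Dirichlet(1,1,1,1) prior updated with the observed cells, estimated from
#' `n_draws` seeded Monte-Carlo draws; the credible bounds are
#' `E(IC) +/- 2 sqrt(V(IC))`. Rows are processed in order from a single
#' seeded stream, so fixed (table, n_draws, seed) gives identical bounds.
#'
#' @inheritParams ror_ci
#' @param n_draws Number of posterior draws per table (>= 1e4).
#' @param seed Integer seed for the draws; the caller's RNG state is
#'   preserved.
#' @return `tbl` with columns `ic`, `ic025`, `ic975`, `corrected` added.
#' @export
ic_ci <- function(tbl, n_draws = 1e5, seed = 20240101) {
  if (n_draws < 1e4) abort("n_draws must be at least 1e4 for stable bounds.")
  cc <- correct_cells(tbl)
  n <- cc$a + cc$b + cc$c + cc$d
  ic <- log2(cc$a * n / ((cc$a + cc$b) * (cc$a + cc$c)))
  mom <- with_local_seed(seed, {
    vapply(seq_along(cc$a), function(i) {
      ic_posterior_moments(cc$a[i], cc$b[i], cc$c[i], cc$d[i], n_draws)
    }, c(mean = 0, var = 0))
  })
  dplyr::mutate(tbl,
    ic = ic,
    ic025 = mom["mean", ] - 2 * sqrt(mom["var", ]),
    ic975 = mom["mean", ] + 2 * sqrt(mom["var", ]),
    corrected = cc$corrected
  )
}

#' Default positivity thresholds
#'
#' ROR: a >= 3 and CI lower bound > 1. PRR: a >= 3, PRR >= 2,
#' chi-squared >= 4. BCPNN: IC025 > 0.
#' @return Named list of threshold values.
#' @export
signal_thresholds <- function() {
  list(min_a = 3, ror_lo_gt = 1, prr_ge = 2, chi2_ge = 4, ic025_gt = 0)
}

#' Apply the positivity criteria to computed statistics
#'
#' The consensus flag `positive` is true when any of the three methods'
#' criteria are met. The raw `a` (before any continuity correction) governs
#' the a >= 3 requirement.
#'
#' @param stats Tibble with columns `a`, `ror_lo`, `prr`, `chi2`, `ic025`.
#' @param thresholds See [signal_thresholds()].
#' @return `stats` with logical columns `flag_ror`, `flag_prr`,
#'   `flag_bcpnn`, `positive` added.
#' @export
evaluate_criteria <- function(stats, thresholds = signal_thresholds()) {
  dplyr::mutate(stats,
    flag_ror = .data$a >= thresholds$min_a & .data$ror_lo > thresholds$ror_lo_gt,
    flag_prr = .data$a >= thresholds$min_a & .data$prr >= thresholds$prr_ge &
      .data$chi2 >= thresholds$chi2_ge,
    flag_bcpnn = .data$ic025 > thresholds$ic025_gt,
    positive = .data$flag_ror | .data$flag_prr | .data$flag_bcpnn
  )
}

#' All three disproportionality statistics plus positivity flags
#'
#' Convenience wrapper running [ror_ci()], [prr_chi2()], [ic_ci()] and
#' [evaluate_criteria()] on a table of cell counts.
#'
#' @inheritParams ic_ci
#' @param thresholds See [signal_thresholds()].
#' @return `tbl` with all statistic, bound, flag and `corrected` columns.
#' @examples
#' signal_stats(tibble::tibble(entity = "X", a = 20, b = 80, c = 100, d = 9800),
#'              n_draws = 1e4, seed = 1)
#' @export
signal_stats <- function(tbl, n_draws = 1e5, seed = 20240101,
                         thresholds = signal_thresholds()) {
  out <- ror_ci(tbl)
  out <- prr_chi2(out)
  out <- ic_ci(out, n_draws = n_draws, seed = seed)
  evaluate_criteria(out, thresholds)
}
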