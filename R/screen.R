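#' Configuration for a disproportionality screen
#'
#' @param top_n Number of top drugs to screen (default 30), ranked by event
#'   case count after exclusions.
#' @param pt_dictionary Event PT dictionary; defaults to the packaged
#'   coagulopathies set ([coagulopathy_pts()]).
#' @param synonym_map Drug-name synonym map ([default_synonyms()]).
#' @param exclusion_list Ingredients removed before ranking
#'   ([default_exclusion_list()]).
#' @param atc_map Ingredient -> therapeutic class map ([default_atc_map()]).
#' @param thresholds Positivity criteria ([signal_thresholds()]).
#' @param n_draws Monte-Carlo draws for the IC credible bounds.
#' @param seed Seed for the IC draws (recorded in the result).
#' @return List of class `screen_config`.
#' @export
screen_config <- function(top_n = 30,
                          pt_dictionary = coagulopathy_pts(),
                          synonym_map = default_synonyms(),
                          exclusion_list = default_exclusion_list(),
                          atc_map = default_atc_map(),
                          thresholds = signal_thresholds(),
                          n_draws = 1e5,
                          seed = 20240101) {
  if (top_n < 1) abort("top_n must be >= 1.")
  structure(
    list(top_n = as.integer(top_n), pt_dictionary = pt_dictionary,
         synonym_map = synonym_map, exclusion_list = exclusion_list,
         atc_map = atc_map, thresholds = thresholds,
         n_draws = n_draws, seed = as.integer(seed)),
    class = "screen_config"
  )
}

#' Rank drugs by event-case count
#'
#' Entities are ordered by `a` — the number of event cases with the entity
#' as primary suspect — descending, ties broken alphabetically, truncated to
#' `top_n`. Exclusions must already have been applied (they precede
#' ranking).
#'
#' @param drug_cases Tibble of distinct (caseid, ingredient) PS pairs,
#'   already restricted to non-excluded ingredients.
#' @param event_cases Character vector of event case ids.
#' @param top_n Number of entities to keep.
#' @return Tibble `ingredient`, `a`, ordered; all entities (with a message)
#'   when fewer than `top_n` exist.
#' @export
rank_top_drugs <- function(drug_cases, event_cases, top_n = 30) {
  ranked <- drug_cases %>%
    dplyr::group_by(.data$ingredient) %>%
    dplyr::summarise(a = sum(.data$caseid %in% event_cases), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$a), .data$ingredient)
  if (nrow(ranked) < top_n) {
    inform(paste0("Only ", nrow(ranked), " entities available for top_n = ",
                  top_n, "; returning all."))
  }
  head(ranked, top_n)
}

# shared cell construction: one row of (a,b,c,d) per entity, all against the
# same universe so a + c = total event cases for every entity
entity_cells <- function(entity_cases, event_cases, n_universe, entity_col = "ingredient") {
  n_event <- length(event_cases)
  entity_cases %>%
    dplyr::group_by(.data[[entity_col]]) %>%
    dplyr::summarise(
      a = sum(.data$caseid %in% event_cases),
      n_entity = dplyr::n(), .groups = "drop"
    ) %>%
    dplyr::mutate(
      b = .data$n_entity - .data$a,
      c = n_event - .data$a,
      d = n_universe - n_event - .data$b,
      n = n_universe
    ) %>%
    dplyr::select(dplyr::all_of(entity_col), "a", "b", "c", "d", "n")
}

#' Screen ranked single drugs
#'
#' One [signal_stats()] row per ranked entity; every 2x2 table uses the full
#' deduplicated case set as universe, so `a + c` equals the total event-case
#' count for every entity. Per-entity statistic failures are caught and
#' reported as `NA` rows rather than aborting the batch.
#'
#' @param ranked Output of [rank_top_drugs()].
#' @param drug_cases Distinct (caseid, ingredient) PS pairs (all entities,
#'   used for the entity margins).
#' @param event_cases Event case ids.
#' @param universe All deduplicated case ids.
#' @param config A [screen_config()].
#' @return Tibble of signal results in ranking order.
#' @export
screen_single_drugs <- function(ranked, drug_cases, event_cases, universe, config) {
  cells <- entity_cells(
    dplyr::semi_join(dplyr::distinct(drug_cases, .data$caseid, .data$ingredient),
                     ranked, by = "ingredient"),
    event_cases, length(unique(universe))
  )
  cells <- cells[match(ranked$ingredient, cells$ingredient), , drop = FALSE]
  out <- tryCatch(
    signal_stats(cells, n_draws = config$n_draws, seed = config$seed,
                 thresholds = config$thresholds),
    error = function(e) NULL
  )
  if (!is.null(out)) return(out)
  # fall back to per-entity computation so one degenerate table cannot
  # abort the batch
  dplyr::bind_rows(lapply(seq_len(nrow(cells)), function(i) {
    tryCatch(
      signal_stats(cells[i, ], n_draws = config$n_draws,
                   seed = config$seed + i, thresholds = config$thresholds),
      error = function(e) dplyr::mutate(cells[i, ], ror = NA_real_)
    )
  }))
}

#' Screen therapeutic classes
#'
#' For each class, the entity case set is the union of its member drugs'
#' case sets (a case with two member drugs counts once); results are ranked
#' by ROR descending. Classes with zero cases are skipped with a notice.
#'
#' @param drug_cases Distinct (caseid, ingredient) PS pairs restricted to
#'   the screened entities.
#' @param event_cases Event case ids.
#' @param universe All deduplicated case ids.
#' @param config A [screen_config()]; `config$atc_map` supplies the class of
#'   each ingredient.
#' @return Tibble of signal results, one row per class, ROR-descending.
#' @export
screen_groups <- function(drug_cases, event_cases, universe, config) {
  class_cases <- drug_cases %>%
    dplyr::mutate(atc_class = assign_group(.data$ingredient, config$atc_map)) %>%
    dplyr::filter(.data$atc_class != "Unknown") %>%
    dplyr::distinct(.data$caseid, .data$atc_class)
  if (nrow(class_cases) == 0) {
    inform("No screened entity maps to a known class; skipping class screen.")
    return(tibble())
  }
  cells <- entity_cells(class_cases, event_cases, length(unique(universe)),
                        entity_col = "atc_class")
  signal_stats(cells, n_draws = config$n_draws, seed = config$seed,
               thresholds = config$thresholds) %>%
    dplyr::arrange(dplyr::desc(.data$ror))
}

#' Stratified demographic summary of event cases
#'
#' Counts and percentages by sex, age band, reporting country (top 5 plus
#' "Others or unknown") and outcome. One outcome per case, chosen by
#' severity priority (DE > HO > LT > DS > CA > other), so every dimension
#' partitions the case total. Percentages are rounded half away from zero
#' to 1 decimal.
#'
#' @param cases Deduplicated event-case tibble with `sex`, `age_band`,
#'   `country` columns.
#' @param outcomes Optional tibble of outcome rows (`caseid`, `outc_cod`).
#' @return Tibble `dimension`, `stratum`, `count`, `percent`.
#' @export
demographic_summary <- function(cases, outcomes = NULL) {
  total <- nrow(cases)
  if (total == 0) {
    return(tibble(dimension = character(), stratum = character(),
                  count = integer(), percent = numeric()))
  }
  one_dim <- function(values, dimension, order = NULL) {
    d <- tibble(stratum = values) %>%
      dplyr::count(.data$stratum, name = "count") %>%
      dplyr::mutate(dimension = dimension,
                    percent = percent(.data$count, total, digits = 1))
    if (!is.null(order)) d <- d[order(match(d$stratum, order)), , drop = FALSE]
    dplyr::select(d, "dimension", "stratum", "count", "percent")
  }

  country <- ifelse(is.na(cases$country) | cases$country %in% c("", "Unknown"),
                    NA_character_, cases$country)
  top5 <- names(sort(table(country), decreasing = TRUE))
  top5 <- head(top5, 5)
  country_grp <- ifelse(!is.na(country) & country %in% top5,
                        country, "Others or unknown")

  out <- dplyr::bind_rows(
    one_dim(cases$sex, "sex", c("Male", "Female", "Unknown")),
    one_dim(cases$age_band, "age_band",
            c("<18", "18-64.9", "65-85", ">85", "Unknown")),
    one_dim(country_grp, "country", c(top5, "Others or unknown"))
  )

  if (!is.null(outcomes) && nrow(outcomes) > 0) {
    severity <- c("DE", "HO", "LT", "DS", "CA")
    per_case <- outcomes %>%
      dplyr::semi_join(cases, by = "caseid") %>%
      dplyr::mutate(rank = match(.data$outc_cod, severity)) %>%
      dplyr::arrange(.data$caseid, .data$rank) %>%
      dplyr::distinct(.data$caseid, .keep_all = TRUE)
    oc <- setNames(per_case$outc_cod, per_case$caseid)[cases$caseid]
    oc <- ifelse(is.na(oc) | !oc %in% severity, "Others or unknown", oc)
    out <- dplyr::bind_rows(
      out, one_dim(oc, "outcome", c(severity, "Others or unknown"))
    )
  }
  out
}

#' Annual trend of event-case counts
#'
#' Counts event cases by receipt year (from `fda_dt`); the year range is
#' completed with zero-filled gaps so the trend is plot-ready.
#'
#' @param cases Deduplicated event-case tibble with `fda_dt`.
#' @return Tibble `year` (integer), `n_cases`.
#' @export
annual_trend <- function(cases) {
  yr <- suppressWarnings(as.integer(substr(cases$fda_dt, 1, 4)))
  yr <- yr[!is.na(yr)]
  if (length(yr) == 0) return(tibble(year = integer(), n_cases = integer()))
  tibble(year = yr) %>%
    dplyr::count(.data$year, name = "n_cases") %>%
    tidyr::complete(year = tidyr::full_seq(.data$year, 1),
                    fill = list(n_cases = 0L)) %>%
    dplyr::mutate(year = as.integer(.data$year))
}

#' Run the full coagulopathy disproportionality screen
#'
#' End-to-end orchestration: deduplicate reports into cases, flag event
#' cases against the PT dictionary, normalize drug names, keep
#' primary-suspect mentions, apply the anticoagulant/antiplatelet
#' exclusions, rank the top `top_n` drugs by event-case count, compute
#' single-drug and class-level disproportionality statistics, and produce
#' the descriptive summaries (demographics, PT distribution, annual trend).
#' Fixed input + config + seed gives identical output tables.
#'
#' @param x A `faers_case_set` (from [assemble_cases()] /
#'   [read_faers_package()]) or an `srs_db` (from [simulate_srs()]).
#' @param config A [screen_config()].
#' @return Object of class `pv_screen` with elements `signals`, `groups`,
#'   `demographics`, `pt_distribution`, `trend`, `dedup`, `drop_report`,
#'   `n_cases`, `n_event_cases`, `config`. Use [tidy()] for the signal
#'   table, [glance()] for the one-row summary, [autoplot()] for figures.
#' @export
pv_screen <- function(x, config = screen_config()) {
  if (inherits(x, "srs_db")) {
    x <- assemble_cases(list(DEMO = x$demo, DRUG = x$drug, REAC = x$reac,
                             OUTC = x$outc, THER = x$ther, INDI = x$indi,
                             RPSR = x$rpsr))
  }
  stopifnot(inherits(x, "faers_case_set"))

  cases <- dedup_cases(x$cases)
  universe <- cases$caseid

  reactions <- dplyr::semi_join(x$reactions, cases, by = "primaryid")
  flags <- flag_event_cases(reactions, config$pt_dictionary)
  event_cases <- unique(flags$caseid)

  mentions <- dplyr::semi_join(x$drugs, cases, by = "primaryid")
  mentions <- filter_role(mentions, "PS")
  norm <- normalize_drug_name(mentions$drugname, synonym_map = config$synonym_map)
  mentions$ingredient <- norm$ingredient
  drop_report <- tibble(
    n_ps_mentions = nrow(mentions),
    n_unresolved = sum(norm$status == "unresolved"),
    n_unmapped = sum(norm$status == "unmapped")
  )
  drug_cases <- mentions %>%
    dplyr::filter(!is.na(.data$ingredient)) %>%
    dplyr::distinct(.data$caseid, .data$ingredient)

  kept_entities <- apply_exclusions(unique(drug_cases$ingredient),
                                    config$exclusion_list)
  drug_cases_kept <- dplyr::filter(drug_cases, .data$ingredient %in% kept_entities)

  ranked <- rank_top_drugs(drug_cases_kept, event_cases, config$top_n)
  signals <- screen_single_drugs(ranked, drug_cases_kept, event_cases,
                                 universe, config)
  groups <- screen_groups(
    dplyr::semi_join(drug_cases_kept, ranked, by = "ingredient"),
    event_cases, universe, config
  )

  ev <- dplyr::filter(cases, .data$caseid %in% event_cases)
  structure(
    list(
      signals = signals,
      groups = groups,
      demographics = demographic_summary(ev, x$outcomes),
      pt_distribution = pt_distribution(flags),
      trend = annual_trend(ev),
      dedup = dedup_report(cases),
      drop_report = drop_report,
      n_cases = length(universe),
      n_event_cases = length(event_cases),
      config = config
    ),
    class = "pv_screen"
  )
}

#' @export
print.pv_screen <- function(x, ...) {
  cat("Disproportionality screen\n")
  cat(sprintf("  cases: %d (events: %d)\n", x$n_cases, x$n_event_cases))
  cat(sprintf("  screened drugs: %d, positive: %d\n",
              nrow(x$signals), sum(x$signals$positive, na.rm = TRUE)))
  cat(sprintf("  classes screened: %d\n", nrow(x$groups)))
  invisible(x)
}

#' Tidy the signal table of a screen
#'
#' @param x A `pv_screen`.
#' @param level `"drug"` (default) for single-drug results or `"class"`.
#' @param ... Unused.
#' @return Tibble of signal results.
#' @method tidy pv_screen
#' @export
tidy.pv_screen <- function(x, level = c("drug", "class"), ...) {
  level <- match.arg(level)
  if (level == "drug") x$signals else x$groups
}

#' One-row summary of a screen
#'
#' @param x A `pv_screen`.
#' @param ... Unused.
#' @return One-row tibble: case counts, entity counts, positives per method.
#' @method glance pv_screen
#' @export
glance.pv_screen <- function(x, ...) {
  tibble(
    n_cases = x$n_cases,
    n_event_cases = x$n_event_cases,
    n_entities = nrow(x$signals),
    n_positive = sum(x$signals$positive, na.rm = TRUE),
    n_flag_ror = sum(x$signals$flag_ror, na.rm = TRUE),
    n_flag_prr = sum(x$signals$flag_prr, na.rm = TRUE),
    n_flag_bcpnn = sum(x$signals$flag_bcpnn, na.rm = TRUE)
  )
}

#' Plot a screen result
#'
#' `type = "forest"` draws ROR with 95% CI per screened drug on a log scale
#' (the dashed line at 1 is the no-association reference); `"classes"` does
#' the same per therapeutic class; `"trend"` shows annual event-case counts.
#'
#' @param object A `pv_screen`.
#' @param type One of `"forest"`, `"classes"`, `"trend"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pv_screen
#' @export
autoplot.pv_screen <- function(object, type = c("forest", "classes", "trend"), ...) {
  type <- match.arg(type)
  if (type == "trend") {
    return(
      ggplot2::ggplot(object$trend, ggplot2::aes(x = .data$year, y = .data$n_cases)) +
        ggplot2::geom_col(fill = "steelblue") +
        ggplot2::labs(x = "Receipt year", y = "Event cases",
                      title = "Annual coagulopathy report trend") +
        ggplot2::theme_minimal()
    )
  }
  d <- if (type == "forest") {
    dplyr::rename(object$signals, entity = "ingredient")
  } else {
    dplyr::rename(object$groups, entity = "atc_class")
  }
  d <- dplyr::filter(d, !is.na(.data$ror))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$ror,
                                  y = stats::reorder(.data$entity, .data$ror),
                                  colour = .data$positive)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$ror_lo, xmax = .data$ror_hi),
                            height = 0.3) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ROR (95% CI, log scale)", y = NULL, colour = "Positive",
                  title = if (type == "forest") "Single-drug signals"
                          else "Therapeutic-class signals") +
    ggplot2::theme_minimal()
}

#' Write the screen's output tables to a directory
#'
#' Emits `signals.csv`, `groups.csv`, `demographics.csv`,
#' `pt_distribution.csv`, `trend.csv` and a `run_metadata.txt` recording the
#' seed, thresholds and package version. Statistics are rounded half away
#' from zero to 2 decimals in the written tables (full precision stays in
#' the R object).
#'
#' @param x A `pv_screen`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_screen <- function(x, dir) {
  stopifnot(inherits(x, "pv_screen"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  round_stats <- function(d) {
    dplyr::mutate(d, dplyr::across(
      dplyr::any_of(c("ror", "ror_lo", "ror_hi", "prr", "chi2",
                      "ic", "ic025", "ic975")),
      ~ round_half_up(.x, 2)
    ))
  }
  readr::write_csv(round_stats(x$signals), file.path(dir, "signals.csv"), progress = FALSE)
  readr::write_csv(round_stats(x$groups), file.path(dir, "groups.csv"), progress = FALSE)
  readr::write_csv(x$demographics, file.path(dir, "demographics.csv"), progress = FALSE)
  readr::write_csv(x$pt_distribution, file.path(dir, "pt_distribution.csv"), progress = FALSE)
  readr::write_csv(x$trend, file.path(dir, "trend.csv"), progress = FALSE)
  meta <- c(
    paste0("pvsignal version: ", as.character(utils::packageVersion("pvsignal"))),
    paste0("seed: ", x$config$seed),
    paste0("n_draws: ", format(x$config$n_draws, scientific = FALSE)),
    paste0("top_n: ", x$config$top_n),
    paste0("thresholds: ", paste(names(x$config$thresholds),
                                 unlist(x$config$thresholds),
                                 sep = "=", collapse = ", "))
  )
  writeLines(meta, file.path(dir, "run_metadata.txt"))
  invisible(dir)
}
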