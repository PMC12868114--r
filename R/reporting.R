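block_pct <- function(level, n) {
  tibble(level = as.character(level), n = as.integer(n),
         pct = 100 * n / sum(n))
}

quant_summary <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(tibble(n = 0L, mean = NA_real_, sd = NA_real_, median = NA_real_,
                  q1 = NA_real_, q3 = NA_real_, min = NA_real_,
                  max = NA_real_, degenerate = TRUE))
  }
  tibble(
    n = length(x),
    mean = mean(x),
    sd = if (length(x) > 1) sd(x) else 0,
    median = median(x),
    q1 = unname(quantile(x, 0.25)),
    q3 = unname(quantile(x, 0.75)),
    min = min(x),
    max = max(x),
    degenerate = length(x) < 2
  )
}

#' Demographic and clinical summary of a report universe
#'
#' Tabulates counts and percentages by sex, age group, reporting year,
#' reporter class, top-k reporting countries and outcome codes, plus
#' quantitative summaries of age, weight and (optionally) onset days. Each
#' categorical block uses its own denominator — the sum of that block's
#' counts — so within-block percentages always total 100. Note the country
#' block's convention: percentages are shares of the top-k subtotal, not of
#' all reports (the usual convention of published demographic tables for
#' this database); the outcome block's denominator is the total number of
#' outcome codes.
#'
#' @param cases Case tibble from [assemble_cases()].
#' @param onsets Optional onset tibble from [compute_onset()]; adds the
#'   onset-bin block and onset quantitative summary.
#' @param top_k_countries Number of countries in the country block.
#' @param clean_age If TRUE, ages above `max_plausible_age` are excluded
#'   from the quantitative age summary (they always remain in the age-group
#'   tabulation). Default FALSE: implausible outliers are retained
#'   as-reported.
#' @param max_plausible_age Cleaning threshold in years.
#' @param age_scheme Age bins, as in [subgroup_levels()].
#' @return Object of class `demographic_summary`: a named list of blocks
#'   (`sex`, `age_group`, `year`, `reporter`, `country`, `outcome`, and
#'   `onset_bin` if onsets are given; each a tibble `level`, `n`, `pct`)
#'   plus quantitative summaries `age`, `weight`, `onset` and the universe
#'   size `n_reports`.
#' @export
demographic_summary <- function(cases, onsets = NULL, top_k_countries = 5,
                                clean_age = FALSE, max_plausible_age = 120,
                                age_scheme = "results") {
  sex_tab <- cases %>% count(level = .data$sex) %>%
    with(block_pct(level, n))
  ages <- subgroup_levels(cases, "age", age_scheme)
  age_order <- c("<18", "18-44", "45-64", ">64", "18-60", ">60", "Unknown")
  age_tab <- tibble(level = ages) %>% count(.data$level) %>%
    arrange(match(.data$level, age_order)) %>%
    with(block_pct(level, n))
  year_tab <- cases %>% count(level = .data$year) %>% arrange(.data$level) %>%
    with(block_pct(level, n))
  rep_tab <- cases %>% count(level = .data$reporter_class) %>%
    arrange(desc(.data$n)) %>% with(block_pct(level, n))
  country_tab <- cases %>%
    filter(!is.na(.data$country)) %>%
    count(level = .data$country, sort = TRUE) %>%
    slice_head(n = top_k_countries) %>%
    with(block_pct(level, n))
  outcome_tab <- tibble(level = as.character(unlist(cases$outcomes))) %>%
    count(.data$level) %>%
    arrange(desc(.data$n)) %>%
    with(block_pct(level, n))

  age_vals <- cases$age_years
  if (clean_age) age_vals <- age_vals[is.na(age_vals) | age_vals <= max_plausible_age]
  out <- list(
    n_reports = nrow(cases),
    sex = sex_tab,
    age_group = age_tab,
    year = year_tab,
    reporter = rep_tab,
    country = country_tab,
    outcome = outcome_tab,
    age = dplyr::bind_cols(quant_summary(age_vals),
                           tibble(n_missing = sum(is.na(cases$age_years)))),
    weight = dplyr::bind_cols(quant_summary(cases$weight_kg),
                              tibble(n_missing = sum(is.na(cases$weight_kg))))
  )
  if (!is.null(onsets)) {
    out$onset_bin <- onsets %>% count(level = .data$bin, .drop = FALSE) %>%
      with(block_pct(level, n))
    out$onset <- quant_summary(onsets$onset_days)
  }
  structure(out, class = "demographic_summary")
}

#' @export
print.demographic_summary <- function(x, ...) {
  cat(sprintf("<demographic_summary> %d reports\n", x$n_reports))
  for (nm in c("sex", "age_group", "country", "outcome", "onset_bin")) {
    if (is.null(x[[nm]])) next
    cat(sprintf("-- %s --\n", nm))
    tab <- x[[nm]]
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-12s %8d (%.1f%%)\n", tab$level[i], tab$n[i], tab$pct[i]))
    }
  }
  invisible(x)
}

#' Check that every block's percentages are self-consistent
#'
#' Recomputes each categorical block's percentages from its own counts and
#' verifies they total 100 within rounding.
#'
#' @param summary A `demographic_summary`.
#' @param tol Allowed deviation of the block total from 100.
#' @return TRUE invisibly; aborts on inconsistency.
#' @export
check_summary_consistency <- function(summary, tol = 0.2) {
  blocks <- c("sex", "age_group", "year", "reporter", "country", "outcome",
              "onset_bin")
  for (nm in intersect(blocks, names(summary))) {
    tab <- summary[[nm]]
    if (nrow(tab) == 0) next
    recomputed <- 100 * tab$n / sum(tab$n)
    if (max(abs(recomputed - tab$pct)) > 1e-8 ||
        abs(sum(tab$pct) - 100) > tol) {
      abort(sprintf("block '%s' percentages are not self-consistent", nm))
    }
  }
  invisible(TRUE)
}

#' Quantitative and binned summary of onset times
#'
#' @param onsets Onset tibble from [compute_onset()] (columns `onset_days`,
#'   `bin`), or any tibble with those columns.
#' @return List with `stats` (one-row tibble: n, mean, sd with the n-1
#'   denominator, median, quartiles by linear interpolation, min, max,
#'   degenerate flag — a single observation reports sd 0 and
#'   `degenerate = TRUE`) and `bins` (tibble level/n/pct). An empty input
#'   yields an explicit empty summary (`n = 0`, all statistics `NA`).
#' @export
onset_summary <- function(onsets) {
  stats <- quant_summary(onsets$onset_days)
  bins <- onsets %>% count(level = .data$bin, .drop = FALSE) %>%
    with(block_pct(level, n))
  if (nrow(onsets) == 0) bins$pct <- rep(NA_real_, nrow(bins))
  list(stats = stats, bins = bins)
}

#' Death versus non-death demographic comparison
#'
#' Classifies each report by presence of the death outcome code (`DE`),
#' cross-tabulates against sex and age group, and tests each block with the
#' Pearson chi-square test. Percentages are shares of the block's own grand
#' total (the sum of every cell in that block), the convention of published
#' death/non-death tables for this database. A block with an all-zero row or
#' column is not tested (reason recorded).
#'
#' @param cases Case tibble from [assemble_cases()].
#' @param age_scheme Age bins, as in [subgroup_levels()].
#' @return Object of class `mortality_comparison`: per-block tibbles
#'   (`level`, `death_n`, `death_pct`, `nondeath_n`, `nondeath_pct`),
#'   p-values `sex_p`, `age_p` (NA with `*_skip_reason` when untestable) and
#'   counts `n_death`, `n_nondeath`.
#' @export
mortality_comparison <- function(cases, age_scheme = "results") {
  death <- purrr::map_lgl(cases$outcomes, ~ "DE" %in% .x)
  blocks <- list(
    sex = ifelse(cases$sex %in% c("F", "M"), cases$sex, "UNK"),
    age = subgroup_levels(cases, "age", age_scheme)
  )
  out <- list(n_death = sum(death), n_nondeath = sum(!death))
  for (nm in names(blocks)) {
    lev <- blocks[[nm]]
    tab <- table(factor(lev, levels = unique(lev)), factor(death, c(TRUE, FALSE)))
    grand <- sum(tab)
    block <- tibble(
      level = rownames(tab),
      death_n = as.integer(tab[, "TRUE"]),
      death_pct = 100 * tab[, "TRUE"] / grand,
      nondeath_n = as.integer(tab[, "FALSE"]),
      nondeath_pct = 100 * tab[, "FALSE"] / grand
    )
    testable <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
    if (nrow(testable) >= 2 && ncol(testable) >= 2) {
      p <- suppressWarnings(chisq.test(testable)$p.value)
      reason <- NA_character_
    } else {
      p <- NA_real_
      reason <- "all-zero row or column; test skipped"
    }
    out[[nm]] <- block
    out[[paste0(nm, "_p")]] <- p
    out[[paste0(nm, "_skip_reason")]] <- reason
  }
  structure(out, class = "mortality_comparison")
}

#' @export
print.mortality_comparison <- function(x, ...) {
  cat(sprintf("<mortality_comparison> %d death / %d non-death cases\n",
              x$n_death, x$n_nondeath))
  for (nm in c("sex", "age")) {
    cat(sprintf("-- %s (P = %s) --\n", nm,
                format(signif(x[[paste0(nm, "_p")]], 3))))
    tab <- x[[nm]]
    for (i in seq_len(nrow(tab))) {
      cat(sprintf("  %-8s death %6d (%.2f%%)   non-death %6d (%.2f%%)\n",
                  tab$level[i], tab$death_n[i], tab$death_pct[i],
                  tab$nondeath_n[i], tab$nondeath_pct[i]))
    }
  }
  invisible(x)
}

#' Run the full pipeline on a synthetic or on-disk universe
#'
#' Orchestrates generation (or reading), deduplication, case assembly,
#' target-drug restriction, time-to-onset, disproportionality statistics,
#' signal criteria, ranked tables, demographic/onset/mortality summaries,
#' and writes every table plus a step-by-step flow report and a
#' machine-readable run manifest. Deterministic given the config seed: two
#' runs with the same config produce byte-identical tables.
#'
#' @param config A [synthetic_config()] (synthetic mode) or a named list of
#'   table paths as accepted by [read_quarter()] (file mode).
#' @param target_names Name variants of the target drug.
#' @param out_dir Output directory; created if needed. `NULL` skips writing.
#' @param soc_map Optional PT-to-SOC tibble; defaults to the synthetic map
#'   when `config` is a `synthetic_config`.
#' @param k Rows kept in the ranked signal tables.
#' @return Invisibly, a list with elements `cases`, `stats`, `results`,
#'   `top_frequency`, `top_intensity`, `onsets`, `demography`, `mortality`,
#'   `flow` (the filter-chain counts) and `manifest`.
#' @export
run_pipeline <- function(config, target_names = venlafaxine_names,
                         out_dir = NULL, soc_map = NULL, k = 30) {
  flow <- list()
  if (inherits(config, "synthetic_config")) {
    gen <- generate_faers(config)
    records <- gen$records
    if (is.null(soc_map)) soc_map <- synthetic_meddra_map(config)
    seed <- config$seed
  } else {
    records <- read_quarter(config)
    seed <- NA_integer_
  }
  flow$raw_reports <- nrow(records$demo)
  dedup <- deduplicate(records)
  flow$deduplicated <- nrow(dedup$demo)
  cases <- assemble_cases(dedup)
  flow$with_reactions <- nrow(cases)
  target_cases <- filter_primary_suspect(cases, target_names)
  flow$primary_suspect <- nrow(target_cases)
  onsets <- compute_onset(target_cases, target_names)
  flow$onset_computable <- nrow(onsets)

  empty_universe <- nrow(target_cases) == 0
  if (empty_universe) {
    stats <- tibble()
    results <- tibble()
    topf <- tibble()
    topi <- tibble()
  } else {
    stats <- disproportionality_stats(cases, target_names, soc_map = soc_map)
    results <- evaluate_criteria(stats)
    topf <- rank_by_frequency(results, k)
    topi <- rank_by_intensity(results, k)
  }
  demography <- demographic_summary(target_cases, onsets)
  mortality <- mortality_comparison(target_cases)

  manifest <- list(
    package = "faersignal",
    package_version = as.character(utils::packageVersion("faersignal")),
    r_version = as.character(getRversion()),
    seed = seed,
    target_names = target_names,
    flow = flow,
    n_flagged_all_four = if (nrow(results) > 0) sum(results$meets_all_four) else 0L,
    status = if (empty_universe) "EMPTY" else "OK"
  )

  if (!is.null(out_dir)) {
    if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
    wt <- function(x, f) readr::write_tsv(x, file.path(out_dir, f), na = "")
    if (nrow(results) > 0) {
      wt(results, "statistics.tsv")
      wt(topf, "top_frequency.tsv")
      wt(topi, "top_intensity.tsv")
    }
    wt(onsets, "onsets.tsv")
    wt(tibble(step = names(flow), n = unlist(flow)), "flow_report.tsv")
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    if (empty_universe) {
      writeLines("no primary-suspect cases; statistics not computed",
                 file.path(out_dir, "EMPTY"))
    }
  }
  invisible(list(cases = cases, target_cases = target_cases, stats = stats,
                 results = results, top_frequency = topf, top_intensity = topi,
                 onsets = onsets, demography = demography,
                 mortality = mortality, flow = flow, manifest = manifest))
}
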