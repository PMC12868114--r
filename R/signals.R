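#' Apply the four-algorithm signal criteria
#'
#' Flags each PT row by the established thresholds: ROR requires at least
#' `min_n` case reports and the lower 95% confidence bound above 1; PRR uses
#' the Evans rule (n >= `min_n`, PRR >= 2 and chi-square >= 4; the chi-square
#' companion can be dropped via `use_chi2 = FALSE`); BCPNN requires IC025
#' above 0; MGPS requires EBGM05 above 2. `meets_all_four` is the conjunction
#' of the four per-method flags. A non-estimable ROR (zero cell) fails the
#' ROR criterion.
#'
#' @param stats Statistics tibble with columns `n`, `ror_low`, `prr`, `chi2`,
#'   `ic025`, `ebgm05` (e.g. from [disproportionality_stats()], or printed
#'   rows assembled by hand).
#' @param min_n Minimum case-report count for the frequentist criteria.
#' @param prr_threshold,chi2_threshold Evans-rule thresholds for PRR.
#' @param use_chi2 Include the chi-square >= 4 component in the PRR flag.
#' @return `stats` with added logical columns `flag_ror`, `flag_prr`,
#'   `flag_ic`, `flag_ebgm`, `meets_all_four`.
#' @export
evaluate_criteria <- function(stats, min_n = 3, prr_threshold = 2,
                              chi2_threshold = 4, use_chi2 = TRUE) {
  need <- c("n", "ror_low", "prr", "chi2", "ic025", "ebgm05")
  missing <- setdiff(need, names(stats))
  if (length(missing) > 0) {
    abort(paste0("evaluate_criteria: missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  out <- mutate(stats,
    flag_ror = .data$n >= min_n &
      !is.na(.data$ror_low) & .data$ror_low > 1,
    flag_prr = .data$n >= min_n &
      !is.na(.data$prr) & .data$prr >= prr_threshold &
      (!use_chi2 | .data$chi2 >= chi2_threshold),
    flag_ic = !is.na(.data$ic025) & .data$ic025 > 0,
    flag_ebgm = !is.na(.data$ebgm05) & .data$ebgm05 > 2
  )
  mutate(out, meets_all_four = .data$flag_ror & .data$flag_prr &
           .data$flag_ic & .data$flag_ebgm)
}

signal_filter <- function(results, criteria) {
  switch(criteria,
    all4 = filter(results, .data$meets_all_four),
    any = filter(results, .data$flag_ror | .data$flag_prr |
                   .data$flag_ic | .data$flag_ebgm),
    ror = filter(results, .data$flag_ror),
    prr = filter(results, .data$flag_prr),
    ic = filter(results, .data$flag_ic),
    ebgm = filter(results, .data$flag_ebgm),
    abort(sprintf("unknown criteria '%s'", criteria))
  )
}

#' Top signals ranked by reporting frequency
#'
#' Keeps flagged rows (by default those meeting all four criteria) and ranks
#' by case-report count `n` descending, breaking ties by EBGM descending and
#' then PT lexicographically.
#'
#' @param results Evaluated statistics from [evaluate_criteria()].
#' @param k Number of rows to keep.
#' @param criteria One of `"all4"` (default), `"any"`, `"ror"`, `"prr"`,
#'   `"ic"`, `"ebgm"`.
#' @return The top-`k` tibble (fewer rows if fewer qualify).
#' @export
rank_by_frequency <- function(results, k = 30, criteria = "all4") {
  signal_filter(results, criteria) %>%
    arrange(desc(.data$n), desc(.data$ebgm), .data$pt) %>%
    slice_head(n = k)
}

#' Top signals ranked by signal intensity
#'
#' As [rank_by_frequency()] but ordered by EBGM descending (ties: `n`
#' descending, then PT), surfacing rare but strongly disproportionate
#' events.
#'
#' @inheritParams rank_by_frequency
#' @export
rank_by_intensity <- function(results, k = 30, criteria = "all4") {
  signal_filter(results, criteria) %>%
    arrange(desc(.data$ebgm), desc(.data$n), .data$pt) %>%
    slice_head(n = k)
}

age_bins_results <- function(age) {
  dplyr::case_when(
    is.na(age) ~ "Unknown",
    age < 18 ~ "<18",
    age <= 44 ~ "18-44",
    age <= 64 ~ "45-64",
    TRUE ~ ">64"
  )
}

age_bins_methods <- function(age) {
  dplyr::case_when(
    is.na(age) ~ "Unknown",
    age < 18 ~ "<18",
    age <= 60 ~ "18-60",
    TRUE ~ ">60"
  )
}

#' Assign subgroup strata to cases
#'
#' @param cases Case tibble.
#' @param variable `"sex"`, `"age"` or `"region"`.
#' @param age_scheme `"results"` for bins `<18, 18-44, 45-64, >64` (the
#'   reproduction target of the stratified tables) or `"methods"` for
#'   `<18, 18-60, >60`.
#' @return Character vector of stratum labels (missing values map to
#'   `"Unknown"`).
#' @export
subgroup_levels <- function(cases, variable = c("sex", "age", "region"),
                            age_scheme = c("results", "methods")) {
  variable <- match.arg(variable)
  age_scheme <- match.arg(age_scheme)
  switch(variable,
    sex = ifelse(cases$sex %in% c("F", "M"), cases$sex, "Unknown"),
    age = if (age_scheme == "results") age_bins_results(cases$age_years)
          else age_bins_methods(cases$age_years),
    region = ifelse(is.na(cases$country) | cases$country == "",
                    "Unknown", cases$country)
  )
}

#' Stratified re-analysis of the target drug
#'
#' Restricts the universe to each stratum of the chosen variable, rebuilds
#' the contingency tables, re-fits the shrinkage prior within the stratum
#' (falling back to the diffuse prior, with a message, when the stratum has
#' fewer than 100 qualifying pairs), recomputes all four statistics and the
#' signal flags. The `Unknown` stratum (missing values) is tabulated too but
#' marked `tested = FALSE`.
#'
#' @inheritParams disproportionality_stats
#' @inheritParams subgroup_levels
#' @param k Optional truncation of each stratum's table to its top-k by
#'   frequency among flagged rows (`NULL` keeps every PT).
#' @return Tibble of per-stratum evaluated statistics with leading columns
#'   `variable`, `stratum`, `tested`.
#' @export
subgroup_analysis <- function(cases, target_names = venlafaxine_names,
                              variable = c("sex", "age", "region"),
                              age_scheme = c("results", "methods"),
                              soc_map = NULL, k = NULL) {
  variable <- match.arg(variable)
  age_scheme <- match.arg(age_scheme)
  strata <- subgroup_levels(cases, variable, age_scheme)
  levels <- unique(strata)
  known <- setdiff(levels, "Unknown")
  ordered_levels <- c(sort(known), intersect("Unknown", levels))
  purrr::map_dfr(ordered_levels, function(lev) {
    sub <- cases[strata == lev, ]
    stats <- disproportionality_stats(sub, target_names, soc_map = soc_map)
    res <- evaluate_criteria(stats)
    if (!is.null(k)) res <- rank_by_frequency(res, k)
    dplyr::bind_cols(
      tibble(variable = variable, stratum = lev, tested = lev != "Unknown")[
        rep(1, nrow(res)), ],
      res
    )
  })
}
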