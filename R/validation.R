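scan_with_stats <- function(cases, min_n = 3) {
  full <- contingency_scan(cases, complete = TRUE)
  prior <- if (sum(full$a >= 1) >= 100) gps_fit(full) else gps_diffuse_prior()
  full %>%
    filter(.data$a >= min_n) %>%
    add_ror() %>%
    add_prr() %>%
    add_chi2() %>%
    add_ic() %>%
    add_ebgm(prior) %>%
    mutate(n = .data$a) %>%
    evaluate_criteria()
}

#' Null calibration of the signal criteria
#'
#' Generates replicate universes under the global null (every relative
#' reporting rate 1, see [validation_config()]), evaluates all four criteria
#' on every (drug, PT) pair with at least `min_n` reports, and reports the
#' flagged fraction. Because every association in these universes is a
#' sampling fluctuation, the flagged fraction is the pipeline's
#' database-wide false-positive rate.
#'
#' @param seeds Integer vector, one replicate universe per seed.
#' @param n_cases Universe size per replicate.
#' @param min_n Minimum pair count entering evaluation (default 3, matching
#'   the signal rule's case threshold).
#' @return Tibble with one row per replicate: `seed`, `n_pairs`,
#'   `n_flagged`, `frac_flagged`.
#' @export
null_calibration <- function(seeds, n_cases = 20000, min_n = 3) {
  purrr::map_dfr(seeds, function(s) {
    gen <- generate_faers(validation_config("null", seed = s,
                                            n_cases = n_cases))
    cases <- assemble_cases(deduplicate(gen$records))
    res <- suppressWarnings(scan_with_stats(cases, min_n = min_n))
    tibble(seed = s, n_pairs = nrow(res),
           n_flagged = sum(res$meets_all_four),
           frac_flagged = sum(res$meets_all_four) / nrow(res))
  })
}

#' Recovery of injected signals
#'
#' Generates replicate universes from the canonical recovery design (target
#' pairs at lambda 8 and 4 plus a heterogeneous background, see
#' [validation_config()]), runs the full target-drug analysis, and reports
#' for each injected target pair whether all four criteria flagged it and
#' the EBGM it received.
#'
#' @inheritParams null_calibration
#' @return Tibble with one row per replicate and injected target pair:
#'   `seed`, `pt`, `lambda`, `a`, `expected`, `ebgm`, `flagged`.
#' @export
signal_recovery <- function(seeds, n_cases = 20000) {
  purrr::map_dfr(seeds, function(s) {
    cfg <- validation_config("recovery", seed = s, n_cases = n_cases)
    gen <- generate_faers(cfg)
    cases <- assemble_cases(deduplicate(gen$records))
    res <- suppressWarnings(
      evaluate_criteria(disproportionality_stats(cases))
    )
    inj <- cfg$signal_pairs[cfg$signal_pairs$drug == 1L, ]
    pt_names <- sprintf("PT_%03d", inj$pt)
    hit <- res[match(pt_names, res$pt), ]
    tibble(seed = s, pt = pt_names, lambda = inj$lambda,
           a = hit$a, expected = hit$expected, ebgm = hit$ebgm,
           flagged = dplyr::coalesce(hit$meets_all_four, FALSE))
  })
}
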