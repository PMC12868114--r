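#' Configuration for the synthetic report generator
#'
#' Describes a synthetic spontaneous-report universe: vocabulary sizes,
#' background reporting rates, injected drug-event signals with known
#' relative reporting rates, duplicate submissions, and field-level
#' missingness. The defaults emulate the structure of a large public
#' adverse-event extract: a Zipf-like drug popularity and PT background
#' distribution, roughly 64/25/11 female/male/unknown sex reporting shares,
#' about a third of ages missing, a small rate of implausible ages (data-entry
#' artifacts), and a bimodal time-to-onset mixture with an early peak inside
#' the first month and a long right tail beyond a year.
#'
#' @param n_cases Number of distinct cases to draw (before duplication).
#' @param n_drugs,n_pts,n_socs Vocabulary sizes for drugs, Preferred Terms
#'   and System Organ Classes.
#' @param target_drug_names Synonym strings under which drug 1 (the target)
#'   is reported; a random synonym is used on each drug row.
#' @param target_share Share of reports with the target drug (drug 1) as
#'   primary suspect when `drug_popularity` is NULL; default 2%, a realistic
#'   order of magnitude for a single widely used drug in a large
#'   spontaneous-report database (and small enough that an injected signal
#'   barely contaminates its own PT margin).
#' @param drug_popularity Probability vector (length `n_drugs`) for the
#'   primary-suspect drug of a case; default `target_share` for drug 1 and
#'   Zipf (weight proportional to 1/rank) over the rest.
#' @param background_pt_weights Probability vector (length `n_pts`) of PT
#'   reporting under no signal; default Zipf.
#' @param pts_per_case_mean Mean of the zero-truncated Poisson number of PT
#'   draws per case.
#' @param signal_pairs Tibble with columns `drug`, `pt` (integer indices) and
#'   `lambda` (relative reporting rate, all >= 1). Signals multiply the
#'   background weight of the pair's PT for cases whose suspect drug matches,
#'   with renormalisation, so the per-case PT count stays rate-stable.
#'   Default: none (global null).
#' @param duplicate_rate Probability that a case is re-submitted later with a
#'   new `primaryid` and strictly larger `fda_dt`.
#' @param missing_rate Named list of per-field missingness probabilities
#'   (`sex`, `age`, `weight`, `country`, `reporter`, `event_dt`, `start_dt`);
#'   partial replacement of the defaults is allowed.
#' @param sex_distribution Named probability vector over `F`, `M`, `UNK`.
#' @param age_mean,age_sd Normal age model (years), truncated to (0, 100].
#' @param implausible_age_rate Rate at which an age is replaced by an
#'   implausible outlier (uniform on 150-25000 years), emulating unit
#'   data-entry errors seen in real extracts.
#' @param weight_mean,weight_sd Normal weight model (kg), truncated to
#'   (0.4, 300].
#' @param onset_mix_short Mixing weight of the short-latency onset component.
#' @param onset_meanlog_short,onset_sdlog_short,onset_meanlog_long,onset_sdlog_long
#'   Log-normal parameters (days) of the short- and long-latency onset
#'   components.
#' @param outcome_probs Named vector of independent per-case probabilities of
#'   each outcome code (`DE`, `LT`, `HO`, `DS`, `CA`, `RI`, `OT`).
#' @param countries Character vector of reporter-country codes to sample
#'   (Zipf-weighted).
#' @param seed Integer seed; generation is fully deterministic given the
#'   config.
#' @return An object of class `synthetic_config` (named list).
#' @export
synthetic_config <- function(n_cases = 20000,
                             n_drugs = 40,
                             n_pts = 150,
                             n_socs = 12,
                             target_drug_names = venlafaxine_names,
                             target_share = 0.02,
                             drug_popularity = NULL,
                             background_pt_weights = NULL,
                             pts_per_case_mean = 2.5,
                             signal_pairs = NULL,
                             duplicate_rate = 0.05,
                             missing_rate = list(),
                             sex_distribution = c(F = 0.638, M = 0.250, UNK = 0.112),
                             age_mean = 47.4, age_sd = 18,
                             implausible_age_rate = 0.002,
                             weight_mean = 79.4, weight_sd = 20,
                             onset_mix_short = 0.45,
                             onset_meanlog_short = log(12), onset_sdlog_short = 1.0,
                             onset_meanlog_long = log(300), onset_sdlog_long = 1.1,
                             outcome_probs = c(DE = 0.056, LT = 0.05, HO = 0.20,
                                               DS = 0.046, CA = 0.02, RI = 0.01,
                                               OT = 0.15),
                             countries = c("US", "GB", "DE", "FR", "CA", "JP",
                                           "AU", "NL", "IT", "ES"),
                             seed = 1L) {
  if (is.null(drug_popularity)) {
    rest <- 1 / seq_len(n_drugs - 1)
    drug_popularity <- c(target_share, (1 - target_share) * rest / sum(rest))
  }
  if (is.null(background_pt_weights)) {
    background_pt_weights <- (1 / seq_len(n_pts))
    background_pt_weights <- background_pt_weights / sum(background_pt_weights)
  }
  if (is.null(signal_pairs)) {
    signal_pairs <- tibble(drug = integer(), pt = integer(), lambda = numeric())
  }
  signal_pairs <- as_tibble(signal_pairs)
  mr_default <- list(sex = 0.11, age = 0.35, weight = 0.55, country = 0.08,
                     reporter = 0.12, event_dt = 0.45, start_dt = 0.55)
  missing_rate <- modifyList(mr_default, as.list(missing_rate))

  cfg <- structure(list(
    n_cases = as.integer(n_cases), n_drugs = as.integer(n_drugs),
    n_pts = as.integer(n_pts), n_socs = as.integer(n_socs),
    target_drug_names = target_drug_names,
    drug_popularity = drug_popularity,
    background_pt_weights = background_pt_weights,
    pts_per_case_mean = pts_per_case_mean,
    signal_pairs = signal_pairs,
    duplicate_rate = duplicate_rate,
    missing_rate = missing_rate,
    sex_distribution = sex_distribution,
    age_mean = age_mean, age_sd = age_sd,
    implausible_age_rate = implausible_age_rate,
    weight_mean = weight_mean, weight_sd = weight_sd,
    onset_mix_short = onset_mix_short,
    onset_meanlog_short = onset_meanlog_short,
    onset_sdlog_short = onset_sdlog_short,
    onset_meanlog_long = onset_meanlog_long,
    onset_sdlog_long = onset_sdlog_long,
    outcome_probs = outcome_probs,
    countries = countries,
    seed = as.integer(seed)
  ), class = "synthetic_config")
  validate_synthetic_config(cfg)
}

validate_synthetic_config <- function(cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  if (length(cfg$drug_popularity) != cfg$n_drugs) {
    abort("drug_popularity must have length n_drugs")
  }
  if (length(cfg$background_pt_weights) != cfg$n_pts) {
    abort("background_pt_weights must have length n_pts")
  }
  if (abs(sum(cfg$drug_popularity) - 1) > 1e-9 ||
      abs(sum(cfg$background_pt_weights) - 1) > 1e-9 ||
      abs(sum(cfg$sex_distribution) - 1) > 1e-9) {
    abort("probability vectors must sum to 1 (tolerance 1e-9)")
  }
  sp <- cfg$signal_pairs
  if (nrow(sp) > 0) {
    if (!all(c("drug", "pt", "lambda") %in% names(sp))) {
      abort("signal_pairs needs columns drug, pt, lambda")
    }
    if (any(sp$lambda < 1)) abort("all signal lambda must be >= 1")
    if (any(sp$drug < 1 | sp$drug > cfg$n_drugs) ||
        any(sp$pt < 1 | sp$pt > cfg$n_pts)) {
      abort("signal_pairs indices out of range")
    }
  }
  rates <- c(cfg$duplicate_rate, unlist(cfg$missing_rate),
             cfg$implausible_age_rate, cfg$outcome_probs, cfg$onset_mix_short)
  if (any(rates < 0 | rates > 1)) abort("rates/probabilities must lie in [0, 1]")
  cfg
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat(sprintf(
    "<synthetic_config> %d cases, %d drugs, %d PTs, %d signal pair(s), seed %d\n",
    x$n_cases, x$n_drugs, x$n_pts, nrow(x$signal_pairs), x$seed
  ))
  invisible(x)
}

## Draw from a zero-truncated Poisson by inverse CDF (exact, vectorised).
rztpois <- function(n, mean) {
  lambda <- uniroot(function(l) l / (1 - exp(-l)) - mean,
                    interval = c(1e-8, mean * 2 + 10), tol = 1e-10)$root
  u <- runif(n, dpois(0, lambda), 1)
  qpois(u, lambda)
}

date_to_string <- function(d) format(d, "%Y%m%d")

## Run `expr` under the config seed without disturbing the caller's RNG state.
with_config_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

#' Generate a synthetic multi-table report universe with known ground truth
#'
#' Draws `n_cases` independent cases. Each case gets one primary-suspect drug
#' from the popularity distribution; its PT multiset is drawn from the
#' background PT weights multiplied by the case drug's injected relative
#' reporting rates and renormalised; demographics, outcome codes, therapy
#' start and event dates follow the configured distributions. A configurable
#' fraction of cases is re-submitted as a duplicate with a new `primaryid`
#' and strictly larger `fda_dt` (exercising the deduplication rule), and the
#' duplicate may fill in a previously missing sex field, emulating the
#' "most current information" behaviour of real resubmissions.
#'
#' @param config A [synthetic_config()].
#' @return A list with elements `records` (a [raw_record_set()]) and `truth`
#'   (class `ground_truth`): `truth$pair_lambda` holds the injected relative
#'   rate for every signal pair (lambda = 1 elsewhere by construction) and
#'   `truth$duplicates` the duplicate lineage (caseid, original and duplicate
#'   primaryid, submission order).
#' @export
generate_faers <- function(config) {
  cfg <- validate_synthetic_config(config)
  with_config_seed(cfg$seed, generate_faers_impl(cfg))
}

generate_faers_impl <- function(cfg) {
  n <- cfg$n_cases
  caseid <- as.character(20000000L + seq_len(n))
  primaryid <- paste0(caseid, "1")

  ## -- drugs ---------------------------------------------------------------
  drug_idx <- sample.int(cfg$n_drugs, n, replace = TRUE, prob = cfg$drug_popularity)
  drug_names <- c("TARGETDRUG", sprintf("DRUG_%03d", seq_len(cfg$n_drugs - 1)))
  synonyms <- cfg$target_drug_names
  drugname <- ifelse(
    drug_idx == 1L,
    toupper(synonyms[sample.int(length(synonyms), n, replace = TRUE)]),
    drug_names[drug_idx]
  )

  ## -- reactions: per-case PT multiset -------------------------------------
  k <- rztpois(n, cfg$pts_per_case_mean)
  case_of_draw <- rep.int(seq_len(n), k)
  pt_draws <- integer(length(case_of_draw))
  sig_drugs <- unique(cfg$signal_pairs$drug)
  plain <- !(drug_idx %in% sig_drugs)
  idx_plain <- which(plain[case_of_draw])
  if (length(idx_plain) > 0) {
    pt_draws[idx_plain] <- sample.int(cfg$n_pts, length(idx_plain),
                                      replace = TRUE,
                                      prob = cfg$background_pt_weights)
  }
  for (d in sig_drugs) {
    w <- cfg$background_pt_weights
    rows <- cfg$signal_pairs[cfg$signal_pairs$drug == d, ]
    w[rows$pt] <- w[rows$pt] * rows$lambda
    w <- w / sum(w)
    idx_d <- which(drug_idx[case_of_draw] == d)
    if (length(idx_d) > 0) {
      pt_draws[idx_d] <- sample.int(cfg$n_pts, length(idx_d),
                                    replace = TRUE, prob = w)
    }
  }
  pt_labels <- sprintf("PT_%03d", seq_len(cfg$n_pts))
  reac <- distinct(tibble(
    primaryid = primaryid[case_of_draw],
    caseid = caseid[case_of_draw],
    pt = pt_labels[pt_draws]
  ))

  ## -- dates ---------------------------------------------------------------
  origin <- as.Date("2004-01-01")
  horizon <- as.Date("2025-06-30")
  start_date <- origin + sample.int(as.integer(as.Date("2024-06-30") - origin),
                                    n, replace = TRUE)
  short <- runif(n) < cfg$onset_mix_short
  onset_days <- ceiling(ifelse(
    short,
    rlnorm(n, cfg$onset_meanlog_short, cfg$onset_sdlog_short),
    rlnorm(n, cfg$onset_meanlog_long, cfg$onset_sdlog_long)
  ))
  onset_days <- pmax(onset_days, 1)
  event_date <- start_date + (onset_days - 1)
  fda_date <- pmin(event_date + sample.int(90, n, replace = TRUE), horizon)
  fda_date <- pmax(fda_date, origin)

  ## -- demographics ---------------------------------------------------------
  sex <- names(cfg$sex_distribution)[
    sample.int(length(cfg$sex_distribution), n, replace = TRUE,
               prob = cfg$sex_distribution)]
  age <- pmin(pmax(rnorm(n, cfg$age_mean, cfg$age_sd), 0.1), 100)
  outlier <- runif(n) < cfg$implausible_age_rate
  age[outlier] <- runif(sum(outlier), 150, 25000)
  weight <- pmin(pmax(rnorm(n, cfg$weight_mean, cfg$weight_sd), 0.4), 300)
  occp <- sample(c("CN", "MD", "OT", "PH", "LW"), n, replace = TRUE,
                 prob = c(0.45, 0.25, 0.15, 0.1, 0.05))
  cw <- 1 / seq_along(cfg$countries)
  country <- sample(cfg$countries, n, replace = TRUE, prob = cw / sum(cw))

  mr <- cfg$missing_rate
  blank <- function(x, rate) ifelse(runif(length(x)) < rate, NA_character_, x)
  sex_f <- blank(sex, mr$sex)
  age_f <- blank(sprintf("%.0f", age), mr$age)
  wt_f <- blank(sprintf("%.1f", weight), mr$weight)
  country_f <- blank(country, mr$country)
  occp_f <- blank(occp, mr$reporter)
  event_f <- blank(date_to_string(event_date), mr$event_dt)
  start_f <- blank(date_to_string(start_date), mr$start_dt)

  demo <- tibble(
    primaryid = primaryid, caseid = caseid,
    fda_dt = date_to_string(fda_date),
    event_dt = event_f,
    age = age_f,
    age_cod = ifelse(is.na(age_f), NA_character_, "YR"),
    sex = sex_f,
    wt = wt_f,
    occp_cod = occp_f,
    reporter_country = country_f
  )
  drug <- tibble(
    primaryid = primaryid, caseid = caseid,
    drug_seq = "1", role_cod = "PS", drugname = drugname
  )
  ther <- tibble(
    primaryid = primaryid, caseid = caseid,
    dsg_drug_seq = "1", start_dt = start_f
  )

  ## -- outcomes -------------------------------------------------------------
  oc <- purrr::imap(as.list(cfg$outcome_probs), function(p, code) {
    hit <- which(runif(n) < p)
    tibble(primaryid = primaryid[hit], caseid = caseid[hit], outc_cod = code)
  })
  outc <- arrange(bind_rows(oc), .data$caseid, .data$outc_cod)
  if (nrow(outc) == 0) {
    outc <- tibble(primaryid = character(), caseid = character(),
                   outc_cod = character())
  }

  ## -- duplicate submissions ------------------------------------------------
  dup_idx <- which(runif(n) < cfg$duplicate_rate)
  dup_lineage <- tibble(caseid = character(), primaryid_original = character(),
                        primaryid_duplicate = character(), order = integer())
  if (length(dup_idx) > 0) {
    dup_case <- caseid[dup_idx]
    dup_pid <- paste0(dup_case, "2")
    dup_fda <- date_to_string(
      pmin(fda_date[dup_idx] + sample.int(300, length(dup_idx), replace = TRUE),
           horizon + 365))
    demo_dup <- demo[dup_idx, ]
    demo_dup$primaryid <- dup_pid
    demo_dup$fda_dt <- dup_fda
    ## resubmission may carry more complete information
    fill <- is.na(demo_dup$sex)
    demo_dup$sex[fill] <- sex[dup_idx][fill]
    clone <- function(tab) {
      sub <- tab[tab$caseid %in% dup_case, ]
      sub$primaryid <- paste0(sub$caseid, "2")
      sub
    }
    demo <- bind_rows(demo, demo_dup)
    drug <- bind_rows(drug, clone(drug))
    reac <- bind_rows(reac, clone(reac))
    outc <- bind_rows(outc, clone(outc))
    ther <- bind_rows(ther, clone(ther))
    dup_lineage <- tibble(
      caseid = dup_case,
      primaryid_original = paste0(dup_case, "1"),
      primaryid_duplicate = dup_pid,
      order = 2L
    )
  }

  pair_lambda <- dplyr::mutate(
    cfg$signal_pairs,
    drugname = drug_names[.data$drug],
    pt_name = pt_labels[.data$pt]
  )
  truth <- structure(
    list(pair_lambda = pair_lambda, duplicates = dup_lineage,
         target_names = cfg$target_drug_names,
         drug_index = setNames(seq_len(cfg$n_drugs), drug_names),
         case_drug = tibble(caseid = caseid, drug = drug_idx),
         onset_days = tibble(caseid = caseid, onset_days = as.integer(onset_days))),
    class = "ground_truth"
  )
  list(records = raw_record_set(demo, drug, reac, outc, ther), truth = truth)
}

#' Canonical validation configurations
#'
#' Two designed experiments used throughout the package's validation:
#'
#' * `"null"`: the global null — no injected pairs, no duplicates, all
#'   relative reporting rates 1. Used to measure the pipeline's
#'   false-positive rate (fraction of pairs with at least 3 reports flagged
#'   by all four criteria).
#' * `"recovery"`: two target-drug signals, lambda = 8 on a moderately
#'   common PT (index 20, expected around 65 reports at the default 20,000
#'   cases) and lambda = 4 on a commoner one (index 6, expected around 110
#'   reports), so both pairs clearly satisfy an expected report count of at
#'   least 50. A background of 40 elevated pairs (lambda 2-8) on
#'   mid-popularity drugs (indices 12-31) and PTs disjoint from the target's
#'   emulates the abundant true associations of a real spontaneous-report
#'   database; without them an empirical-Bayes fit on otherwise pure-null
#'   data correctly collapses to a point mass at 1 and no shrinkage method
#'   could be validated.
#'
#' @param kind `"null"` or `"recovery"`.
#' @param seed Seed stored in the config.
#' @param n_cases Universe size (default 20,000).
#' @return A [synthetic_config()].
#' @export
validation_config <- function(kind = c("null", "recovery"), seed = 1L,
                              n_cases = 20000) {
  kind <- match.arg(kind)
  if (kind == "null") {
    return(synthetic_config(n_cases = n_cases, seed = seed,
                            duplicate_rate = 0, signal_pairs = NULL))
  }
  target_pairs <- tibble(drug = 1L, pt = c(20L, 6L), lambda = c(8, 4))
  bg_pts <- setdiff(30:150, c(6L, 20L))
  background <- tibble(
    drug = rep(2:40, length.out = 150),
    pt = rep(bg_pts, length.out = 150),
    lambda = rep(c(1.5, 2, 2.5, 3, 4, 5, 6, 8), length.out = 150)
  )
  synthetic_config(
    n_cases = n_cases, seed = seed, target_share = 0.025,
    signal_pairs = bind_rows(target_pairs, background)
  )
}

#' Synthetic PT-to-SOC vocabulary matching a generator config
#'
#' Fabricates a consistent Preferred Term to System Organ Class assignment
#' for the generator's PT vocabulary (round-robin over `n_socs` classes).
#'
#' @param config A [synthetic_config()].
#' @return Tibble with columns `pt`, `soc`.
#' @export
synthetic_meddra_map <- function(config) {
  tibble(
    pt = sprintf("PT_%03d", seq_len(config$n_pts)),
    soc = sprintf("SOC_%02d", (seq_len(config$n_pts) - 1L) %% config$n_socs + 1L)
  )
}

#' Empirical versus injected relative reporting rates
#'
#' For every injected signal pair, compares the realized relative reporting
#' rate (observed report count over its independence expectation
#' `(a+b)(a+c)/N`, computed on the deduplicated realization) with the
#' injected lambda, along with a Monte-Carlo standard error.
#'
#' @param records A [raw_record_set()] produced by [generate_faers()].
#' @param truth The matching `ground_truth`.
#' @return Tibble with one row per injected pair: `drugname`, `pt`, `lambda`,
#'   `a` (observed), `expected`, `realized` (a / expected) and `se`
#'   (Poisson-approximation standard error of `realized`). Empty signal list
#'   gives an empty table.
#' @export
realized_rates <- function(records, truth) {
  stopifnot(inherits(records, "raw_record_set"), inherits(truth, "ground_truth"))
  pairs <- truth$pair_lambda
  if (nrow(pairs) == 0) {
    return(tibble(drugname = character(), pt = character(), lambda = numeric(),
                  a = integer(), expected = numeric(), realized = numeric(),
                  se = numeric()))
  }
  dedup <- deduplicate(records)
  demo <- dedup$demo
  n_total <- nrow(demo)
  case_drug <- distinct(dedup$drug[, c("caseid", "drugname")])
  case_drug$drugname <- ifelse(
    normalize_drug_name(case_drug$drugname) %in%
      normalize_drug_name(truth$target_names %||% venlafaxine_names),
    "TARGETDRUG", case_drug$drugname)
  case_pt <- distinct(dedup$reac[, c("caseid", "pt")])
  purrr::pmap_dfr(pairs, function(drug, pt, lambda, drugname, pt_name) {
    with_drug <- unique(case_drug$caseid[case_drug$drugname == drugname])
    with_pt <- unique(case_pt$caseid[case_pt$pt == pt_name])
    a <- length(intersect(with_drug, with_pt))
    expected <- length(with_drug) * length(with_pt) / n_total
    tibble(
      drugname = drugname, pt = pt_name, lambda = lambda,
      a = a, expected = expected,
      realized = a / expected,
      se = sqrt(max(a, 1)) / expected
    )
  })
}
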