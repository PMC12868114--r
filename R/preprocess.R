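#' Deduplicate a record set by the FDA case rule
#'
#' Multiple submissions of the same case (same `caseid`) are collapsed to the
#' most current one: the submission with the highest `fda_dt` survives; when
#' `fda_dt` ties, the highest `primaryid` wins. Child-table rows are retained
#' only for surviving `primaryid`s. The rule is a pure argmax, so the result
#' is independent of input row order and the operation is idempotent.
#'
#' @param records A [raw_record_set()].
#' @return A deduplicated [raw_record_set()] with one DEMO row per `caseid`.
#'   DEMO rows lacking a `caseid` are routed to a rejects tibble in the
#'   `"rejects"` attribute.
#' @export
deduplicate <- function(records) {
  stopifnot(inherits(records, "raw_record_set"))
  demo <- records$demo
  bad <- is.na(demo$caseid) | demo$caseid == ""
  rejects <- demo[bad, ]
  demo <- demo[!bad, ]
  keep <- demo %>%
    mutate(.fda = suppressWarnings(as.numeric(.data$fda_dt)),
           .pid = suppressWarnings(as.numeric(.data$primaryid))) %>%
    group_by(.data$caseid) %>%
    filter(rank_last(.data$.fda, .data$.pid)) %>%
    ungroup() %>%
    select(-".fda", -".pid")
  surviving <- keep$primaryid
  out <- raw_record_set(
    demo = keep,
    drug = filter(records$drug, .data$primaryid %in% surviving),
    reac = filter(records$reac, .data$primaryid %in% surviving),
    outc = filter(records$outc, .data$primaryid %in% surviving),
    ther = filter(records$ther, .data$primaryid %in% surviving)
  )
  attr(out, "rejects") <- rejects
  out
}

## TRUE for the single argmax row by (x, then y); NA sorts lowest.
rank_last <- function(x, y) {
  x[is.na(x)] <- -Inf
  y[is.na(y)] <- -Inf
  ord <- order(x, y, decreasing = TRUE)
  out <- logical(length(x))
  out[ord[1]] <- TRUE
  out
}

## Age-unit conversion factors to years.
age_unit_factor <- c(DEC = 10, YR = 1, MON = 1 / 12, WK = 1 / 52.18,
                     DY = 1 / 365.25, HR = 1 / 8766)

occp_map <- c(CN = "consumer", MD = "physician", PH = "pharmacist",
              OT = "other health-professional", LW = "lawyer")

#' Assemble per-case reports from a deduplicated record set
#'
#' Joins the five tables on `primaryid` into one row per case with
#' list-columns for drugs (name, role, therapy start date), reactions
#' (distinct PT strings) and outcome codes. Ages are normalised to years via
#' the unit code (DEC x10, YR x1, MON /12, WK /52.18, DY /365.25, HR /8766);
#' sex is normalised to F/M/UNK, reporter occupation codes to named classes.
#' Cases without any reaction row are excluded (count available via
#' `attr(x, "n_dropped_no_reaction")`).
#'
#' @param records A deduplicated [raw_record_set()].
#' @return A tibble with one row per case: `caseid`, `primaryid`, `fda_dt`,
#'   `event_dt`, `sex`, `age_years`, `weight_kg`, `reporter_class`,
#'   `country`, `outcomes` (list of codes), `drugs` (list of tibbles),
#'   `reactions` (list of PT vectors), `year` (reporting year from fda_dt).
#' @export
assemble_cases <- function(records) {
  stopifnot(inherits(records, "raw_record_set"))
  demo <- records$demo
  if (anyDuplicated(demo$caseid) > 0) {
    abort("records must be deduplicated before assembly (duplicate caseid found)")
  }
  age_num <- suppressWarnings(as.numeric(demo$age))
  fac <- unname(age_unit_factor[toupper(demo$age_cod)])
  fac[is.na(fac) & !is.na(age_num)] <- 1  # missing unit: assume years
  sex <- toupper(demo$sex)
  sex[!(sex %in% c("F", "M"))] <- "UNK"
  sex[is.na(demo$sex)] <- "UNK"
  reporter <- occp_map[toupper(demo$occp_cod)]
  reporter[is.na(reporter)] <- "unknown"

  drugs <- records$drug %>%
    left_join(records$ther,
              by = c("primaryid", "caseid", "drug_seq" = "dsg_drug_seq")) %>%
    select("primaryid", "drugname", role = "role_cod", start_dt = "start_dt") %>%
    tidyr::nest(drugs = c("drugname", "role", "start_dt"))
  reactions <- records$reac %>%
    distinct(.data$primaryid, .data$pt) %>%
    group_by(.data$primaryid) %>%
    summarise(reactions = list(.data$pt), .groups = "drop")
  outcomes <- records$outc %>%
    distinct(.data$primaryid, .data$outc_cod) %>%
    group_by(.data$primaryid) %>%
    summarise(outcomes = list(.data$outc_cod), .groups = "drop")

  cases <- tibble(
    caseid = demo$caseid,
    primaryid = demo$primaryid,
    fda_dt = demo$fda_dt,
    event_dt = demo$event_dt,
    sex = sex,
    age_years = age_num * fac,
    weight_kg = suppressWarnings(as.numeric(demo$wt)),
    reporter_class = unname(reporter),
    country = demo$reporter_country,
    year = substr(demo$fda_dt, 1, 4)
  ) %>%
    left_join(drugs, by = "primaryid") %>%
    left_join(reactions, by = "primaryid") %>%
    left_join(outcomes, by = "primaryid")
  cases$outcomes <- purrr::map(cases$outcomes, ~ .x %||% character())
  cases$drugs <- purrr::map(cases$drugs,
                            ~ .x %||% tibble(drugname = character(),
                                             role = character(),
                                             start_dt = character()))
  no_reac <- purrr::map_lgl(cases$reactions, is.null)
  out <- cases[!no_reac, ]
  attr(out, "n_dropped_no_reaction") <- sum(no_reac)
  if (sum(no_reac) > 0) {
    inform(sprintf("assemble_cases: %d case(s) without reactions excluded",
                   sum(no_reac)))
  }
  out
}

#' Normalise a drug name for matching
#'
#' Trims, collapses internal whitespace and upper-cases; matching is exact
#' after normalisation (no substring matching, so e.g. a congener whose name
#' contains the target's name as a substring does not match).
#'
#' @param x Character vector of drug names.
#' @return Normalised character vector.
#' @export
normalize_drug_name <- function(x) {
  toupper(stringr::str_squish(x))
}

#' Classify each case's relationship to the target drug
#'
#' @param cases Case tibble from [assemble_cases()].
#' @param target_names Character vector of name variants of the target drug.
#' @return `cases` with an added factor column `target_match` with levels
#'   `none`, `any_role`, `primary_suspect`: `primary_suspect` iff some
#'   matching drug row carries role code PS; `any_role` iff the drug appears
#'   only under other role codes (SS/C/I).
#' @export
match_target_drug <- function(cases, target_names = venlafaxine_names) {
  stopifnot(length(target_names) > 0)
  targets <- normalize_drug_name(target_names)
  cls <- purrr::map_chr(cases$drugs, function(d) {
    hit <- normalize_drug_name(d$drugname) %in% targets
    if (!any(hit)) return("none")
    if (any(toupper(d$role[hit]) == "PS")) "primary_suspect" else "any_role"
  })
  mutate(cases, target_match = factor(cls, levels = c("none", "any_role",
                                                      "primary_suspect")))
}

#' Restrict to cases with the target drug as primary suspect
#'
#' @inheritParams match_target_drug
#' @return The subset of `cases` where the target drug is primary suspect.
#' @export
filter_primary_suspect <- function(cases, target_names = venlafaxine_names) {
  matched <- match_target_drug(cases, target_names)
  filter(matched, .data$target_match == "primary_suspect")
}

onset_bin_breaks <- c(0, 30, 60, 90, 120, 150, 180, 360, Inf)
onset_bin_labels <- c("0-30", "31-60", "61-90", "91-120", "121-150",
                      "151-180", "181-360", ">360")

#' Bin onset days into the standard latency intervals
#'
#' Inclusive upper edges: 151-180 means 151 <= d <= 180; >360 means d >= 361.
#'
#' @param days Positive integer vector of onset days.
#' @return Factor with the eight latency bins as levels.
#' @export
onset_bin <- function(days) {
  cut(days, breaks = onset_bin_breaks, labels = onset_bin_labels, right = TRUE)
}

parse_day_date <- function(x) {
  full <- !is.na(x) & grepl("^[0-9]{8}$", x)
  out <- rep(as.Date(NA), length(x))
  out[full] <- as.Date(x[full], format = "%Y%m%d")
  out
}

#' Time to onset for target-drug cases
#'
#' Onset is the day difference between the adverse-event date and the
#' earliest therapy start date among target-drug rows, plus one, so a
#' same-day event counts as day 1 (never 0). Cases are rejected, not
#' errored, when either date is missing or below day precision
#' (`YYYYMM`/`YYYY` partial dates are not imputed) or when the event precedes
#' therapy start.
#'
#' @param cases Case tibble (normally restricted to primary-suspect cases).
#' @param target_names Name variants of the target drug.
#' @return Tibble of accepted records: `caseid`, `onset_days`, `bin`.
#'   Rejections are attached as attribute `"rejections"`, a tibble with
#'   `caseid` and `reason` in `missing_event_date`, `missing_start_date`,
#'   `event_before_start`; see [onset_rejections()].
#' @export
compute_onset <- function(cases, target_names = venlafaxine_names) {
  targets <- normalize_drug_name(target_names)
  start_raw <- purrr::map_chr(cases$drugs, function(d) {
    hit <- normalize_drug_name(d$drugname) %in% targets
    starts <- d$start_dt[hit]
    starts <- starts[!is.na(starts) & grepl("^[0-9]{8}$", starts)]
    if (length(starts) == 0) NA_character_ else starts[which.min(as.integer(starts))]
  })
  event <- parse_day_date(cases$event_dt)
  start <- parse_day_date(start_raw)
  reason <- dplyr::case_when(
    is.na(event) ~ "missing_event_date",
    is.na(start) ~ "missing_start_date",
    event < start ~ "event_before_start",
    TRUE ~ NA_character_
  )
  ok <- is.na(reason)
  out <- tibble(
    caseid = cases$caseid[ok],
    onset_days = as.integer(event[ok] - start[ok]) + 1L
  )
  out$bin <- onset_bin(out$onset_days)
  attr(out, "rejections") <- tibble(caseid = cases$caseid[!ok],
                                    reason = reason[!ok])
  out
}

#' Rejected cases of an onset computation
#'
#' @param onsets Result of [compute_onset()].
#' @return Tibble with columns `caseid`, `reason`.
#' @export
onset_rejections <- function(onsets) {
  attr(onsets, "rejections") %||% tibble(caseid = character(), reason = character())
}
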