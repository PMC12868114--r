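# Shared fixture builders: every fixture is constructed in code.

# A minimal raw record set; demo_rows is a tibble with at least primaryid,
# caseid, fda_dt (other DEMO columns filled with NA), and child rows default
# to one drug + one reaction per submission.
make_records <- function(demo_rows,
                         drug_rows = NULL, reac_rows = NULL,
                         outc_rows = NULL, ther_rows = NULL) {
  demo <- tibble::tibble(
    primaryid = demo_rows[["primaryid"]],
    caseid = demo_rows[["caseid"]],
    fda_dt = demo_rows[["fda_dt"]] %||% "20200101",
    event_dt = demo_rows[["event_dt"]] %||% NA_character_,
    age = demo_rows[["age"]] %||% NA_character_,
    age_cod = demo_rows[["age_cod"]] %||% NA_character_,
    sex = demo_rows[["sex"]] %||% NA_character_,
    wt = demo_rows[["wt"]] %||% NA_character_,
    occp_cod = demo_rows[["occp_cod"]] %||% NA_character_,
    reporter_country = demo_rows[["reporter_country"]] %||% NA_character_
  )
  if (is.null(drug_rows)) {
    drug_rows <- tibble::tibble(primaryid = demo$primaryid, caseid = demo$caseid,
                                drug_seq = "1", role_cod = "PS",
                                drugname = "DRUG_A")
  }
  if (is.null(reac_rows)) {
    reac_rows <- tibble::tibble(primaryid = demo$primaryid, caseid = demo$caseid,
                                pt = "PT_A")
  }
  if (is.null(outc_rows)) {
    outc_rows <- tibble::tibble(primaryid = character(), caseid = character(),
                                outc_cod = character())
  }
  if (is.null(ther_rows)) {
    ther_rows <- tibble::tibble(primaryid = character(), caseid = character(),
                                dsg_drug_seq = character(),
                                start_dt = character())
  }
  raw_record_set(demo, drug_rows, reac_rows, outc_rows, ther_rows)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Build an assembled case universe directly from per-report drug/PT specs.
# drugs: character vector (one PS drug per report); pts: list of PT vectors.
make_universe <- function(drugs, pts, sex = NULL, age_years = NULL,
                          outcomes = NULL, country = NULL,
                          event_dt = NULL, start_dt = NULL) {
  n <- length(drugs)
  stopifnot(length(pts) == n)
  tibble::tibble(
    caseid = sprintf("C%06d", seq_len(n)),
    primaryid = sprintf("C%06d1", seq_len(n)),
    fda_dt = "20200101",
    event_dt = event_dt %||% rep(NA_character_, n),
    sex = sex %||% rep("UNK", n),
    age_years = age_years %||% rep(NA_real_, n),
    weight_kg = NA_real_,
    reporter_class = "unknown",
    country = country %||% rep(NA_character_, n),
    year = "2020",
    drugs = purrr::map2(drugs, start_dt %||% rep(NA_character_, n),
                        ~ tibble::tibble(drugname = .x, role = "PS",
                                         start_dt = .y)),
    reactions = purrr::map(pts, as.character),
    outcomes = purrr::map(outcomes %||% rep(list(character()), n), as.character)
  )
}

# Expand per-level counts into a vector of levels (for printed-table fixtures).
expand_counts <- function(levels, counts) rep(levels, times = counts)

# A moderate, non-degenerate shrinkage prior used in closed-form-vs-oracle
# comparisons.
fixture_prior <- function() {
  pr <- gps_diffuse_prior()
  pr$alpha1 <- 1.2; pr$beta1 <- 0.9; pr$alpha2 <- 2.5; pr$beta2 <- 2.0
  pr$w <- 0.15
  pr
}

# Brute-force oracle for the posterior of lambda given (a, E): numerical
# integration of prior(lambda) * Poisson(a | lambda E), independent of the
# package's closed-form mixture update.
oracle_ebgm <- function(a, E, prior) {
  g_raw <- function(l) {
    (prior$w * stats::dgamma(l, prior$alpha1, prior$beta1) +
       (1 - prior$w) * stats::dgamma(l, prior$alpha2, prior$beta2)) *
      stats::dpois(a, l * E)
  }
  # normalise by the value near the likelihood mode so the integrand is O(1):
  # integrate()'s absolute tolerance swamps integrals of magnitude << 1
  scale <- g_raw(max(a / E, 0.05))
  if (!is.finite(scale) || scale <= 0) scale <- 1
  g <- function(l) g_raw(l) / scale
  # finite range comfortably covering the posterior mass (peak near a/E);
  # integrate() over [0, Inf) can miss a far-out spike
  hi <- 5 * (a + 20) / max(E, 1e-3) + 50
  z <- stats::integrate(g, 0, hi, rel.tol = 1e-12,
                        subdivisions = 2000L)$value
  elog <- stats::integrate(function(l) log(l) * g(l), 1e-300, hi,
                           rel.tol = 1e-12, subdivisions = 2000L)$value / z
  cdf <- function(x) stats::integrate(g, 0, x, rel.tol = 1e-12,
                                      subdivisions = 2000L)$value / z
  q05 <- stats::uniroot(function(x) cdf(x) - 0.05,
                        lower = 1e-12, upper = hi, tol = 1e-12)$root
  list(ebgm = exp(elog), ebgm05 = q05)
}
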