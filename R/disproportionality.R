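#' Per-PT 2x2 contingency tables for a target drug
#'
#' For every Preferred Term in the universe, counts reports in the four cells
#' of the drug-event table: `a` (target drug and the PT), `b` (target drug
#' without the PT), `c` (PT without the target drug), `d` (neither). The
#' counting unit is the deduplicated report: a report contributes at most
#' once per PT regardless of repeated reaction rows, and the comparator is
#' all other reports in the same universe. `expected` is the independence
#' expectation of cell `a`, `(a+b)(a+c)/N`.
#'
#' @param cases Case tibble from [assemble_cases()] (the analysis universe).
#' @param target_names Name variants of the target drug; a report is exposed
#'   iff the target drug appears with role PS.
#' @param pts Optional character vector restricting the PTs tabulated; PTs
#'   absent from the universe get `a = c = 0`.
#' @return Tibble with columns `pt`, `a`, `b`, `c`, `d`, `n_reports` (N) and
#'   `expected`, one row per PT.
#' @export
contingency_tables <- function(cases, target_names = venlafaxine_names,
                               pts = NULL) {
  matched <- match_target_drug(cases, target_names)
  exposed_ids <- matched$caseid[matched$target_match == "primary_suspect"]
  n_total <- nrow(cases)
  n_exposed <- length(exposed_ids)
  case_pt <- tidyr::unnest(select(cases, "caseid", "reactions"),
                           "reactions") %>%
    rename(pt = "reactions") %>%
    distinct()
  case_pt$exposed <- case_pt$caseid %in% exposed_ids
  counts <- case_pt %>%
    group_by(.data$pt) %>%
    summarise(a = sum(.data$exposed), a_plus_c = dplyr::n(), .groups = "drop")
  if (!is.null(pts)) {
    counts <- tibble(pt = pts) %>%
      left_join(counts, by = "pt") %>%
      mutate(a = dplyr::coalesce(.data$a, 0L),
             a_plus_c = dplyr::coalesce(.data$a_plus_c, 0L))
  }
  counts %>%
    mutate(
      b = n_exposed - .data$a,
      c = .data$a_plus_c - .data$a,
      d = n_total - n_exposed - .data$c,
      n_reports = n_total,
      expected = (.data$a + .data$b) * (.data$a + .data$c) / n_total
    ) %>%
    select("pt", "a", "b", "c", "d", "n_reports", "expected") %>%
    arrange(desc(.data$a), .data$pt)
}

#' All (suspect drug, PT) pair counts over a universe
#'
#' Tabulates, for every primary-suspect drug and every PT it co-occurs with,
#' the observed report count `a` and the independence expectation
#' `(a+b)(a+c)/N`, plus the full 2x2 cells. This pairwise scan is the input
#' to the empirical-Bayes prior fit and to database-wide calibration checks.
#'
#' @param cases Case tibble from [assemble_cases()].
#' @param complete If TRUE, returns the full drug-by-PT grid including pairs
#'   never reported together (`a = 0`); required for an unbiased
#'   empirical-Bayes prior fit, since restricting to observed pairs
#'   truncates the zero counts. Default FALSE (observed pairs only).
#' @return Tibble with one row per (drug, PT) pair: `drugname`,
#'   `pt`, `a`, `b`, `c`, `d`, `n_reports`, `expected`.
#' @export
contingency_scan <- function(cases, complete = FALSE) {
  n_total <- nrow(cases)
  ps_drug <- purrr::map_chr(cases$drugs, function(d) {
    ps <- normalize_drug_name(d$drugname[toupper(d$role) == "PS"])
    if (length(ps) == 0) NA_character_ else ps[1]
  })
  universe <- tibble(caseid = cases$caseid, drugname = ps_drug,
                     reactions = cases$reactions) %>%
    filter(!is.na(.data$drugname))
  case_pt <- tidyr::unnest(universe, "reactions") %>%
    rename(pt = "reactions") %>%
    distinct(.data$caseid, .data$drugname, .data$pt)
  drug_margin <- universe %>% count(.data$drugname, name = "n_drug")
  pt_margin <- case_pt %>% distinct(.data$caseid, .data$pt) %>%
    count(.data$pt, name = "n_pt")
  pairs <- count(case_pt, .data$drugname, .data$pt, name = "a")
  if (complete) {
    grid <- tidyr::expand_grid(drugname = drug_margin$drugname,
                               pt = pt_margin$pt)
    pairs <- grid %>%
      left_join(pairs, by = c("drugname", "pt")) %>%
      mutate(a = dplyr::coalesce(.data$a, 0L))
  }
  pairs %>%
    left_join(drug_margin, by = "drugname") %>%
    left_join(pt_margin, by = "pt") %>%
    mutate(
      b = .data$n_drug - .data$a,
      c = .data$n_pt - .data$a,
      d = n_total - .data$n_drug - .data$c,
      n_reports = n_total,
      expected = .data$n_drug * .data$n_pt / n_total
    ) %>%
    select("drugname", "pt", "a", "b", "c", "d", "n_reports", "expected")
}

#' Reporting odds ratio with 95% confidence interval
#'
#' `ROR = ad / bc`, with the log-method interval
#' `exp(log(ROR) +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. Any zero cell makes
#' the ratio non-estimable (returned as `NA` with a reason; no continuity
#' correction is applied, since the signal rule already requires n >= 3).
#'
#' @param tbl Contingency tibble with columns `a`, `b`, `c`, `d`.
#' @return `tbl` with added columns `ror`, `ror_low`, `ror_high`,
#'   `ror_reason` (`NA` when estimable, `"zero_cell"` otherwise).
#' @export
add_ror <- function(tbl) {
  zero <- tbl$a == 0 | tbl$b == 0 | tbl$c == 0 | tbl$d == 0
  est <- (tbl$a * tbl$d) / (tbl$b * tbl$c)
  se <- sqrt(1 / tbl$a + 1 / tbl$b + 1 / tbl$c + 1 / tbl$d)
  mutate(tbl,
    ror = ifelse(zero, NA_real_, est),
    ror_low = ifelse(zero, NA_real_, exp(log(est) - 1.96 * se)),
    ror_high = ifelse(zero, NA_real_, exp(log(est) + 1.96 * se)),
    ror_reason = ifelse(zero, "zero_cell", NA_character_)
  )
}

#' Proportional reporting ratio with 95% confidence interval
#'
#' `PRR = (a/(a+b)) / (c/(c+d))`, interval
#' `exp(log(PRR) +/- 1.96 sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d)))`. With
#' `c = 0` the ratio is non-estimable; with `a = 0` (and `a+b > 0`) the
#' point estimate is 0 (estimable, never a signal) and the interval is
#' undefined.
#'
#' @inheritParams add_ror
#' @return `tbl` with added `prr`, `prr_low`, `prr_high`, `prr_reason`.
#' @export
add_prr <- function(tbl) {
  a <- tbl$a; b <- tbl$b; cc <- tbl$c; d <- tbl$d
  none <- cc == 0 | (a + b) == 0
  est <- (a / (a + b)) / (cc / (cc + d))
  se <- sqrt(1 / a - 1 / (a + b) + 1 / cc - 1 / (cc + d))
  zero_a <- a == 0 & !none
  mutate(tbl,
    prr = dplyr::case_when(none ~ NA_real_, zero_a ~ 0, TRUE ~ est),
    prr_low = ifelse(none | zero_a, NA_real_, exp(log(est) - 1.96 * se)),
    prr_high = ifelse(none | zero_a, NA_real_, exp(log(est) + 1.96 * se)),
    prr_reason = ifelse(none, "zero_margin", NA_character_)
  )
}

#' Yates-corrected Pearson chi-square of the 2x2 table
#'
#' `sum((|O - E_cell| - 0.5)^2 / E_cell)` over the four cells, with the
#' continuity correction clamped to zero when `|O - E_cell| < 0.5`. A table
#' with any zero margin carries no information and returns 0. Setting
#' `correct = FALSE` gives the uncorrected Pearson statistic.
#'
#' @inheritParams add_ror
#' @param correct Apply the Yates continuity correction (default TRUE).
#' @return `tbl` with an added numeric column `chi2`.
#' @export
add_chi2 <- function(tbl, correct = TRUE) {
  a <- tbl$a; b <- tbl$b; cc <- tbl$c; d <- tbl$d
  n <- a + b + cc + d
  r1 <- a + b; r2 <- cc + d; c1 <- a + cc; c2 <- b + d
  zero_margin <- r1 == 0 | r2 == 0 | c1 == 0 | c2 == 0
  chi2 <- numeric(nrow(tbl))
  idx <- which(!zero_margin)
  if (length(idx) > 0) {
    e <- cbind(r1 * c1, r1 * c2, r2 * c1, r2 * c2)[idx, , drop = FALSE] / n[idx]
    o <- cbind(a, b, cc, d)[idx, , drop = FALSE]
    dev <- abs(o - e)
    if (correct) dev <- pmax(dev - 0.5, 0)
    chi2[idx] <- rowSums(dev^2 / e)
  }
  mutate(tbl, chi2 = chi2)
}

#' BCPNN information component with lower credibility bound
#'
#' Default (`variant = "shrunk"`) is the widely used shrinkage closed form
#' `IC = log2((a + 0.5) / (E + 0.5))` with delta-method variance
#' `(1/(a + 0.5)) / ln(2)^2`, and `IC025 = IC - z * sd`. The alternative
#' (`variant = "moment"`) is the original full-Bayes moment expansion with
#' Dirichlet/beta priors (prior strengths alpha1 = beta1 = 1 on the margins,
#' alpha = beta = 2 on the totals); both variants agree to within about 0.1
#' bit once `a >= 10`.
#'
#' @inheritParams add_ror
#' @param variant `"shrunk"` (default) or `"moment"`.
#' @param z Lower-bound multiplier: 1.96 for the 95% interval (default); 2
#'   for the alternative convention used by some programmes.
#' @return `tbl` with added columns `ic`, `ic025`.
#' @export
add_ic <- function(tbl, variant = c("shrunk", "moment"), z = 1.96) {
  variant <- match.arg(variant)
  a <- tbl$a
  n <- tbl$a + tbl$b + tbl$c + tbl$d
  if (variant == "shrunk") {
    e <- tbl$expected %||% ((tbl$a + tbl$b) * (tbl$a + tbl$c) / n)
    ic <- log2((a + 0.5) / (e + 0.5))
    sdv <- sqrt((1 / (a + 0.5)) / log(2)^2)
  } else {
    r1 <- tbl$a + tbl$b
    c1 <- tbl$a + tbl$c
    a1 <- 1; b1 <- 1; al <- 2; be <- 2; g11 <- 1
    gam <- g11 * (n + al) * (n + be) / ((r1 + a1) * (c1 + b1))
    ic <- log2((a + g11) * (n + al) * (n + be) /
                 ((n + gam) * (r1 + a1) * (c1 + b1)))
    vr <- ((n - a + gam - g11) / ((a + g11) * (1 + n + gam)) +
           (n - r1 + al - a1) / ((r1 + a1) * (1 + n + al)) +
           (n - c1 + be - b1) / ((c1 + b1) * (1 + n + be))) / log(2)^2
    sdv <- sqrt(vr)
  }
  mutate(tbl, ic = ic, ic025 = ic - z * sdv)
}

## Log marginal likelihood of observed counts under the two-component
## gamma-Poisson mixture: a ~ Poisson(lambda E), lambda ~ w Gamma(a1, b1)
## + (1-w) Gamma(a2, b2) (shape/rate), marginally a negative-binomial mixture.
gps_loglik <- function(par, a, E) {
  l1 <- dnbinom(a, size = par[["alpha1"]],
                prob = par[["beta1"]] / (par[["beta1"]] + E), log = TRUE)
  l2 <- dnbinom(a, size = par[["alpha2"]],
                prob = par[["beta2"]] / (par[["beta2"]] + E), log = TRUE)
  m <- pmax(l1, l2)
  sum(m + log(par[["w"]] * exp(l1 - m) + (1 - par[["w"]]) * exp(l2 - m)))
}

gps_default_start <- c(alpha1 = 0.2, beta1 = 0.1, alpha2 = 2, beta2 = 4, w = 1 / 3)

#' Fit the gamma-Poisson shrinker prior by marginal maximum likelihood
#'
#' DuMouchel's empirical-Bayes model for a database of (drug, event) report
#' counts: each pair's count `a` is Poisson with mean `lambda * E`, where `E`
#' is its independence expectation and the relative reporting rate `lambda`
#' follows a two-component gamma mixture prior
#' `w Gamma(alpha1, beta1) + (1 - w) Gamma(alpha2, beta2)` (shape/rate).
#' Marginally each count is a mixture of negative binomials; the five
#' hyperparameters are estimated by maximising the marginal likelihood over
#' all supplied pairs, with positivity enforced by log transform and the
#' weight by logit transform. Optimisation is deterministic from the
#' canonical start (0.2, 0.1, 2, 4, 1/3): Nelder-Mead followed by a BFGS
#' polish, converged when the relative log-likelihood change is below
#' `reltol`.
#'
#' With fewer than `min_pairs` pairs having `a >= 1`, fitting is refused and
#' the diffuse canonical start is returned as the prior (flagged in the
#' object and in a message).
#'
#' @param pairs Tibble with columns `a` and `expected` (one row per
#'   drug-event pair), e.g. from [contingency_scan()]. Pairs with `a = 0`
#'   are tolerated but typically absent from sparse scans.
#' @param min_pairs Minimum number of pairs with `a >= 1` (default 100).
#' @param reltol Relative log-likelihood convergence tolerance.
#' @param max_iter Iteration cap for the optimiser.
#' @return Object of class `gps_prior`: hyperparameters `alpha1`, `beta1`,
#'   `alpha2`, `beta2`, `w`, plus `loglik`, `start_loglik`, `converged`,
#'   `fallback`, `n_pairs`. Supports [tidy()] and [glance()].
#' @references DuMouchel W (1999). Bayesian data mining in large frequency
#'   tables, with an application to the FDA spontaneous reporting system.
#'   The American Statistician 53(3):177-190.
#' @export
gps_fit <- function(pairs, min_pairs = 100, reltol = 1e-8, max_iter = 2000) {
  a <- pairs$a
  E <- pairs$expected
  stopifnot(length(a) == length(E), all(E > 0 | a == 0))
  keep <- E > 0
  a <- a[keep]; E <- E[keep]
  n_pos <- sum(a >= 1)
  start <- gps_default_start
  if (n_pos < min_pairs) {
    inform(sprintf(
      "gps_fit: only %d pair(s) with a >= 1 (< %d); using diffuse default prior",
      n_pos, min_pairs))
    return(new_gps_prior(start, loglik = gps_loglik(start, a, E),
                         start_loglik = gps_loglik(start, a, E),
                         converged = NA, fallback = TRUE, n_pairs = length(a)))
  }
  to_par <- function(theta) {
    theta <- unname(theta)
    c(alpha1 = exp(theta[1]), beta1 = exp(theta[2]),
      alpha2 = exp(theta[3]), beta2 = exp(theta[4]),
      w = stats::plogis(theta[5]))
  }
  nll <- function(theta) {
    p <- to_par(theta)
    ll <- gps_loglik(p, a, E)
    if (!is.finite(ll)) return(1e12)
    -ll
  }
  theta0 <- c(log(start[1:4]), stats::qlogis(start[5]))
  fit1 <- optim(theta0, nll, method = "Nelder-Mead",
                control = list(maxit = max_iter, reltol = reltol))
  fit2 <- tryCatch(
    optim(fit1$par, nll, method = "BFGS",
          control = list(maxit = max_iter, reltol = reltol)),
    error = function(e) fit1)
  fit <- if (fit2$value <= fit1$value) fit2 else fit1
  par <- to_par(fit$par)
  start_ll <- gps_loglik(start, a, E)
  final_ll <- -fit$value
  converged <- fit$convergence == 0 ||
    abs(fit2$value - fit1$value) <= reltol * (abs(fit1$value) + reltol)
  if (!converged) {
    warn(sprintf("gps_fit: optimiser did not report convergence (code %d)",
                 fit$convergence))
  }
  if (par[["w"]] < 1e-6 || par[["w"]] > 1 - 1e-6) {
    warn("gps_fit: mixture weight pinned at the boundary; prior is effectively one-component")
  }
  new_gps_prior(par, loglik = final_ll, start_loglik = start_ll,
                converged = converged, fallback = FALSE, n_pairs = length(a))
}

new_gps_prior <- function(par, loglik, start_loglik, converged, fallback,
                          n_pairs) {
  structure(list(
    alpha1 = unname(par[["alpha1"]]), beta1 = unname(par[["beta1"]]),
    alpha2 = unname(par[["alpha2"]]), beta2 = unname(par[["beta2"]]),
    w = unname(par[["w"]]),
    loglik = loglik, start_loglik = start_loglik,
    converged = converged, fallback = fallback, n_pairs = n_pairs
  ), class = "gps_prior")
}

#' Diffuse default gamma-mixture prior
#'
#' The canonical starting prior of the gamma-Poisson shrinker (0.2, 0.1, 2,
#' 4, w = 1/3), used as a fallback when a universe has too few pairs to fit.
#'
#' @return A `gps_prior` object flagged as fallback.
#' @export
gps_diffuse_prior <- function() {
  new_gps_prior(gps_default_start, loglik = NA_real_, start_loglik = NA_real_,
                converged = NA, fallback = TRUE, n_pairs = 0L)
}

#' @export
print.gps_prior <- function(x, ...) {
  cat(sprintf(
    "<gps_prior> w=%.3f  Gamma(%.3f, %.3f) + Gamma(%.3f, %.3f)%s\n",
    x$w, x$alpha1, x$beta1, x$alpha2, x$beta2,
    if (isTRUE(x$fallback)) "  [diffuse fallback]" else ""
  ))
  cat(sprintf("  prior mean %.3f, logLik %.2f on %d pairs\n",
              gps_prior_mean(x), x$loglik, x$n_pairs))
  invisible(x)
}

#' Mean of the fitted relative-reporting-rate prior
#'
#' @param prior A `gps_prior`.
#' @return `w alpha1/beta1 + (1-w) alpha2/beta2`.
#' @export
gps_prior_mean <- function(prior) {
  prior$w * prior$alpha1 / prior$beta1 +
    (1 - prior$w) * prior$alpha2 / prior$beta2
}

#' @rdname tidy.gps_prior
#' @export
glance.gps_prior <- function(x, ...) {
  tibble(logLik = x$loglik, start_logLik = x$start_loglik,
         n_pairs = x$n_pairs, converged = x$converged,
         fallback = x$fallback, prior_mean = gps_prior_mean(x))
}

#' Tidiers for fitted shrinkage priors
#'
#' @param x A `gps_prior` object.
#' @param ... Unused.
#' @return `tidy()` returns one row per hyperparameter (`term`, `estimate`);
#'   `glance()` a one-row model summary.
#' @export
tidy.gps_prior <- function(x, ...) {
  tibble(term = c("alpha1", "beta1", "alpha2", "beta2", "w"),
         estimate = c(x$alpha1, x$beta1, x$alpha2, x$beta2, x$w))
}

## Posterior mixture given (a, E): components Gamma(alpha_j + a, beta_j + E)
## with weights proportional to prior weight times negative-binomial evidence.
gps_posterior <- function(a, E, prior) {
  l1 <- dnbinom(a, size = prior$alpha1,
                prob = prior$beta1 / (prior$beta1 + E), log = TRUE)
  l2 <- dnbinom(a, size = prior$alpha2,
                prob = prior$beta2 / (prior$beta2 + E), log = TRUE)
  m <- pmax(l1, l2)
  q1 <- prior$w * exp(l1 - m)
  q2 <- (1 - prior$w) * exp(l2 - m)
  tot <- q1 + q2
  list(q1 = q1 / tot, q2 = q2 / tot,
       shape1 = prior$alpha1 + a, rate1 = prior$beta1 + E,
       shape2 = prior$alpha2 + a, rate2 = prior$beta2 + E)
}

#' Empirical Bayes geometric mean and its 5th posterior percentile
#'
#' Under the fitted gamma-mixture prior the posterior of the relative
#' reporting rate given `(a, E)` is again a two-component gamma mixture with
#' updated parameters `(alpha_j + a, beta_j + E)` and weights proportional to
#' prior weight times negative-binomial evidence. `EBGM` is the geometric
#' mean `2^(E[log2 lambda | a, E])` (computed in closed form via digamma);
#' `EBGM05` is the 5th percentile of the posterior mixture, found by monotone
#' root-finding on the mixture CDF to absolute tolerance 1e-10.
#'
#' @param a,expected Numeric vectors of observed counts and independence
#'   expectations (recycled to common length).
#' @param prior A `gps_prior` from [gps_fit()] (or [gps_diffuse_prior()]).
#' @return Tibble with columns `ebgm`, `ebgm05`.
#' @export
ebgm_stats <- function(a, expected, prior) {
  stopifnot(inherits(prior, "gps_prior"))
  n <- max(length(a), length(expected))
  a <- rep_len(a, n); E <- rep_len(expected, n)
  post <- gps_posterior(a, E, prior)
  mean_log <- post$q1 * (digamma(post$shape1) - log(post$rate1)) +
    post$q2 * (digamma(post$shape2) - log(post$rate2))
  ebgm <- exp(mean_log)
  ebgm05 <- vapply(seq_len(n), function(i) {
    cdf <- function(x) {
      post$q1[i] * pgamma(x, post$shape1[i], post$rate1[i]) +
        post$q2[i] * pgamma(x, post$shape2[i], post$rate2[i]) - 0.05
    }
    lo <- min(qgamma(0.049, post$shape1[i], post$rate1[i]),
              qgamma(0.049, post$shape2[i], post$rate2[i]))
    hi <- max(qgamma(0.051, post$shape1[i], post$rate1[i]),
              qgamma(0.051, post$shape2[i], post$rate2[i]))
    lo <- max(lo, .Machine$double.xmin)
    uniroot(cdf, lower = lo, upper = hi, extendInt = "upX",
            tol = 1e-10)$root
  }, numeric(1))
  tibble(ebgm = ebgm, ebgm05 = ebgm05)
}

#' @rdname ebgm_stats
#' @param tbl Contingency tibble with columns `a` and `expected`.
#' @return For `add_ebgm()`: `tbl` with added `ebgm`, `ebgm05`.
#' @export
add_ebgm <- function(tbl, prior) {
  dplyr::bind_cols(tbl, ebgm_stats(tbl$a, tbl$expected, prior))
}

#' Full disproportionality statistics for one target drug
#'
#' Builds the per-PT 2x2 tables over the universe and adds all four
#' statistics: ROR and PRR with 95% intervals, Yates-corrected chi-square,
#' the information component with IC025, and EBGM with EBGM05 under the
#' gamma-Poisson shrinker. Unless a `prior` is supplied, the shrinker prior
#' is fitted to the universe-wide (drug, PT) pair scan, falling back to the
#' diffuse default when the universe is too sparse.
#'
#' @inheritParams contingency_tables
#' @param prior Optional pre-fitted `gps_prior`.
#' @param soc_map Optional PT-to-SOC tibble (see [read_meddra_map()]); adds a
#'   `soc` column.
#' @param ic_variant,ic_z Passed to [add_ic()].
#' @param chi2_correct Passed to [add_chi2()].
#' @return Tibble, one row per PT, with the contingency cells, `soc` (if
#'   mapped), `n` (= `a`) and all statistic columns. The fitted prior is
#'   attached as attribute `"gps_prior"`.
#' @export
disproportionality_stats <- function(cases, target_names = venlafaxine_names,
                                     prior = NULL, soc_map = NULL,
                                     ic_variant = "shrunk", ic_z = 1.96,
                                     chi2_correct = TRUE) {
  if (is.null(prior)) {
    scan <- contingency_scan(cases, complete = TRUE)
    prior <- if (sum(scan$a >= 1) >= 100) gps_fit(scan) else {
      inform("disproportionality_stats: sparse universe; using diffuse prior")
      gps_diffuse_prior()
    }
  }
  out <- contingency_tables(cases, target_names) %>%
    add_ror() %>%
    add_prr() %>%
    add_chi2(correct = chi2_correct) %>%
    add_ic(variant = ic_variant, z = ic_z) %>%
    add_ebgm(prior) %>%
    mutate(n = .data$a, .after = "pt")
  if (!is.null(soc_map)) {
    out <- mutate(out, soc = pt_to_soc(.data$pt, soc_map), .after = "pt")
  }
  attr(out, "gps_prior") <- prior
  out
}
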