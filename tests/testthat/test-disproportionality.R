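tbl1 <- function(a, b, c, d) {
  tibble::tibble(a = a, b = b, c = c, d = d,
                 n_reports = a + b + c + d,
                 expected = (a + b) * (a + c) / (a + b + c + d))
}

test_that("contingency cells match brute-force enumeration of a hand-built universe", {
  # 6 reports: 3 with the drug (2 of them with the PT), 1 non-drug report
  # has the PT, 2 have neither.
  cases <- make_universe(
    drugs = c("EFFEXOR", "EFFEXOR", "EFFEXOR", "OTHER", "OTHER", "OTHER"),
    pts = list(c("HEADACHE", "NAUSEA"), "HEADACHE", "INSOMNIA",
               "HEADACHE", "NAUSEA", "FATIGUE")
  )
  ct <- contingency_tables(cases, venlafaxine_names)
  row <- ct[ct$pt == "HEADACHE", ]
  expect_equal(c(row$a, row$b, row$c, row$d), c(2, 1, 1, 2))
  expect_equal(row$expected, 3 * 3 / 6)
  # conservation on every row
  expect_true(all(ct$a + ct$b + ct$c + ct$d == nrow(cases)))
  # repeated PT rows in one report count once
  cases2 <- make_universe(drugs = c("EFFEXOR", "OTHER"),
                          pts = list(c("P", "P", "P"), "P"))
  ct2 <- contingency_tables(cases2, venlafaxine_names)
  expect_equal(ct2$a[ct2$pt == "P"], 1L)
})

test_that("degenerate universes produce degenerate but conserved tables", {
  cases <- make_universe(drugs = rep("EFFEXOR", 4), pts = rep(list("P"), 4))
  ct <- contingency_tables(cases)
  expect_equal(c(ct$a, ct$b, ct$c, ct$d), c(4, 0, 0, 0))
  # a PT absent from the universe: a = c = 0
  ct2 <- contingency_tables(cases, pts = c("P", "ABSENT"))
  absent <- ct2[ct2$pt == "ABSENT", ]
  expect_equal(c(absent$a, absent$c), c(0, 0))
})

test_that("the pairwise scan marginals agree with per-target tables", {
  gen <- generate_faers(synthetic_config(n_cases = 400, seed = 23))
  cases <- assemble_cases(deduplicate(gen$records))
  scan <- contingency_scan(cases)
  expect_true(all(scan$a + scan$b + scan$c + scan$d == nrow(cases)))
  # sum over PTs of a for the target equals its (report, PT) pair count
  target <- scan[scan$drugname %in% normalize_drug_name(venlafaxine_names), ]
  ct <- contingency_tables(cases)
  expect_equal(sum(target$a), sum(ct$a))
  full <- contingency_scan(cases, complete = TRUE)
  expect_true(all(full$expected > 0))
  expect_gt(nrow(full), nrow(scan))
  expect_equal(sum(full$a), sum(scan$a))
})

test_that("ROR matches cross-product arithmetic with the log-method interval", {
  r <- add_ror(tbl1(10, 10, 10, 10))
  expect_equal(r$ror, 1)
  expect_lt(r$ror_low, 1); expect_gt(r$ror_high, 1)
  r2 <- add_ror(tbl1(20, 80, 100, 9800))
  expect_equal(r2$ror, 24.5)
  se <- sqrt(1 / 20 + 1 / 80 + 1 / 100 + 1 / 9800)
  expect_equal(r2$ror_low, exp(log(24.5) - 1.96 * se))
  r3 <- add_ror(tbl1(0, 100, 100, 9800))
  expect_true(is.na(r3$ror))
  expect_equal(r3$ror_reason, "zero_cell")
})

test_that("PRR matches direct ratio arithmetic and its edge policies", {
  r <- add_prr(tbl1(20, 80, 100, 9800))
  expect_equal(r$prr, (20 / 100) / (100 / 9900))
  expect_equal(r$prr, 19.8)
  # equal proportions in both margins
  expect_equal(add_prr(tbl1(5, 45, 10, 90))$prr, 1)
  # a = 0 is estimable as 0 and can never signal
  expect_equal(add_prr(tbl1(0, 50, 10, 940))$prr, 0)
  # c = 0 is non-estimable
  expect_true(is.na(add_prr(tbl1(5, 45, 0, 950))$prr))
})

test_that("the Yates chi-square matches an independent generic oracle", {
  t1 <- tbl1(20, 80, 100, 9800)
  mine <- add_chi2(t1)$chi2
  oracle <- unname(suppressWarnings(
    stats::chisq.test(matrix(c(20, 80, 100, 9800), 2, byrow = TRUE))
  )$statistic)
  expect_equal(mine, oracle, tolerance = 1e-12)
  # uncorrected variant against the Pearson oracle
  mine_u <- add_chi2(t1, correct = FALSE)$chi2
  oracle_u <- unname(suppressWarnings(
    stats::chisq.test(matrix(c(20, 80, 100, 9800), 2, byrow = TRUE),
                      correct = FALSE)
  )$statistic)
  expect_equal(mine_u, oracle_u, tolerance = 1e-12)
})

test_that("chi-square clamps the correction near independence and handles zero margins", {
  # all |O - E| < 0.5: statistic must be exactly 0, not negative
  near <- tbl1(25, 25, 25, 25)
  expect_equal(add_chi2(near)$chi2, 0)
  expect_equal(add_chi2(tbl1(0, 0, 10, 90))$chi2, 0)
  # doubling all cells more than doubles the statistic when ratios != 1
  base <- add_chi2(tbl1(20, 80, 100, 9800))$chi2
  dbl <- add_chi2(tbl1(40, 160, 200, 19600))$chi2
  expect_gt(dbl, 2 * base)
})

test_that("the information component matches its closed form", {
  # a = E, both large: independence, IC ~ 0
  t0 <- tbl1(100, 900, 900, 8100)
  expect_equal(add_ic(t0)$ic, 0, tolerance = 1e-10)
  # a = 20, E = 2
  t1 <- tibble::tibble(a = 20, b = 180, c = 80, d = 9720,
                       expected = 2)
  r <- add_ic(t1)
  expect_equal(r$ic, log2(20.5 / 2.5))
  expect_equal(r$ic, 3.036, tolerance = 1e-3)
  expect_equal(r$ic025, r$ic - 1.96 * sqrt((1 / 20.5) / log(2)^2))
  # ic025 < ic always
  set.seed(31)
  rand <- tbl1(sample(1:50, 20, TRUE), sample(1:500, 20, TRUE),
               sample(1:500, 20, TRUE), sample(1000:9000, 20, TRUE))
  r2 <- add_ic(rand)
  expect_true(all(r2$ic025 < r2$ic))
  # z = 2 convention gives a lower bound
  expect_true(all(add_ic(rand, z = 2)$ic025 < r2$ic025))
})

test_that("shrunk and moment BCPNN variants agree for well-filled tables", {
  # agreement regime: a >= 10 and E >= 5 (the moment variant shrinks harder
  # when the expected count is small)
  set.seed(8)
  n <- 100000
  r1 <- sample(500:5000, 40, TRUE)
  E <- runif(40, 5, 60)
  c1 <- round(E * n / r1)
  a <- pmax(10, round(E * runif(40, 0.8, 4)))
  tabs <- tibble::tibble(a = a, b = r1 - a, c = c1 - a, d = n - r1 - c1 + a,
                         expected = r1 * c1 / n)
  tabs <- tabs[tabs$b > 0 & tabs$c > 0, ]
  shrunk <- add_ic(tabs, variant = "shrunk")$ic
  moment <- add_ic(tabs, variant = "moment")$ic
  expect_lt(max(abs(shrunk - moment)), 0.15)
})

test_that("the shrinker prior recovers a pure null (all lambda = 1)", {
  set.seed(101)
  E <- rlnorm(3000, log(3), 1)
  a <- rpois(3000, E)
  fit <- suppressWarnings(gps_fit(tibble::tibble(a = a, expected = E)))
  expect_gte(gps_prior_mean(fit), 0.8)
  expect_lte(gps_prior_mean(fit), 1.2)
  # ascent property: fitted likelihood at least the starting likelihood
  g <- glance(fit)
  expect_gte(g$logLik, g$start_logLik)
})

test_that("the shrinker prior recovers a known two-component mixture", {
  set.seed(202)
  n <- 4000
  E <- rlnorm(n, log(3), 1)
  lam <- ifelse(runif(n) < 0.1, 8, 1)
  a <- rpois(n, lam * E)
  fit <- suppressWarnings(gps_fit(tibble::tibble(a = a, expected = E)))
  means <- c(fit$alpha1 / fit$beta1, fit$alpha2 / fit$beta2)
  weights <- c(fit$w, 1 - fit$w)
  expect_true(any(weights >= 0.05 & means >= 4))
  expect_gte(glance(fit)$logLik, glance(fit)$start_logLik)
})

test_that("too-sparse universes fall back to the diffuse prior with a message", {
  expect_message(
    fit <- gps_fit(tibble::tibble(a = c(1, 2, 0), expected = c(1, 1, 1))),
    "diffuse"
  )
  expect_true(glance(fit)$fallback)
  expect_equal(tidy(fit)$estimate,
               unname(c(0.2, 0.1, 2, 4, 1 / 3)))
})

test_that("EBGM under a near-degenerate null prior stays near 1", {
  pr <- gps_diffuse_prior()
  pr$alpha1 <- 1e4; pr$beta1 <- 1e4; pr$alpha2 <- 1e4; pr$beta2 <- 1e4
  pr$w <- 0.5
  out <- ebgm_stats(a = c(2, 50, 400), expected = c(1, 10, 20), prior = pr)
  expect_equal(out$ebgm, rep(1, 3), tolerance = 0.05)
})

test_that("EBGM approaches the observed ratio under a diffuse prior but shrinks", {
  out <- ebgm_stats(100, 10, gps_diffuse_prior())
  expect_equal(out$ebgm, 10, tolerance = 0.1 * 10)
  expect_lt(out$ebgm, 100 / 10)
  expect_lt(out$ebgm05, out$ebgm)
})

test_that("EBGM is non-decreasing in the observed count at fixed expectation", {
  pr <- fixture_prior()
  out <- ebgm_stats(1:50, 5, pr)
  expect_true(all(diff(out$ebgm) >= -1e-12))
  expect_true(all(out$ebgm05 <= out$ebgm))
})

test_that("closed-form EBGM and EBGM05 match brute-force posterior integration", {
  pr <- fixture_prior()
  set.seed(77)
  a <- sample(1:200, 12, replace = TRUE)
  E <- runif(12, 0.2, 40)
  mine <- ebgm_stats(a, E, pr)
  for (i in seq_along(a)) {
    orc <- oracle_ebgm(a[i], E[i], pr)
    expect_equal(mine$ebgm[i], orc$ebgm, tolerance = 1e-4)
    expect_equal(mine$ebgm05[i], orc$ebgm05, tolerance = 1e-4)
  }
})

test_that("statistics are sign-concordant and shrinkage is bounded on a synthetic universe", {
  gen <- generate_faers(validation_config("recovery", seed = 55, n_cases = 8000))
  cases <- assemble_cases(deduplicate(gen$records))
  st <- suppressWarnings(disproportionality_stats(cases))
  full <- st[st$a >= 5 & st$b >= 5 & st$c >= 5 & st$d >= 5, ]
  expect_true(all(sign(full$ror - 1) == sign(full$prr - 1)))
  # sign(a - E) = sign(ror - 1) exactly, and the +0.5 shrink preserves it
  expect_true(all(sign(full$ror - 1) == sign(full$ic)))
  # ebgm strictly between 1 and a/E for strongly elevated pairs: each
  # posterior component mean interpolates between a/E and that component's
  # prior mean, so shrinkage toward 1 is guaranteed once a/E exceeds every
  # prior component mean (here both are < 3) and the count is informative
  pr <- attr(st, "gps_prior")
  comp_means <- c(pr$alpha1 / pr$beta1, pr$alpha2 / pr$beta2)
  if (gps_prior_mean(pr) <= 1.5 && max(comp_means) < 3) {
    up <- st[st$a / st$expected > 3 & st$a >= 20, ]
    expect_gt(nrow(up), 0)
    expect_true(all(up$ebgm > 1))
    expect_true(all(up$ebgm < up$a / up$expected))
  }
})
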