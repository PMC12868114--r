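test_that("per-block percentages use the block's own denominator", {
  # sex split mirroring a large reporting database: 30216 F, 11810 M, 5299 UNK
  n_f <- 3022; n_m <- 1181; n_u <- 530   # 1/10-scale, same shares
  cases <- make_universe(
    drugs = rep("X", n_f + n_m + n_u),
    pts = rep(list("P"), n_f + n_m + n_u),
    sex = expand_counts(c("F", "M", "UNK"), c(n_f, n_m, n_u))
  )
  s <- demographic_summary(cases)
  expect_equal(s$sex$pct[s$sex$level == "F"],
               100 * n_f / (n_f + n_m + n_u), tolerance = 1e-12)
  check_summary_consistency(s)
})

test_that("a single-category universe reports 100% in that category", {
  cases <- make_universe(drugs = rep("X", 7), pts = rep(list("P"), 7),
                         sex = rep("F", 7))
  s <- demographic_summary(cases)
  expect_equal(s$sex$pct, 100)
  expect_equal(s$sex$n, 7L)
})

test_that("implausible ages are retained by default and cleanable on request", {
  cases <- make_universe(drugs = rep("X", 4), pts = rep(list("P"), 4),
                         age_years = c(30, 40, 50, 23124))
  raw <- demographic_summary(cases)
  expect_equal(raw$age$mean, mean(c(30, 40, 50, 23124)))
  expect_equal(raw$age$max, 23124)
  clean <- demographic_summary(cases, clean_age = TRUE)
  expect_equal(clean$age$mean, 40)
  # the age-group tabulation keeps the outlier either way
  expect_equal(sum(clean$age_group$n), 4L)
})

test_that("onset summaries compute the standard descriptive statistics", {
  on <- tibble::tibble(onset_days = c(1L, 2L, 3L), bin = onset_bin(c(1, 2, 3)))
  s <- onset_summary(on)
  expect_equal(s$stats$mean, 2)
  expect_equal(s$stats$median, 2)
  expect_equal(s$stats$sd, 1)  # n-1 denominator
  expect_false(s$stats$degenerate)
  # a single observation: sd reported as 0 with the degenerate flag
  s1 <- onset_summary(tibble::tibble(onset_days = 5L, bin = onset_bin(5)))
  expect_equal(s1$stats$sd, 0)
  expect_true(s1$stats$degenerate)
  # empty input: explicit empty summary
  s0 <- onset_summary(tibble::tibble(onset_days = integer(),
                                     bin = onset_bin(integer())))
  expect_equal(s0$stats$n, 0L)
  expect_true(is.na(s0$stats$mean))
})

test_that("generated onsets reproduce the configured early-bin share", {
  cfg <- synthetic_config(n_cases = 15000, seed = 29, duplicate_rate = 0,
                          missing_rate = list(event_dt = 0, start_dt = 0))
  gen <- generate_faers(cfg)
  cases <- assemble_cases(deduplicate(gen$records))
  on <- compute_onset(cases, target_names = unique(
    purrr::map_chr(cases$drugs, ~ .x$drugname[1])))
  s <- onset_summary(on)
  share_early <- s$bins$pct[s$bins$level == "0-30"]
  # short-latency component weight 0.45; its mass below 30 days is ~0.82,
  # the long component adds a little: expect the share within a few points
  expect_gt(share_early, 30)
  expect_lt(share_early, 48)
})

test_that("death/non-death blocks use the block grand total and a chi-square test", {
  # equal death rates across sexes: p ~ 1
  cases <- make_universe(
    drugs = rep("X", 400), pts = rep(list("P"), 400),
    sex = rep(c("F", "M"), each = 200),
    outcomes = c(rep(list("DE"), 40), rep(list(character()), 160),
                 rep(list("DE"), 40), rep(list(character()), 160))
  )
  mc <- mortality_comparison(cases)
  expect_equal(mc$n_death, 80L)
  expect_gt(mc$sex_p, 0.9)
  expect_equal(sum(mc$sex$death_n + mc$sex$nondeath_n), 400L)
  expect_equal(sum(mc$sex$death_pct + mc$sex$nondeath_pct), 100, tolerance = 1e-9)
  # death concentrated in one sex: p < 0.001
  cases2 <- make_universe(
    drugs = rep("X", 1000), pts = rep(list("P"), 1000),
    sex = rep(c("F", "M"), each = 500),
    outcomes = c(rep(list("DE"), 150), rep(list(character()), 350),
                 rep(list(character()), 500))
  )
  mc2 <- mortality_comparison(cases2)
  expect_lt(mc2$sex_p, 0.001)
  # independent oracle for the same table
  oracle <- stats::chisq.test(matrix(c(150, 350, 0, 500), 2, byrow = TRUE))
  expect_equal(mc2$sex_p, oracle$p.value, tolerance = 1e-12)
})

test_that("an untestable block is skipped with a reason", {
  cases <- make_universe(drugs = rep("X", 10), pts = rep(list("P"), 10),
                         sex = rep("F", 10),
                         outcomes = rep(list(character()), 10))
  mc <- mortality_comparison(cases)
  expect_true(is.na(mc$sex_p))
  expect_match(mc$sex_skip_reason, "skipped")
})

test_that("the full pipeline is deterministic and recovers the injected signal", {
  cfg <- validation_config("recovery", seed = 71, n_cases = 8000)
  dir1 <- withr::local_tempdir()
  dir2 <- withr::local_tempdir()
  out1 <- suppressWarnings(suppressMessages(run_pipeline(cfg, out_dir = dir1)))
  out2 <- suppressWarnings(suppressMessages(run_pipeline(cfg, out_dir = dir2)))
  # byte-identical statistics tables across runs
  expect_identical(readLines(file.path(dir1, "statistics.tsv")),
                   readLines(file.path(dir2, "statistics.tsv")))
  # flow counts monotonically non-increasing along the filter chain
  flow <- unlist(out1$flow)
  expect_true(all(diff(flow) <= 0))
  # the lambda = 8 pair appears in the all-four table
  expect_true("PT_020" %in% out1$top_frequency$pt)
  expect_true(file.exists(file.path(dir1, "manifest.json")))
})

test_that("a universe with no target cases yields a graceful empty run", {
  cfg <- synthetic_config(n_cases = 300, seed = 5)
  dir <- withr::local_tempdir()
  out <- suppressWarnings(suppressMessages(
    run_pipeline(cfg, target_names = "NOSUCHDRUG", out_dir = dir)
  ))
  expect_equal(out$flow$primary_suspect, 0L)
  expect_equal(out$manifest$status, "EMPTY")
  expect_true(file.exists(file.path(dir, "EMPTY")))
  expect_true(file.exists(file.path(dir, "flow_report.tsv")))
})

test_that("plot helpers return ggplot objects", {
  on <- tibble::tibble(onset_days = c(5L, 10L, 400L),
                       bin = onset_bin(c(5, 10, 400)))
  expect_s3_class(plot_onset_distribution(on), "ggplot")
  rows <- evaluate_criteria(tibble::tibble(
    pt = c("A", "B"), n = c(10, 3), ror_low = c(2, 0.5), prr = c(3, 1),
    chi2 = c(30, 1), ic025 = c(1, -1), ebgm = c(4, 1), ebgm05 = c(2.5, 0.7)
  ))
  expect_s3_class(plot_signal_overview(rows), "ggplot")
  expect_s3_class(ggplot2::autoplot(gps_diffuse_prior()), "ggplot")
})
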