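Package: faersignal
Title: Disproportionality Signal Detection for Spontaneous Adverse Event Reports
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for pharmacovigilance signal detection
    on FAERS-style spontaneous adverse event reports. Reads and writes quarterly
    "$"-delimited ASCII tables (DEMO, DRUG, REAC, OUTC, THER), deduplicates
    cases by the FDA rule (latest FDA_DT, ties broken by PRIMARYID), assembles
    per-case reports, matches a target drug through its name variants, and
    computes four disproportionality statistics per MedDRA Preferred Term:
    reporting odds ratio (ROR), proportional reporting ratio (PRR) with
    Yates-corrected chi-square, the BCPNN information component (IC with IC025),
    and the DuMouchel multi-item gamma-Poisson shrinker (EBGM with EBGM05).
    Includes signal-criteria evaluation, frequency- and intensity-ranked signal
    tables, sex/age/region subgroup re-analysis, time-to-onset and demographic
    summaries, mortality comparisons, and a synthetic FAERS generator with
    injected ground-truth signals for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    generics,
    rlang,
    ggplot2,
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
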