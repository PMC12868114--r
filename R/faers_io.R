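#' Raw multi-table record sets
#'
#' A raw record set bundles the five quarterly tables of a spontaneous-report
#' extract before deduplication: DEMO (one row per submission), DRUG, REAC,
#' OUTC and THER (child tables keyed by `primaryid`). All fields are kept as
#' character strings; in particular dates stay exactly as reported (8-digit
#' `YYYYMMDD`, 6-digit `YYYYMM` or 4-digit `YYYY`) so that partial dates are
#' never silently promoted to day precision.
#'
#' Child rows whose (`primaryid`, `caseid`) pair has no DEMO row are kept but
#' counted as orphans (retrievable via [orphan_counts()]).
#'
#' @param demo,drug,reac,outc,ther Data frames with at least the mandatory
#'   columns of each table (see [faers_schema()]).
#' @return An object of class `raw_record_set`: a named list of five tibbles.
#' @seealso [read_quarter()], [write_quarter()], [generate_faers()]
#' @export
raw_record_set <- function(demo, drug, reac, outc, ther) {
  tabs <- list(demo = demo, drug = drug, reac = reac, outc = outc, ther = ther)
  schema <- faers_schema()
  tabs <- purrr::imap(tabs, function(tab, name) {
    tab <- as_tibble(tab)
    names(tab) <- tolower(names(tab))
    missing <- setdiff(schema[[name]], names(tab))
    if (length(missing) > 0) {
      abort(sprintf(
        "table '%s' is missing mandatory column(s): %s",
        name, paste(missing, collapse = ", ")
      ), class = "faersignal_schema_error")
    }
    dplyr::mutate(tab, dplyr::across(dplyr::everything(), as.character))
  })
  keys <- dplyr::distinct(tabs$demo[c("primaryid", "caseid")])
  orphans <- purrr::map_int(
    tabs[c("drug", "reac", "outc", "ther")],
    function(tab) nrow(anti_join(tab, keys, by = c("primaryid", "caseid")))
  )
  structure(tabs, orphan_counts = orphans, class = "raw_record_set")
}

#' Mandatory columns per quarterly table
#'
#' @return Named list of character vectors, one per table kind.
#' @export
faers_schema <- function() {
  list(
    demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
             "sex", "wt", "occp_cod", "reporter_country"),
    drug = c("primaryid", "caseid", "drug_seq", "role_cod", "drugname"),
    reac = c("primaryid", "caseid", "pt"),
    outc = c("primaryid", "caseid", "outc_cod"),
    ther = c("primaryid", "caseid", "dsg_drug_seq", "start_dt")
  )
}

#' @export
print.raw_record_set <- function(x, ...) {
  cat("<raw_record_set>\n")
  for (nm in names(x)) {
    cat(sprintf("  %s: %d rows\n", nm, nrow(x[[nm]])))
  }
  orp <- orphan_counts(x)
  if (any(orp > 0)) {
    cat("  orphan child rows:",
        paste(sprintf("%s=%d", names(orp)[orp > 0], orp[orp > 0]),
              collapse = ", "), "\n")
  }
  invisible(x)
}

#' Orphan child-row counts of a raw record set
#'
#' @param records A [raw_record_set()].
#' @return Named integer vector (drug, reac, outc, ther): child rows whose
#'   (`primaryid`, `caseid`) pair is absent from DEMO.
#' @export
orphan_counts <- function(records) {
  stopifnot(inherits(records, "raw_record_set"))
  attr(records, "orphan_counts")
}

#' Read one quarter of "$"-delimited ASCII tables
#'
#' Reads the DEMO/DRUG/REAC/OUTC/THER files of a quarterly release. Every
#' column is read as character (dates are preserved verbatim), header names
#' are matched case-insensitively, and rows the parser cannot interpret are
#' collected into a rejects report rather than dropped silently.
#'
#' @param paths Named character vector or list with elements `demo`, `drug`,
#'   `reac`, `outc`, `ther` giving one file path per table.
#' @param delim Field delimiter; `"$"` as in the public quarterly ASCII
#'   releases.
#' @param quiet Suppress the per-table row-count messages.
#' @return A [raw_record_set()]. Parse problems, if any, are attached as a
#'   tibble in the `"rejects"` attribute.
#' @export
read_quarter <- function(paths, delim = "$", quiet = FALSE) {
  needed <- c("demo", "drug", "reac", "outc", "ther")
  if (!all(needed %in% names(paths))) {
    abort(paste0("`paths` must name files for: ", paste(needed, collapse = ", ")))
  }
  rejects <- list()
  tabs <- purrr::map(setNames(needed, needed), function(nm) {
    path <- paths[[nm]]
    if (!file.exists(path)) {
      abort(sprintf("file for table '%s' not found: %s", nm, path))
    }
    tab <- readr::read_delim(
      path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
      na = "", progress = FALSE, show_col_types = FALSE
    )
    prob <- readr::problems(tab)
    if (nrow(prob) > 0) {
      rejects[[nm]] <<- dplyr::mutate(as_tibble(prob), table = nm)
    }
    if (!quiet) inform(sprintf("read_quarter: %s rows in '%s'", nrow(tab), nm))
    tab
  })
  out <- raw_record_set(tabs$demo, tabs$drug, tabs$reac, tabs$outc, tabs$ther)
  attr(out, "rejects") <- if (length(rejects) > 0) bind_rows(rejects) else tibble()
  out
}

#' Write a record set as "$"-delimited ASCII tables
#'
#' Emits one file per table (`demo.txt`, `drug.txt`, ...) re-readable by
#' [read_quarter()] with bit-identical string fields. Missing values are
#' written as empty fields. A field containing the delimiter cannot be
#' represented in this format and raises an error.
#'
#' @param records A [raw_record_set()].
#' @param out_dir Output directory (created if absent).
#' @inheritParams read_quarter
#' @return Invisibly, the named vector of files written.
#' @export
write_quarter <- function(records, out_dir, delim = "$") {
  stopifnot(inherits(records, "raw_record_set"))
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  files <- setNames(file.path(out_dir, paste0(names(records), ".txt")),
                    names(records))
  for (nm in names(records)) {
    tab <- records[[nm]]
    bad <- purrr::map_lgl(tab, ~ any(grepl(delim, .x, fixed = TRUE), na.rm = TRUE))
    if (any(bad)) {
      abort(sprintf(
        "table '%s': field(s) %s contain the delimiter '%s' and cannot be written",
        nm, paste(names(tab)[bad], collapse = ", "), delim
      ))
    }
    readr::write_delim(tab, files[[nm]], delim = delim, na = "", quote = "none")
  }
  invisible(files)
}

#' Read a Preferred Term to System Organ Class map
#'
#' The licensed MedDRA dictionary cannot ship with analysis code, so the
#' PT-to-SOC assignment is supplied as a plain two-column delimited file
#' (PT, SOC). Terms absent from the map fall back to the sentinel class
#' `"UNMAPPED"` at lookup time.
#'
#' @param path Two-column delimited text file with header `pt`, `soc`.
#' @param delim Field delimiter (default `"$"`).
#' @return A tibble with columns `pt`, `soc`; one row per PT.
#' @export
read_meddra_map <- function(path, delim = "$") {
  map <- readr::read_delim(
    path, delim = delim, col_types = readr::cols(.default = readr::col_character()),
    na = "", progress = FALSE, show_col_types = FALSE
  )
  names(map) <- tolower(names(map))
  if (!all(c("pt", "soc") %in% names(map))) {
    abort("MedDRA map must have columns 'pt' and 'soc'",
          class = "faersignal_schema_error")
  }
  dup <- map$pt[duplicated(map$pt)]
  if (length(dup) > 0) {
    abort(sprintf("PT(s) mapped to more than one SOC: %s",
                  paste(unique(dup), collapse = ", ")))
  }
  dplyr::select(map, "pt", "soc")
}

#' Look up the primary SOC for each PT
#'
#' @param pts Character vector of Preferred Terms.
#' @param map Tibble with columns `pt`, `soc` (see [read_meddra_map()]).
#' @return Character vector of SOCs; unmapped PTs return `"UNMAPPED"`.
#' @export
pt_to_soc <- function(pts, map) {
  out <- map$soc[match(pts, map$pt)]
  out[is.na(out)] <- "UNMAPPED"
  out
}
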