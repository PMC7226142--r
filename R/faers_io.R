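#' FAERS table dialect
#'
#' Declares the required columns of each of the six quarterly ASCII tables
#' the pipeline consumes. The layout follows the post-2012 FAERS convention
#' (one `"$"`-separated file per entity, keyed by `primaryid`), with one
#' deliberate extension: the reaction table carries an `onset_dt` column so
#' that each MedDRA-coded event keeps its own onset date. Schema descriptors
#' are plain named lists, so site-specific dialects can be passed to
#' [read_table_set()] in place of this default.
#'
#' @return named list of character vectors (required columns per table).
#' @export
faers_dialect <- function() {
  list(
    demo = c("primaryid", "caseid", "caseversion", "age", "age_cod", "sex",
             "occp_cod", "reporter_country", "rept_yr"),
    drug = c("primaryid", "drug_seq", "role_cod", "drugname"),
    reac = c("primaryid", "pt", "onset_dt"),
    outc = c("primaryid", "outc_cod"),
    indi = c("primaryid", "indi_drug_seq", "indi_pt"),
    ther = c("primaryid", "dsg_drug_seq", "start_dt", "end_dt")
  )
}

outcome_codes <- function() {
  c(DE = "death", LT = "life-threatening", HO = "hospitalization",
    DS = "disability", RI = "required intervention", CA = "congenital anomaly",
    OT = "other serious")
}

drug_roles <- function() {
  c(PS = "primary suspect", SS = "secondary suspect",
    C = "concomitant", I = "interacting")
}

#' Read a FAERS-dialect table set
#'
#' Reads the six delimited ASCII tables of one quarterly extract into memory.
#' All values are read as character; typing happens in [assemble_reports()].
#' Rows without a report identifier are dropped and counted, as are child
#' rows whose identifier does not occur in the demographics table.
#'
#' @param paths named list/vector of file paths with names
#'   `demo, drug, reac, outc, indi, ther`.
#' @param dialect schema descriptor, see [faers_dialect()]. Tables present in
#'   the dialect but absent from `paths` raise an error.
#' @param delim field delimiter; FAERS ships `"$"`, fixtures may use `","`.
#' @param source_quarter free-text label for provenance.
#' @return an object of class `raw_table_set`: the six tibbles plus a
#'   `load_report` tibble counting rows dropped per table and the quarter
#'   label.
#' @export
read_table_set <- function(paths, dialect = faers_dialect(), delim = "$",
                           source_quarter = NA_character_) {
  missing_tbl <- setdiff(names(dialect), names(paths))
  assert_that(length(missing_tbl) == 0,
              paste0("no path supplied for table(s): ",
                     paste(missing_tbl, collapse = ", ")))
  tabs <- list()
  load_report <- list()
  for (nm in names(dialect)) {
    path <- paths[[nm]]
    assert_that(file.exists(path), paste0("file not found: ", path))
    tab <- readr::read_delim(path, delim = delim, quote = "",
                             col_types = readr::cols(.default = readr::col_character()),
                             na = character(), progress = FALSE,
                             show_col_types = FALSE)
    miss <- setdiff(dialect[[nm]], names(tab))
    if (length(miss)) {
      hdr <- readLines(path, n = 1L)
      stop("schema error in ", path, ": missing column(s) ",
           paste(miss, collapse = ", "), "; first line was: ", hdr,
           call. = FALSE)
    }
    nokey <- is.na(tab$primaryid) | tab$primaryid == ""
    load_report[[nm]] <- tibble::tibble(table = nm,
                                        n_read = nrow(tab),
                                        n_dropped_no_key = sum(nokey),
                                        n_dropped_orphan = 0L)
    tabs[[nm]] <- tab[!nokey, , drop = FALSE]
  }
  keys <- unique(tabs$demo$primaryid)
  for (nm in setdiff(names(tabs), "demo")) {
    orphan <- !(tabs[[nm]]$primaryid %in% keys)
    load_report[[nm]]$n_dropped_orphan <- sum(orphan)
    tabs[[nm]] <- tabs[[nm]][!orphan, , drop = FALSE]
  }
  new_raw_table_set(tabs, dplyr::bind_rows(load_report), source_quarter)
}

new_raw_table_set <- function(tabs, load_report, source_quarter = NA_character_) {
  structure(c(tabs,
              list(load_report = load_report, source_quarter = source_quarter)),
            class = "raw_table_set")
}

#' @export
print.raw_table_set <- function(x, ...) {
  cat("<raw_table_set>", if (!is.na(x$source_quarter)) x$source_quarter, "\n")
  for (nm in c("demo", "drug", "reac", "outc", "indi", "ther"))
    cat(sprintf("  %-5s %d rows\n", nm, nrow(x[[nm]])))
  invisible(x)
}

#' Write a FAERS-dialect table set
#'
#' Inverse of [read_table_set()]; fields are written verbatim with no
#' quoting, matching the FAERS ASCII convention. Round-trips complete
#' records byte-for-byte.
#'
#' @param tables a `raw_table_set`.
#' @param dir output directory (created if absent).
#' @param delim field delimiter.
#' @return invisibly, the named vector of file paths written.
#' @export
write_table_set <- function(tables, dir, delim = "$") {
  stopifnot(inherits(tables, "raw_table_set"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  nms <- c("demo", "drug", "reac", "outc", "indi", "ther")
  paths <- setNames(file.path(dir, paste0(nms, ".txt")), nms)
  for (nm in nms) {
    readr::write_delim(tables[[nm]], paths[[nm]], delim = delim,
                       quote = "none", escape = "none", na = "")
  }
  invisible(paths)
}

# FAERS age codes to years; unconvertible codes yield NA
convert_age_years <- function(age, age_cod) {
  a <- suppressWarnings(as.numeric(age))
  cod <- toupper(trimws(ifelse(is.na(age_cod), "", age_cod)))
  f <- dplyr::case_when(
    cod %in% c("", "YR") ~ 1,
    cod == "DEC" ~ 10,
    cod == "MON" ~ 1 / 12,
    cod == "WK" ~ 1 / 52.18,
    cod == "DY" ~ 1 / 365.25,
    cod == "HR" ~ 1 / 8766,
    TRUE ~ NA_real_
  )
  out <- a * f
  out[!is.na(out) & out < 0] <- NA_real_
  out
}

#' Age class bins
#'
#' Maps age in years onto the four bins used throughout the descriptive
#' tables and as adjustment covariate, with an explicit `"unknown"` level for
#' missing ages. Bounds are inclusive as labelled: 25 falls in the first bin,
#' 26 in the second.
#'
#' @param age_years numeric vector (may contain `NA`).
#' @return factor with levels `"<=25", "26-50", "51-75", ">=76", "unknown"`.
#' @export
age_class_of <- function(age_years) {
  lab <- dplyr::case_when(
    is.na(age_years) ~ "unknown",
    age_years <= 25 ~ "<=25",
    age_years <= 50 ~ "26-50",
    age_years <= 75 ~ "51-75",
    TRUE ~ ">=76"
  )
  factor(lab, levels = age_levels())
}

age_levels <- function() c("<=25", "26-50", "51-75", ">=76", "unknown")

normalize_sex <- function(x) {
  x <- toupper(trimws(ifelse(is.na(x), "", x)))
  dplyr::case_when(x == "F" ~ "female", x == "M" ~ "male", TRUE ~ "unknown")
}

normalize_reporter <- function(occp_cod) {
  x <- toupper(trimws(ifelse(is.na(occp_cod), "", occp_cod)))
  dplyr::case_when(
    x %in% c("MD", "PH", "OT", "RN", "HP") ~ "health professional",
    x %in% c("CN", "LW") ~ "nonhealth professional",
    TRUE ~ "unknown"
  )
}

#' Assemble report-level data from raw tables
#'
#' Groups the line-oriented raw tables (one line per drug or per reaction)
#' into one record per report identifier, derives the age class, the
#' normalized sex/reporter/country fields and the seriousness flag (a report
#' is serious iff it has at least one outcome code), and parses all partial
#' dates. Conflicting demographic lines for one identifier keep the first
#' occurrence and are counted.
#'
#' @param tables a `raw_table_set` from [read_table_set()] or
#'   [generate_faers()].
#' @return an object of class `faers_reports`: a list of three tibbles,
#'   `reports` (one row per report), `drugs` (one row per drug line, with
#'   parsed therapy dates) and `events` (one row per reaction line, with
#'   parsed onset), plus an assembly log.
#' @export
assemble_reports <- function(tables) {
  stopifnot(inherits(tables, "raw_table_set"))
  demo <- tables$demo
  dup_demo <- duplicated(demo$primaryid)
  n_conflict <- sum(dup_demo)
  if (n_conflict > 0) {
    message(n_conflict, " duplicated demographic line(s) for the same report ",
            "identifier; keeping the first of each")
    demo <- demo[!dup_demo, , drop = FALSE]
  }

  serious_ids <- unique(tables$outc$primaryid[!is.na(tables$outc$outc_cod) &
                                                tables$outc$outc_cod != ""])
  oc <- tables$outc[tables$outc$outc_cod %in% names(outcome_codes()), ,
                    drop = FALSE]
  oc <- oc[!duplicated(paste(oc$primaryid, oc$outc_cod)), , drop = FALSE]
  outc_split <- split(unname(outcome_codes()[oc$outc_cod]), oc$primaryid)

  age_years <- convert_age_years(demo$age, demo$age_cod)
  reports <- tibble::tibble(
    report_id = demo$primaryid,
    case_id = demo$caseid,
    version_seq = {
      v <- suppressWarnings(as.integer(demo$caseversion))
      ifelse(is.na(v), 1L, v)
    },
    age_years = age_years,
    age_class = age_class_of(age_years),
    sex = normalize_sex(demo$sex),
    reporter_type = normalize_reporter(demo$occp_cod),
    country = {
      cc <- trimws(ifelse(is.na(demo$reporter_country), "", demo$reporter_country))
      ifelse(cc == "", "unknown", cc)
    },
    reporting_year = suppressWarnings(as.integer(demo$rept_yr)),
    serious = demo$primaryid %in% serious_ids
  )
  oix <- match(reports$report_id, names(outc_split))
  reports$outcomes <- lapply(oix, function(j)
    if (is.na(j)) character(0) else outc_split[[j]])

  ther <- tables$ther
  start <- parse_partial_date(ther$start_dt, quiet = TRUE)
  end <- parse_partial_date(ther$end_dt, quiet = TRUE)
  ther_parsed <- tibble::tibble(primaryid = ther$primaryid,
                                drug_seq = ther$dsg_drug_seq,
                                start_date = start$date,
                                start_precision = start$precision,
                                end_date = end$date,
                                end_precision = end$precision) |>
    dplyr::distinct(.data$primaryid, .data$drug_seq, .keep_all = TRUE)

  drugs <- tibble::tibble(
    report_id = tables$drug$primaryid,
    drug_seq = tables$drug$drug_seq,
    verbatim_name = tables$drug$drugname,
    role = {
      r <- drug_roles()[toupper(trimws(tables$drug$role_cod))]
      ifelse(is.na(r), "concomitant", unname(r))
    }
  ) |>
    dplyr::left_join(ther_parsed,
                     by = c(report_id = "primaryid", drug_seq = "drug_seq")) |>
    dplyr::mutate(start_precision = dplyr::coalesce(.data$start_precision, "missing"),
                  end_precision = dplyr::coalesce(.data$end_precision, "missing"))

  onset <- parse_partial_date(tables$reac$onset_dt, quiet = TRUE)
  events <- tibble::tibble(
    report_id = tables$reac$primaryid,
    preferred_term = tables$reac$pt,
    term_norm = norm_term(tables$reac$pt),
    onset_date = onset$date,
    onset_precision = onset$precision
  ) |>
    dplyr::filter(!is.na(.data$preferred_term) & .data$preferred_term != "")

  new_faers_reports(reports, drugs, events,
                    log = tibble::tibble(n_demo_conflicts = n_conflict))
}

new_faers_reports <- function(reports, drugs, events, log = NULL) {
  structure(list(reports = reports, drugs = drugs, events = events, log = log),
            class = "faers_reports")
}

#' @export
print.faers_reports <- function(x, ...) {
  cat("<faers_reports>\n",
      sprintf("  %d reports (%d serious), %d drug lines, %d event lines\n",
              nrow(x$reports), sum(x$reports$serious),
              nrow(x$drugs), nrow(x$events)))
  invisible(x)
}

# restrict all component tables to a set of report ids
subset_reports <- function(store, keep_ids) {
  new_faers_reports(
    store$reports[store$reports$report_id %in% keep_ids, , drop = FALSE],
    store$drugs[store$drugs$report_id %in% keep_ids, , drop = FALSE],
    store$events[store$events$report_id %in% keep_ids, , drop = FALSE],
    log = store$log
  )
}
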