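#' Report-inclusion funnel
#'
#' Applies, in fixed order, the three exclusion stages of the analysis:
#' nonserious reports, duplicates (two-step), and aberrant reports whose
#' drug start dates postdate the adverse event. Each stage is also exposed
#' on its own ([filter_serious()], [deduplicate()], [remove_aberrant()]).
#'
#' @param store a `faers_reports` object (drug lines should be resolved if
#'   the aberrant stage is to see suspect-drug start dates; the stage itself
#'   only needs roles and dates).
#' @return list with `store` (retained reports) and `funnel` (a
#'   `funnel_report`).
#' @export
preprocess_reports <- function(store) {
  n_input <- nrow(store$reports)
  s1 <- filter_serious(store)
  s2 <- deduplicate(s1$store)
  s3 <- remove_aberrant(s2$store)
  fr <- funnel_report(n_input = n_input,
                      n_nonserious_removed = s1$n_removed,
                      n_duplicates_removed = s2$n_removed,
                      n_aberrant_removed = s3$n_removed)
  list(store = s3$store, funnel = fr)
}

#' Funnel bookkeeping record
#'
#' @param n_input,n_nonserious_removed,n_duplicates_removed,n_aberrant_removed
#'   nonnegative integers; the retained count is derived and the additive
#'   identity is enforced.
#' @return object of class `funnel_report`.
#' @export
funnel_report <- function(n_input, n_nonserious_removed, n_duplicates_removed,
                          n_aberrant_removed) {
  n_retained <- n_input - n_nonserious_removed - n_duplicates_removed -
    n_aberrant_removed
  assert_that(all(c(n_input, n_nonserious_removed, n_duplicates_removed,
                    n_aberrant_removed, n_retained) >= 0),
              "funnel counts must be nonnegative and must not exceed the input")
  structure(list(n_input = n_input,
                 n_nonserious_removed = n_nonserious_removed,
                 n_duplicates_removed = n_duplicates_removed,
                 n_aberrant_removed = n_aberrant_removed,
                 n_retained = n_retained),
            class = "funnel_report")
}

#' @export
print.funnel_report <- function(x, ...) {
  cat("<funnel_report>\n",
      sprintf("  input      %d\n", x$n_input),
      sprintf("  nonserious -%d\n", x$n_nonserious_removed),
      sprintf("  duplicates -%d\n", x$n_duplicates_removed),
      sprintf("  aberrant   -%d\n", x$n_aberrant_removed),
      sprintf("  retained   %d\n", x$n_retained), sep = "")
  invisible(x)
}

#' Keep serious reports only
#'
#' @param store a `faers_reports`.
#' @return list with `store` (serious reports) and `n_removed`.
#' @export
filter_serious <- function(store) {
  keep <- store$reports$report_id[store$reports$serious]
  list(store = subset_reports(store, keep),
       n_removed = nrow(store$reports) - length(keep))
}

# five-field duplicate key: sorted event-term set, earliest event onset,
# age, sex, country; missing values compare equal only to missing
dedup_key <- function(store) {
  r <- store$reports
  if (nrow(store$events)) {
    ev <- data.table::as.data.table(
      store$events[, c("report_id", "term_norm", "onset_date")])
    terms_dt <- unique(ev[, c("report_id", "term_norm")])
    data.table::setorder(terms_dt, report_id, term_norm)
    terms_dt <- terms_dt[, list(terms = paste(term_norm, collapse = "|")),
                         by = "report_id"]
    # sentinel keeps the grouped min branch-free; it denotes "all missing"
    sentinel <- .Machine$integer.max
    ev[, onset_num := data.table::fifelse(is.na(onset_date), sentinel,
                                          as.integer(onset_date))]
    onset_dt <- ev[, list(onset_num = min(onset_num)), by = "report_id"]
    onset_dt[, onset_key := data.table::fifelse(onset_num == sentinel, "NA",
                                                as.character(onset_num))]
    terms <- terms_dt$terms[match(r$report_id, terms_dt$report_id)]
    onset <- onset_dt$onset_key[match(r$report_id, onset_dt$report_id)]
  } else {
    terms <- onset <- rep(NA_character_, nrow(r))
  }
  tibble::tibble(
    report_id = r$report_id, case_id = r$case_id,
    version_seq = r$version_seq,
    dedup_key = paste(dplyr::coalesce(terms, ""),
                      dplyr::coalesce(onset, "NA"),
                      ifelse(is.na(r$age_years), "NA",
                             format(r$age_years, digits = 10)),
                      r$sex, r$country, sep = "\r"))
}

#' Two-step deduplication
#'
#' Step 1 keeps, within each case identifier, only the highest follow-up
#' version. Step 2 then groups the survivors on the five-field duplicate key
#' (event-term set, earliest event onset date, age, sex, country) and keeps
#' one representative per group — the lexicographically smallest report id,
#' a deterministic tie-break.
#'
#' @param store a `faers_reports`.
#' @return list with `store`, `n_removed` (total), and the per-step counts
#'   `n_removed_versions`, `n_removed_key`.
#' @export
deduplicate <- function(store) {
  k <- dedup_key(store)
  # step 1: within case, keep the highest version (smallest id on ties)
  o <- order(k$case_id, -k$version_seq, k$report_id)
  latest <- k[o, , drop = FALSE]
  latest <- latest[!duplicated(latest$case_id), , drop = FALSE]
  n_versions <- nrow(k) - nrow(latest)
  # step 2: one representative per duplicate key, smallest report id
  o <- order(latest$dedup_key, latest$report_id)
  reps <- latest[o, , drop = FALSE]
  reps <- reps[!duplicated(reps$dedup_key), , drop = FALSE]
  n_key <- nrow(latest) - nrow(reps)
  list(store = subset_reports(store, reps$report_id),
       n_removed = n_versions + n_key,
       n_removed_versions = n_versions,
       n_removed_key = n_key)
}

#' Exclude aberrant reports
#'
#' A report is aberrant when the recorded start of therapy postdates the
#' adverse event: every suspect drug line with a full-precision start date
#' starts strictly after the earliest full-precision event onset. Reports
#' with no full-precision evidence on either side are retained (partial or
#' missing dates are insufficient evidence of aberrance).
#'
#' @param store a `faers_reports`.
#' @return list with `store` and `n_removed`.
#' @export
remove_aberrant <- function(store) {
  dayev <- store$events[store$events$onset_precision == "day",
                        c("report_id", "onset_date")]
  sus <- store$drugs[store$drugs$role %in% c("primary suspect",
                                             "secondary suspect") &
                       store$drugs$start_precision == "day",
                     c("report_id", "start_date")]
  sdt <- data.table::as.data.table(sus)
  bad <- character(0)
  if (nrow(sdt) && nrow(dayev)) {
    odt <- data.table::as.data.table(dayev)
    odt[, onset_num := as.integer(onset_date)]
    oref <- odt[, list(onset_ref = min(onset_num)), by = "report_id"]
    sdt[, start_num := as.integer(start_date)]
    m <- merge(sdt, oref, by = "report_id")
    if (nrow(m)) {
      m[, ok := as.integer(start_num <= onset_ref)]
      agg <- m[, list(n_ok = sum(ok)), by = "report_id"]
      bad <- agg$report_id[agg$n_ok == 0L]
    }
  }
  keep <- setdiff(store$reports$report_id, bad)
  list(store = subset_reports(store, keep), n_removed = length(bad))
}
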