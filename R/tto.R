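#' Time-to-onset per case
#'
#' Time-to-onset is the event onset date minus the therapy start date, in
#' whole days. For each case report exposed to the index drug it uses the
#' earliest qualifying event onset (an event matching the query at the given
#' scope) and the drug's earliest full-precision therapy start. A record is
#' informative only when both dates have day precision and the onset is not
#' before the start; non-informative records are flagged, never silently
#' dropped.
#'
#' @param store a resolved `faers_reports`.
#' @param labels [classify_cases()] output.
#' @param exposures [flag_exposures()] output.
#' @param catalogue an [smq_catalogue()].
#' @param drug index drug INN.
#' @param smq query name.
#' @param scope term scope.
#' @return tibble with one row per exposed case: `report_id`, `drug`,
#'   `smq_name`, `tto_days` (`NA` unless informative), `informative`.
#' @export
compute_tto <- function(store, labels, exposures, catalogue, drug, smq,
                        scope = "narrow") {
  lab <- labels[labels$smq_name == smq & labels$is_case, , drop = FALSE]
  exposed_ids <- exposures$report_id[
    vapply(exposures$tki_set, function(s) drug %in% s, logical(1))]
  ids <- intersect(lab$report_id, exposed_ids)
  terms <- smq_terms(catalogue, smq, scope)

  # length-guarded: summarise probes expressions on an empty slice
  min_date <- function(x) if (length(x) == 0) as.Date(NA) else min(x)

  onset <- store$events |>
    dplyr::filter(.data$report_id %in% ids,
                  .data$term_norm %in% terms,
                  .data$onset_precision == "day") |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(onset = min_date(.data$onset_date), .groups = "drop")

  start <- store$drugs |>
    dplyr::filter(.data$report_id %in% ids,
                  .data$start_precision == "day",
                  vapply(.data$inn, function(v) drug %in% v, logical(1))) |>
    dplyr::group_by(.data$report_id) |>
    dplyr::summarise(start = min_date(.data$start_date), .groups = "drop")

  tibble::tibble(report_id = ids, drug = drug, smq_name = smq) |>
    dplyr::left_join(onset, by = "report_id") |>
    dplyr::left_join(start, by = "report_id") |>
    dplyr::mutate(
      informative = !is.na(.data$onset) & !is.na(.data$start) &
        .data$onset >= .data$start,
      tto_days = ifelse(.data$informative,
                        as.integer(.data$onset - .data$start), NA_integer_)) |>
    dplyr::select("report_id", "drug", "smq_name", "tto_days", "informative")
}

#' Summarize time-to-onset
#'
#' Median and interquartile range over the informative records, after
#' capping at `cap_days` (capped values are retained, not excluded — the
#' repeated upper quartile at the cap in long-latency pairs reflects
#' truncation). Quantiles use linear interpolation between order statistics.
#' Also returns the cumulative distribution over `0..cap_days` for step
#' plots.
#'
#' @param records a [compute_tto()] tibble (or any tibble with `tto_days`,
#'   `informative`).
#' @param cap_days truncation horizon in days (default 365).
#' @return list with `available`, `n_informative`, `median`, `q1`, `q3`,
#'   and `cdf` (tibble `t`, `p` with `p` = fraction of informative records
#'   with capped onset time `<= t`).
#' @export
summarize_tto <- function(records, cap_days = 365) {
  x <- records$tto_days[records$informative]
  x <- x[!is.na(x)]
  if (length(x) == 0) {
    return(list(available = FALSE, n_informative = 0L,
                median = NA_real_, q1 = NA_real_, q3 = NA_real_,
                cdf = tibble::tibble(t = integer(), p = numeric())))
  }
  capped <- pmin(x, cap_days)
  q <- unname(stats::quantile(capped, c(0.25, 0.5, 0.75), type = 7))
  tt <- 0:cap_days
  cdf <- tibble::tibble(t = tt,
                        p = vapply(tt, function(u) mean(capped <= u),
                                   numeric(1)))
  list(available = TRUE, n_informative = length(x),
       median = q[2], q1 = q[1], q3 = q[3], cdf = cdf)
}
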