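#' Counts and display percentages for one stratification
#'
#' Turns raw counts into the `n (%)` presentation used in descriptive
#' safety tables: percentages of the stratification total, rounded half-up
#' to one decimal. Full precision is kept in the `pct_exact` column.
#'
#' @param counts named numeric vector, or data frame with columns `stratum`
#'   and `n`.
#' @param total denominator; defaults to the sum of the counts (pass the
#'   group total explicitly when the strata do not exhaust it).
#' @return tibble with `stratum`, `n`, `pct` (1 decimal, half-up) and
#'   `pct_exact`.
#' @examples
#' describe_counts(c(nilotinib = 2319, dasatinib = 835), total = 3930)
#' @export
describe_counts <- function(counts, total = NULL) {
  if (is.data.frame(counts)) {
    df <- tibble::tibble(stratum = as.character(counts$stratum),
                         n = as.numeric(counts$n))
  } else {
    df <- tibble::tibble(stratum = names(counts), n = as.numeric(counts))
  }
  total <- total %||% sum(df$n)
  assert_that(total > 0, "total must be positive")
  df$pct_exact <- 100 * df$n / total
  df$pct <- round_half_up(df$pct_exact, 1)
  df[, c("stratum", "n", "pct", "pct_exact")]
}

#' Descriptive summary of a report set
#'
#' Counts and percentages per stratum for the requested categorical
#' variables, plus the median and interquartile range of age — the layout
#' of a baseline-characteristics table for cases (or non-cases) of a
#' query.
#'
#' @param reports the `reports` tibble of a `faers_reports` (or any subset
#'   of its rows, e.g. the cases of one SMQ).
#' @param vars categorical columns to tabulate.
#' @return list with one [describe_counts()] tibble per variable and an
#'   `age` element (`median`, `q1`, `q3`, `n_known`).
#' @export
descriptive_summary <- function(reports,
                                vars = c("age_class", "sex", "reporter_type",
                                         "country", "reporting_year")) {
  out <- lapply(setNames(vars, vars), function(v) {
    tab <- table(as.character(reports[[v]]), useNA = "no")
    describe_counts(setNames(as.numeric(tab), names(tab)),
                    total = nrow(reports))
  })
  age <- reports$age_years[!is.na(reports$age_years)]
  out$age <- if (length(age)) {
    q <- unname(stats::quantile(age, c(0.25, 0.5, 0.75), type = 7))
    list(median = q[2], q1 = q[1], q3 = q[3], n_known = length(age))
  } else {
    list(median = NA_real_, q1 = NA_real_, q3 = NA_real_, n_known = 0L)
  }
  out
}

#' Forest plot of the disproportionality screen
#'
#' One panel per query; points are adjusted RORs, whiskers the 95%
#' intervals, the dashed reference line sits at 1, and signals of
#' disproportionate reporting are drawn solid. The plotted numbers are the
#' screen's own output, carried unchanged in `attr(, "table")`.
#'
#' @param results the `results` tibble of a [screen_all()] object (or the
#'   object itself).
#' @return a ggplot; the untouched results table is attached as attribute
#'   `table`.
#' @export
render_forest <- function(results) {
  if (inherits(results, "dispro_screen")) results <- results$results
  assert_that(nrow(results) >= 1, "no eligible results to plot")
  df <- results[!is.na(results$adj_ror), , drop = FALSE]
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$adj_ror, y = .data$drug)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed", colour = "grey40") +
    ggplot2::geom_errorbarh(ggplot2::aes(xmin = .data$adj_ci_low,
                                         xmax = .data$adj_ci_high),
                            height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(shape = .data$sdr), size = 2) +
    ggplot2::scale_shape_manual(values = c(`TRUE` = 16, `FALSE` = 1),
                                name = "SDR") +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~smq_name, scales = "free_x") +
    ggplot2::labs(x = "adjusted ROR (95% CI, log scale)", y = NULL)
  attr(p, "table") <- results
  p
}

#' Display-rounded screen table
#'
#' RORs and interval bounds rounded half-up to one decimal for rendering;
#' machine-readable output should use the screen's full-precision table.
#'
#' @param results `results` tibble of a [screen_all()] object.
#' @return tibble with rounded `crude_ror`, `adj_ror` and interval columns.
#' @export
format_screen <- function(results) {
  if (inherits(results, "dispro_screen")) results <- results$results
  dplyr::mutate(results, dplyr::across(
    c("crude_ror", "crude_ci_low", "crude_ci_high",
      "adj_ror", "adj_ci_low", "adj_ci_high"),
    ~ round_half_up(.x, 1)))
}

#' Published descriptive counts for TKI cardiovascular cases
#'
#' The report counts of the published FAERS screen of cardiovascular
#' toxicity under CML tyrosine-kinase inhibitors (2008--2018; 64,232
#' cardiovascular cases among 717,163 serious anticancer reports, 3,930 of
#' them TKI-exposed). Used as worked-example input for
#' [describe_counts()]: feeding these counts through it reproduces the
#' published percentages.
#'
#' @return nested list of named count vectors with totals
#'   `n_cv_cases`, `n_tki_cases`, `n_tki_noncases`.
#' @export
tki_cv_reference_counts <- function() {
  list(
    n_cv_cases = 64232,
    n_tki_cases = 3930,
    n_tki_noncases = 20443,
    n_anticancer_retained = 717163,
    exposure_of_cv_cases = c(tki = 3930, `other anticancer` = 60302),
    drug_of_tki_cases = c(bosutinib = 38, dasatinib = 835, imatinib = 173,
                          nilotinib = 2319, ponatinib = 565),
    indication_of_tki_cases = c(`chronic myeloid leukemia` = 2678,
                                `acute myeloid leukemia` = 16,
                                `acute lymphocytic leukemia` = 159,
                                `myeloid leukemia` = 22,
                                `gastrointestinal stromal tumour` = 52,
                                hypertension = 19, other = 341, unknown = 643),
    outcome_of_tki_cases = c(death = 396, `life-threatening` = 171,
                             hospitalization = 1375, disability = 63,
                             `required intervention` = 2,
                             `congenital anomaly` = 1, `other serious` = 1922),
    sex_of_tki_cases = c(female = 1423, male = 2079, unknown = 428),
    reporter_of_tki_cases = c(`health professional` = 2877,
                              `nonhealth professional` = 951, unknown = 102),
    country_of_tki_cases = c(US = 1263, JP = 418, DE = 293, FR = 275,
                             other = 1505, unknown = 176),
    year_of_tki_cases = c(`2008` = 120, `2009` = 106, `2010` = 163,
                          `2011` = 209, `2012` = 284, `2013` = 422,
                          `2014` = 546, `2015` = 415, `2016` = 481,
                          `2017` = 501, `2018` = 679, unknown = 4),
    smq_of_tki_cases = c(`cardiac arrhythmias` = 126, `cardiac failure` = 669,
                         cardiomyopathy = 78,
                         `embolic and thrombotic events` = 1049,
                         hypertension = 306, `ischaemic heart disease` = 1306,
                         `pulmonary hypertension` = 127,
                         `torsade de pointes/QT prolongation` = 269),
    smq_of_other_anticancer_cases = c(
      `cardiac arrhythmias` = 1982, `cardiac failure` = 8402,
      cardiomyopathy = 3238, `embolic and thrombotic events` = 27911,
      hypertension = 8236, `ischaemic heart disease` = 8833,
      `pulmonary hypertension` = 854,
      `torsade de pointes/QT prolongation` = 846)
  )
}
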