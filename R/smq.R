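#' The eight cardiovascular SMQs of the screen
#'
#' @return character vector of query names.
#' @export
cv_smq_names <- function() {
  c("cardiac failure", "cardiomyopathy", "hypertension",
    "pulmonary hypertension", "ischaemic heart disease",
    "torsade de pointes/QT prolongation", "cardiac arrhythmias",
    "embolic and thrombotic events")
}

#' Construct an SMQ catalogue from a data frame
#'
#' An SMQ catalogue is a term list: one row per (query, preferred term) with
#' a scope flag. Narrow terms are the specific subset; broad adds the
#' sensitive ones. Real MedDRA content is licensed and therefore always
#' user-supplied; the package ships none.
#'
#' @param terms data frame with columns `smq_name`, `preferred_term`,
#'   `scope` (`"narrow"` or `"broad"`).
#' @param required character vector of query names that must be present
#'   (`NULL` to skip the check).
#' @return tibble of class `smq_catalogue` with an added normalized-term
#'   column.
#' @export
smq_catalogue <- function(terms, required = NULL) {
  stopifnot(all(c("smq_name", "preferred_term", "scope") %in% colnames(terms)))
  bad_scope <- setdiff(unique(terms$scope), c("narrow", "broad"))
  assert_that(length(bad_scope) == 0,
              paste0("invalid scope value(s): ", paste(bad_scope, collapse = ", ")))
  cat <- tibble::as_tibble(terms) |>
    dplyr::mutate(term_norm = norm_term(.data$preferred_term)) |>
    dplyr::distinct(.data$smq_name, .data$term_norm, .data$scope,
                    .keep_all = TRUE)
  confl <- cat |>
    dplyr::count(.data$smq_name, .data$term_norm) |>
    dplyr::filter(.data$n > 1)
  assert_that(nrow(confl) == 0,
              paste0("term(s) listed with conflicting scope: ",
                     paste(paste(confl$smq_name, confl$term_norm, sep = ": "),
                           collapse = "; ")))
  if (!is.null(required)) {
    miss <- setdiff(required, unique(cat$smq_name))
    assert_that(length(miss) == 0,
                paste0("SMQ(s) missing from catalogue: ",
                       paste(miss, collapse = ", ")))
  }
  class(cat) <- c("smq_catalogue", class(cat))
  cat
}

#' Load an SMQ catalogue from a delimited file
#'
#' @param path delimited file with columns `smq_name`, `preferred_term`,
#'   `scope`.
#' @param delim field delimiter.
#' @param required queries that must be present; defaults to the eight
#'   cardiovascular SMQs of the screen.
#' @return an [smq_catalogue()].
#' @export
load_smq_catalogue <- function(path, delim = ",", required = cv_smq_names()) {
  terms <- readr::read_delim(path, delim = delim, show_col_types = FALSE,
                             progress = FALSE)
  smq_catalogue(terms, required = required)
}

smq_terms <- function(catalogue, smq, scope = c("narrow", "broad")) {
  scope <- match.arg(scope)
  rows <- catalogue[catalogue$smq_name == smq, , drop = FALSE]
  assert_that(nrow(rows) > 0, paste0("unknown SMQ: ", smq))
  if (scope == "narrow") rows <- rows[rows$scope == "narrow", , drop = FALSE]
  unique(rows$term_norm)
}

#' Classify reports as case or non-case per SMQ
#'
#' A report is a case for a query when at least one of its events matches a
#' term of the query at the requested scope (the screen uses narrow scope).
#' Every retained report that does not match is a non-case for that query —
#' including reports matching *other* queries, per the case/non-case design.
#' Term matching is exact after case-folding and whitespace collapse.
#'
#' @param store a `faers_reports` (normally the retained set after
#'   [preprocess_reports()]).
#' @param catalogue an [smq_catalogue()].
#' @param scope `"narrow"` (default) or `"broad"`.
#' @param smqs queries to classify against; defaults to all in the
#'   catalogue.
#' @return tibble with columns `report_id`, `smq_name`, `is_case`; one row
#'   per report x query (a full partition: cases + non-cases = reports).
#' @export
classify_cases <- function(store, catalogue, scope = "narrow",
                           smqs = unique(catalogue$smq_name)) {
  stopifnot(inherits(store, "faers_reports"))
  ids <- store$reports$report_id
  out <- lapply(smqs, function(s) {
    terms <- smq_terms(catalogue, s, scope)
    hit <- unique(store$events$report_id[store$events$term_norm %in% terms])
    tibble::tibble(report_id = ids, smq_name = s, is_case = ids %in% hit)
  })
  dplyr::bind_rows(out)
}
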