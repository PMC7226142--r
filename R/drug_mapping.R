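#' The study tyrosine-kinase inhibitors
#'
#' The five BCR-ABL inhibitors with a European marketing authorization for
#' chronic myeloid leukemia; the index drugs of the screen.
#'
#' @return character vector of INNs.
#' @export
tki_drugs <- function() {
  c("imatinib", "dasatinib", "bosutinib", "nilotinib", "ponatinib")
}

#' Build a drug-name archive
#'
#' The archive maps normalized brand/generic name tokens to INN, and INNs to
#' ATC codes. Every INN present in the ATC index is automatically a key of
#' the name map, so normalization is idempotent on already-normalized
#' substance names.
#'
#' @param names data frame with columns `name`, `inn` (brand or generic name
#'   per row).
#' @param atc data frame with columns `inn`, `atc` (one ATC code per row;
#'   an INN may carry several).
#' @return object of class `drug_archive`.
#' @export
drug_archive <- function(names, atc) {
  stopifnot(all(c("name", "inn") %in% colnames(names)),
            all(c("inn", "atc") %in% colnames(atc)))
  nm <- tibble::tibble(key = norm_token(names$name), inn = tolower(names$inn))
  self <- tibble::tibble(key = norm_token(unique(c(names$inn, atc$inn))),
                         inn = tolower(unique(c(names$inn, atc$inn))))
  # identical rows collapse; the same key pointing at two INNs is an error
  nm <- dplyr::distinct(dplyr::bind_rows(nm, self))
  conflict <- unique(nm$key[duplicated(nm$key)])
  assert_that(length(conflict) == 0,
              paste0("conflicting archive entries for: ",
                     paste(conflict, collapse = ", ")))
  atc_index <- split(toupper(atc$atc), tolower(atc$inn))
  structure(list(entries = setNames(nm$inn, nm$key),
                 atc_index = atc_index),
            class = "drug_archive")
}

#' Read a drug-name archive from delimited files
#'
#' @param names_path delimited file with columns `name`, `inn`.
#' @param atc_path delimited file with columns `inn`, `atc`.
#' @param delim field delimiter.
#' @return a [drug_archive()].
#' @export
read_drug_archive <- function(names_path, atc_path, delim = ",") {
  nm <- readr::read_delim(names_path, delim = delim, show_col_types = FALSE,
                          progress = FALSE)
  atc <- readr::read_delim(atc_path, delim = delim, show_col_types = FALSE,
                           progress = FALSE)
  drug_archive(nm, atc)
}

#' @export
print.drug_archive <- function(x, ...) {
  cat("<drug_archive>", length(x$entries), "name entries,",
      length(x$atc_index), "INNs with ATC codes\n")
  invisible(x)
}

# suffix tokens stripped when an exact lookup fails: doses and formulations
dose_pattern <- "^[0-9]+(\\.[0-9]+)?(mg|mcg|ug|g|ml|iu|%)?$|^(mg|mcg|ug|g|ml|iu)$"
formulation_words <- c(
  "tablet", "tablets", "tab", "capsule", "capsules", "cap", "injection",
  "solution", "oral", "film", "coated", "hcl", "hydrochloride", "sodium",
  "extended", "release", "er", "xr", "sr", "cream", "patch", "syrup"
)

strip_dose <- function(tok) {
  parts <- strsplit(tok, " ", fixed = TRUE)[[1]]
  keep <- !(grepl(dose_pattern, parts) | parts %in% formulation_words)
  paste(parts[keep], collapse = " ")
}

normalize_one <- function(tok, archive, fuzzy) {
  if (tok == "") return(NA_character_)
  hit <- archive$entries[tok]
  if (!is.na(hit)) return(unname(hit))
  stripped <- strip_dose(tok)
  if (stripped != tok && stripped != "") {
    hit <- archive$entries[stripped]
    if (!is.na(hit)) return(unname(hit))
    tok <- stripped
  }
  if (fuzzy && nchar(tok) >= 6) {
    d <- utils::adist(tok, names(archive$entries))
    cand <- unique(unname(archive$entries[d == 1L]))
    if (length(cand) == 1L) return(cand)
  }
  NA_character_
}

#' Normalize a free-text drug name to INN
#'
#' Resolution proceeds in three stages: exact match on the normalized token;
#' match after stripping dose/formulation suffixes; and, when `fuzzy = TRUE`,
#' a rescue match at edit distance exactly 1, applied only to tokens of at
#' least 6 characters and only when it identifies a unique INN. Combination
#' products are split on `+` or `;` and each component is resolved on its
#' own. Unresolvable components return `NA`.
#'
#' @param verbatim one free-text drug name.
#' @param archive a [drug_archive()].
#' @param fuzzy enable the bounded edit-distance rescue (off by default; it
#'   risks false merges on terse vocabularies).
#' @return character vector of INNs, one per component (`NA` for unresolved
#'   components).
#' @export
normalize_name <- function(verbatim, archive, fuzzy = FALSE) {
  stopifnot(inherits(archive, "drug_archive"), length(verbatim) == 1L)
  tok <- norm_token(verbatim)
  comps <- trimws(strsplit(tok, "[+;/]")[[1]])
  comps <- gsub("\\s+", " ", comps)
  if (length(comps) == 0) return(NA_character_)
  vapply(comps, normalize_one, character(1), archive = archive, fuzzy = fuzzy,
         USE.NAMES = FALSE)
}

#' Resolve all drug lines of a report store
#'
#' Adds `inn` (list column of resolved component INNs) and `resolved` (any
#' component resolved) to the `drugs` table. Resolution is memoised over the
#' distinct verbatim names.
#'
#' @param store a `faers_reports` object.
#' @inheritParams normalize_name
#' @return the store, with an augmented `drugs` table.
#' @export
resolve_drugs <- function(store, archive, fuzzy = FALSE) {
  stopifnot(inherits(store, "faers_reports"))
  key <- ifelse(is.na(store$drugs$verbatim_name), "", store$drugs$verbatim_name)
  uniq <- unique(key)
  res <- lapply(uniq, normalize_name, archive = archive, fuzzy = fuzzy)
  names(res) <- uniq
  store$drugs$inn <- res[key]
  store$drugs$resolved <- vapply(store$drugs$inn,
                                 function(v) any(!is.na(v)), logical(1))
  store
}

#' Name-mapping coverage
#'
#' Fraction of drug lines with at least one resolved component, plus the
#' most frequent unresolved verbatim names for manual curation.
#'
#' @param store a `faers_reports` whose drugs table went through
#'   [resolve_drugs()].
#' @param n_top how many unresolved tokens to list.
#' @return list with `coverage` (fraction in \[0,1\], `NA` if there are no
#'   drug lines) and `unresolved` (tibble of verbatim name, count).
#' @export
mapping_coverage <- function(store, n_top = 20) {
  d <- store$drugs
  assert_that(!is.null(d$resolved), "run resolve_drugs() first")
  if (nrow(d) == 0) {
    return(list(coverage = NA_real_,
                unresolved = tibble::tibble(verbatim_name = character(),
                                            n = integer())))
  }
  unres <- d |>
    dplyr::filter(!.data$resolved) |>
    dplyr::count(.data$verbatim_name, sort = TRUE, name = "n") |>
    head(n_top)
  list(coverage = mean(d$resolved), unresolved = unres)
}

#' Flag anticancer and study-TKI exposure per report
#'
#' A report is anticancer-exposed when any resolved drug component, in any
#' role (suspect, concomitant or interacting), carries an ATC code starting
#' with `L01`; its TKI set lists which of the five study drugs appear.
#'
#' @param store a resolved `faers_reports`.
#' @param archive the [drug_archive()] used for resolution (for the ATC
#'   index).
#' @return tibble with one row per report: `report_id`, `is_anticancer`,
#'   `tki_set` (list of INNs), `n_tki`.
#' @export
flag_exposures <- function(store, archive) {
  stopifnot(inherits(store, "faers_reports"), inherits(archive, "drug_archive"))
  assert_that(!is.null(store$drugs$inn), "run resolve_drugs() first")
  anticancer_inns <- names(archive$atc_index)[vapply(archive$atc_index,
    function(a) any(startsWith(a, "L01")), logical(1))]
  long <- data.table::data.table(
    report_id = rep(store$drugs$report_id, lengths(store$drugs$inn)),
    inn = unlist(store$drugs$inn, use.names = FALSE))
  long <- long[!is.na(long$inn), ]
  long[, ac := as.integer(inn %in% anticancer_inns)]
  agg <- long[, list(n_ac = sum(ac)), by = "report_id"]
  ac_ids <- agg$report_id[agg$n_ac > 0L]
  tkl <- long[long$inn %in% tki_drugs(), ]
  tsets <- lapply(split(tkl$inn, tkl$report_id), function(v) sort(unique(v)))
  out <- tibble::tibble(report_id = store$reports$report_id)
  out$is_anticancer <- out$report_id %in% ac_ids
  ix <- match(out$report_id, names(tsets))
  out$tki_set <- lapply(ix, function(j)
    if (is.na(j)) character(0) else tsets[[j]])
  out$n_tki <- lengths(out$tki_set)
  out
}
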