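#' @importFrom rlang .data %||%
#' @import dplyr
#' @importFrom data.table as.data.table data.table setorder :=
#' @importFrom stats glm binomial coef vcov quantile qlogis plogis rbinom runif rexp setNames
#' @importFrom utils adist head
NULL

# let data.table find its methods when the package is imported
.datatable.aware <- TRUE

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention used in clinical
#' tables), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return numeric vector rounded to `digits` places.
#' @export
round_half_up <- function(x, digits = 1) {
  m <- 10^digits
  # nudge by an ulp-scale epsilon so that values printed as .x5 round up
  # despite binary representation sitting a hair below the tie
  floor(x * m + 0.5 + sqrt(.Machine$double.eps)) / m
}

# lowercase, punctuation to space, collapse whitespace
norm_token <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- tolower(x)
  x <- gsub("[^a-z0-9+;/]+", " ", x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# normalization used for MedDRA-style preferred terms: case-fold and
# collapse whitespace, nothing else (PT coding is exact)
norm_term <- function(x) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- tolower(x)
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

assert_that <- function(ok, msg) {
  if (!isTRUE(ok)) stop(msg, call. = FALSE)
  invisible(TRUE)
}
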