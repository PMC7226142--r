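#' Parse possibly-partial FAERS date strings
#'
#' FAERS records calendar dates as bare digit strings: `YYYY`, `YYYYMM`, or
#' `YYYYMMDD`. Fields may be empty. This parser keeps an explicit precision
#' marker rather than silently promoting partial dates to full ones; partial
#' dates are anchored at the first day of their period so they remain
#' comparable, and the precision column says how much of the anchor is real.
#'
#' @param x character vector of raw date strings (digits or empty).
#' @param quiet suppress the warning emitted for unparseable values.
#' @return a tibble with one row per input and columns `date` ([base::Date],
#'   `NA` when missing) and `precision` (one of `"day"`, `"month"`,
#'   `"year"`, `"missing"`).
#' @examples
#' parse_partial_date(c("20180415", "201804", "2018", "", "20181341"))
#' @export
parse_partial_date <- function(x, quiet = FALSE) {
  x <- as.character(x)
  x[is.na(x)] <- ""
  x <- trimws(x)
  n <- length(x)
  out_date <- rep(as.Date(NA), n)
  out_prec <- rep("missing", n)
  nc <- nchar(x)
  digits <- grepl("^[0-9]*$", x)
  bad <- (!digits & nc > 0) | (digits & !(nc %in% c(0L, 4L, 6L, 8L)))

  full <- which(digits & nc == 8L)
  if (length(full)) {
    d <- as.Date(x[full], format = "%Y%m%d")
    # as.Date with a format is lenient about some impossible days; re-format
    # to verify round-trip
    ok <- !is.na(d) & format(d, "%Y%m%d") == x[full]
    out_date[full[ok]] <- d[ok]
    out_prec[full[ok]] <- "day"
    bad[full[!ok]] <- TRUE
  }
  ym <- which(digits & nc == 6L)
  if (length(ym)) {
    mo <- as.integer(substr(x[ym], 5, 6))
    ok <- !is.na(mo) & mo >= 1L & mo <= 12L
    out_date[ym[ok]] <- as.Date(paste0(x[ym[ok]], "01"), format = "%Y%m%d")
    out_prec[ym[ok]] <- "month"
    bad[ym[!ok]] <- TRUE
  }
  yy <- which(digits & nc == 4L)
  if (length(yy)) {
    out_date[yy] <- as.Date(paste0(x[yy], "0101"), format = "%Y%m%d")
    out_prec[yy] <- "year"
  }
  if (any(bad) && !quiet) {
    warning(sum(bad), " date value(s) could not be parsed and were set to missing",
            call. = FALSE)
  }
  tibble::tibble(date = out_date, precision = out_prec)
}

# render a (date, precision) pair back to the FAERS digit-string dialect
format_partial_date <- function(date, precision) {
  out <- character(length(date))
  out[precision == "day"] <- format(date[precision == "day"], "%Y%m%d")
  out[precision == "month"] <- format(date[precision == "month"], "%Y%m")
  out[precision == "year"] <- format(date[precision == "year"], "%Y")
  out[precision == "missing" | is.na(date)] <- ""
  out
}
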