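#' Build the 2x2 contingency table for one drug--SMQ pair
#'
#' Over the anticancer report set, index-exposed reports are those whose TKI
#' set contains the index drug (`"tki_class"` means any of the five study
#' drugs); all remaining anticancer reports form the comparator, so for a
#' single drug the comparator may contain the other TKIs, while the class
#' analysis compares against anticancer reports with none of them. `a` and
#' `b` are exposed cases and non-cases, `c` and `d` comparator cases and
#' non-cases.
#'
#' @param labels output of [classify_cases()] for one query (rows for other
#'   queries are ignored once `smq` is given).
#' @param exposures output of [flag_exposures()].
#' @param smq query name.
#' @param index_drug one of [tki_drugs()] or `"tki_class"`.
#' @return object of class `contingency_table` with fields `a,b,c,d`,
#'   `drug`, `smq_name`.
#' @export
build_table <- function(labels, exposures, smq, index_drug) {
  lab <- labels[labels$smq_name == smq, , drop = FALSE]
  assert_that(nrow(lab) > 0, paste0("no labels for SMQ: ", smq))
  df <- dplyr::inner_join(lab, exposures, by = "report_id") |>
    dplyr::filter(.data$is_anticancer)
  exposed <- if (identical(index_drug, "tki_class")) df$n_tki > 0 else
    vapply(df$tki_set, function(s) index_drug %in% s, logical(1))
  a <- sum(exposed & df$is_case)
  b <- sum(exposed & !df$is_case)
  c_ <- sum(!exposed & df$is_case)
  d <- sum(!exposed & !df$is_case)
  assert_that(c_ + d > 0,
              "empty comparator set: no anticancer reports without the index drug")
  structure(list(a = a, b = b, c = c_, d = d,
                 drug = index_drug, smq_name = smq),
            class = "contingency_table")
}

#' @export
print.contingency_table <- function(x, ...) {
  cat(sprintf("<contingency_table> %s / %s\n", x$drug, x$smq_name))
  print(matrix(c(x$a, x$b, x$c, x$d), 2, byrow = TRUE,
               dimnames = list(c("index", "comparator"), c("case", "non-case"))))
  invisible(x)
}

#' Crude reporting odds ratio with Woolf confidence interval
#'
#' `ROR = (a d)/(b c)`; the 95% interval is
#' `exp(log ROR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d))`. No continuity
#' correction is applied: a zero in `b`, `c` or `d` yields a not-computed
#' result with a reason, and the screen's eligibility rule (at least 3
#' exposed cases) handles sparsity in `a`.
#'
#' @param table a [build_table()] result, or a list/vector with `a,b,c,d`.
#' @param conf_z normal quantile for the interval half-width (1.96 for the
#'   conventional 95% interval).
#' @return tibble with `ror`, `ci_low`, `ci_high`, `n_cases` (= `a`),
#'   `eligible` (`a >= 3`), `status` (`"ok"` or the reason the estimate was
#'   not computed).
#' @export
crude_ror <- function(table, conf_z = 1.96) {
  a <- table$a; b <- table$b; c_ <- table$c; d <- table$d
  stopifnot(all(c(a, b, c_, d) >= 0))
  eligible <- a >= 3
  if (min(b, c_, d) == 0) {
    return(tibble::tibble(ror = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                          n_cases = a, eligible = eligible,
                          status = "not computed: zero cell in b, c, or d"))
  }
  if (a == 0) {
    return(tibble::tibble(ror = 0, ci_low = NA_real_, ci_high = NA_real_,
                          n_cases = a, eligible = FALSE,
                          status = "not computed: no exposed cases"))
  }
  ror <- (a * d) / (b * c_)
  se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
  tibble::tibble(ror = ror,
                 ci_low = exp(log(ror) - conf_z * se),
                 ci_high = exp(log(ror) + conf_z * se),
                 n_cases = a, eligible = eligible, status = "ok")
}

# analysis frame for one (smq, index drug): anticancer reports with case
# indicator, exposure indicator and adjustment covariates
dispro_frame <- function(store, labels, exposures, smq, index_drug) {
  lab <- labels[labels$smq_name == smq, , drop = FALSE]
  df <- dplyr::inner_join(lab, exposures, by = "report_id") |>
    dplyr::filter(.data$is_anticancer) |>
    dplyr::inner_join(dplyr::select(store$reports, "report_id", "age_class",
                                    "sex"),
                      by = "report_id")
  df$exposed <- if (identical(index_drug, "tki_class")) df$n_tki > 0 else
    vapply(df$tki_set, function(s) index_drug %in% s, logical(1))
  df
}

#' Age- and sex-adjusted reporting odds ratio
#'
#' Fits `case ~ exposure + age_class + sex` by maximum-likelihood logistic
#' regression over the anticancer report set (index-exposed plus
#' comparator); the adjusted ROR is the exponentiated exposure coefficient
#' with a Wald 95% interval. Age class and sex enter as categorical
#' covariates with explicit `"unknown"` levels, so reports with missing
#' demographics stay in the model.
#'
#' @inheritParams build_table
#' @param store the `faers_reports` the labels were computed from (supplies
#'   the covariates).
#' @param conf_z normal quantile for the interval half-width.
#' @return tibble with `adj_ror`, `adj_ci_low`, `adj_ci_high`,
#'   `n_cases` (exposed cases), `status` (`"ok"`, or a diagnostic when the
#'   estimate is not computed: fewer than 3 exposed cases, non-convergence,
#'   or separation).
#' @export
adjusted_ror <- function(store, labels, exposures, smq, index_drug,
                         conf_z = 1.96) {
  df <- dispro_frame(store, labels, exposures, smq, index_drug)
  a <- sum(df$exposed & df$is_case)
  not_computed <- function(status) {
    tibble::tibble(adj_ror = NA_real_, adj_ci_low = NA_real_,
                   adj_ci_high = NA_real_, n_cases = a, status = status)
  }
  if (a < 3) return(not_computed("not computed: fewer than 3 exposed cases"))
  # collapse to covariate strata: the binomial-counts fit has the same
  # likelihood (and therefore identical MLE and Wald interval) as the
  # report-level Bernoulli fit, at a fraction of the cost
  tab <- table(df$exposed, factor(df$age_class, levels = age_levels()),
               df$sex, df$is_case)
  cnt <- as.data.frame(tab, stringsAsFactors = FALSE)
  names(cnt) <- c("exposed", "age_class", "sex", "is_case", "n")
  y1 <- cnt$n[cnt$is_case == "TRUE"]
  y0 <- cnt$n[cnt$is_case == "FALSE"]
  strata <- cnt[cnt$is_case == "TRUE", c("exposed", "age_class", "sex")]
  keep <- (y1 + y0) > 0
  mdf <- data.frame(y1 = y1[keep], y0 = y0[keep],
                    exposed = strata$exposed[keep] == "TRUE",
                    age_class = droplevels(factor(strata$age_class[keep],
                                                  levels = age_levels())),
                    sex = factor(strata$sex[keep]))
  # extreme fitted probabilities in sparse covariate cells are expected and
  # handled by the separation check below; keep the fit quiet
  fit <- try(withCallingHandlers(
    stats::glm(cbind(y1, y0) ~ exposed + age_class + sex,
               family = stats::binomial(), data = mdf),
    warning = function(w) {
      if (grepl("fitted probabilities numerically", conditionMessage(w)))
        invokeRestart("muffleWarning")
    }), silent = TRUE)
  if (inherits(fit, "try-error")) {
    return(not_computed(paste("not computed: model failure -",
                              attr(fit, "condition")$message)))
  }
  if (!isTRUE(fit$converged)) return(not_computed("not computed: non-convergence"))
  co <- stats::coef(fit)
  if (anyNA(co)) return(not_computed("not computed: rank-deficient design"))
  est <- co[["exposedTRUE"]]
  se <- sqrt(diag(stats::vcov(fit))[["exposedTRUE"]])
  if (!is.finite(est) || !is.finite(se) || abs(est) > 15 || se > 15) {
    return(not_computed("not computed: separation suspected"))
  }
  tibble::tibble(adj_ror = exp(est),
                 adj_ci_low = exp(est - conf_z * se),
                 adj_ci_high = exp(est + conf_z * se),
                 n_cases = a, status = "ok")
}

#' Screen all drug--SMQ pairs
#'
#' Runs the full disproportionality screen: for every query and every index
#' drug (the five TKIs plus the TKI class), builds the contingency table,
#' applies the eligibility rule (at least 3 exposed cases), and computes
#' crude and adjusted RORs. A pair is a signal of disproportionate
#' reporting (SDR) when it is eligible and the adjusted interval's lower
#' bound exceeds 1. Ineligible pairs are not given estimates; they are
#' listed separately with their case counts.
#'
#' @inheritParams adjusted_ror
#' @param catalogue an [smq_catalogue()].
#' @param drugs index drugs; default the five study TKIs.
#' @param include_class also screen the pooled TKI class.
#' @param scope SMQ scope for the labels.
#' @param labels optional precomputed [classify_cases()] output; computed
#'   from `store` when `NULL`.
#' @return list of class `dispro_screen` with `results` (one row per
#'   eligible pair: counts, crude and adjusted ROR with intervals, `sdr`)
#'   and `ineligible` (pairs with fewer than 3 exposed cases).
#' @export
screen_all <- function(store, exposures, catalogue, drugs = tki_drugs(),
                       include_class = TRUE, scope = "narrow", labels = NULL) {
  if (is.null(labels)) labels <- classify_cases(store, catalogue, scope = scope)
  smqs <- unique(labels$smq_name)
  index <- c(drugs, if (include_class) "tki_class")
  res <- list(); inel <- list()
  for (s in smqs) {
    for (d in index) {
      tab <- build_table(labels, exposures, s, d)
      if (tab$a < 3) {
        inel[[length(inel) + 1L]] <- tibble::tibble(drug = d, smq_name = s,
                                                    n_cases = tab$a)
        next
      }
      cr <- crude_ror(tab)
      ad <- adjusted_ror(store, labels, exposures, s, d)
      res[[length(res) + 1L]] <- tibble::tibble(
        drug = d, smq_name = s,
        a = tab$a, b = tab$b, c = tab$c, d = tab$d,
        crude_ror = cr$ror, crude_ci_low = cr$ci_low,
        crude_ci_high = cr$ci_high,
        adj_ror = ad$adj_ror, adj_ci_low = ad$adj_ci_low,
        adj_ci_high = ad$adj_ci_high,
        eligible = TRUE,
        sdr = !is.na(ad$adj_ci_low) & ad$adj_ci_low > 1,
        status = ad$status)
    }
  }
  structure(list(results = dplyr::bind_rows(res),
                 ineligible = dplyr::bind_rows(inel)),
            class = "dispro_screen")
}

#' @export
print.dispro_screen <- function(x, ...) {
  cat("<dispro_screen>", nrow(x$results), "eligible pairs,",
      nrow(x$ineligible), "ineligible;",
      sum(x$results$sdr), "SDR\n")
  invisible(x)
}
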