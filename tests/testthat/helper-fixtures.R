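# fixtures are built in code; nothing binary ships with the package

# minimal report store with sensible defaults, for unit tests that do not
# need the raw-table round trip
fake_reports <- function(n, report_id = sprintf("R%03d", seq_len(n)), ...) {
  defaults <- tibble::tibble(
    report_id = report_id,
    case_id = paste0("C", report_id),
    version_seq = 1L,
    age_years = 60,
    age_class = age_class_of(rep(60, n)),
    sex = "female",
    reporter_type = "health professional",
    country = "US",
    reporting_year = 2015L,
    serious = TRUE,
    outcomes = replicate(n, "hospitalization", simplify = FALSE))
  over <- list(...)
  for (nm in names(over)) defaults[[nm]] <- over[[nm]]
  defaults$age_class <- age_class_of(defaults$age_years)
  defaults
}

empty_drugs <- function() {
  tibble::tibble(report_id = character(), drug_seq = character(),
                 verbatim_name = character(), role = character(),
                 start_date = as.Date(character()),
                 start_precision = character(),
                 end_date = as.Date(character()),
                 end_precision = character())
}

empty_events <- function() {
  tibble::tibble(report_id = character(), preferred_term = character(),
                 term_norm = character(), onset_date = as.Date(character()),
                 onset_precision = character())
}

fake_drugs <- function(report_id, verbatim_name, role = "primary suspect",
                       start_date = as.Date(NA), start_precision = "missing") {
  n <- length(report_id)
  tibble::tibble(report_id = report_id,
                 drug_seq = as.character(seq_len(n)),
                 verbatim_name = verbatim_name,
                 role = rep_len(role, n),
                 start_date = rep_len(start_date, n),
                 start_precision = rep_len(start_precision, n),
                 end_date = as.Date(NA), end_precision = "missing")
}

fake_events <- function(report_id, preferred_term,
                        onset_date = as.Date(NA), onset_precision = "missing") {
  tibble::tibble(report_id = report_id,
                 preferred_term = preferred_term,
                 term_norm = tolower(trimws(gsub("\\s+", " ", preferred_term))),
                 onset_date = rep_len(onset_date, length(report_id)),
                 onset_precision = rep_len(onset_precision, length(report_id)))
}

fake_store <- function(reports, drugs = empty_drugs(), events = empty_events()) {
  structure(list(reports = reports, drugs = drugs, events = events,
                 log = NULL),
            class = "faers_reports")
}

# small archive: the five TKIs with brands plus decoys, mirroring the
# generator's menus
test_archive <- function() {
  archive_from_config(scenario_config(n_reports = 10))
}

# exposures table built by hand
fake_exposures <- function(report_id, tki = vector("list", length(report_id)),
                           is_anticancer = TRUE) {
  tki <- lapply(tki, function(v) if (is.null(v)) character(0) else v)
  tibble::tibble(report_id = report_id,
                 is_anticancer = rep_len(is_anticancer, length(report_id)),
                 tki_set = tki, n_tki = lengths(tki))
}

# independent 2x2 odds-ratio oracle: maximum-likelihood logistic fit on the
# aggregated table; agrees with the closed form only because both are the
# MLE of the same saturated model
oracle_or <- function(a, b, c, d, conf_z = 1.96) {
  df <- data.frame(exposed = c(TRUE, TRUE, FALSE, FALSE),
                   case = c(TRUE, FALSE, TRUE, FALSE),
                   n = c(a, b, c, d))
  fit <- stats::glm(case ~ exposed, weights = n, family = stats::binomial(),
                    data = df,
                    control = stats::glm.control(epsilon = 1e-14, maxit = 100))
  est <- stats::coef(fit)[["exposedTRUE"]]
  se <- sqrt(diag(stats::vcov(fit))[["exposedTRUE"]])
  c(ror = exp(est), lo = exp(est - conf_z * se), hi = exp(est + conf_z * se))
}

run_pipeline <- function(g, cfg, fuzzy = TRUE) {
  arch <- archive_from_config(cfg)
  st <- resolve_drugs(assemble_reports(g$tables), arch, fuzzy = fuzzy)
  pp <- preprocess_reports(st)
  list(store = pp$store, funnel = pp$funnel,
       exposures = flag_exposures(pp$store, arch),
       labels = classify_cases(pp$store, smq_catalogue(cfg$smq_menu)),
       archive = arch)
}
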