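#' Default synthetic drug menu
#'
#' The five study TKIs plus a dozen comparator anticancer substances, each
#' with one trade name and an ATC code, and the marginal probability that a
#' report's primary suspect drug is this substance. All menu drugs are
#' antineoplastic (L01), mirroring the anticancer subset the case/non-case
#' design operates on.
#'
#' @param tki_share total probability mass on the five TKIs (split equally
#'   unless reweighted downstream).
#' @return tibble with columns `inn`, `brand`, `atc`, `share`, `is_tki`.
#' @export
default_drug_menu <- function(tki_share = 0.2) {
  tki <- tibble::tribble(
    ~inn, ~brand, ~atc,
    "imatinib", "gleevec", "L01EA01",
    "dasatinib", "sprycel", "L01EA02",
    "nilotinib", "tasigna", "L01EA03",
    "bosutinib", "bosulif", "L01EA04",
    "ponatinib", "iclusig", "L01EA05")
  comp <- tibble::tribble(
    ~inn, ~brand, ~atc,
    "paclitaxel", "onataxel", "L01CD01",
    "docetaxel", "ribodocel", "L01CD02",
    "carboplatin", "paraplatol", "L01XA02",
    "oxaliplatin", "eloxatin", "L01XA03",
    "gemcitabine", "gemzaris", "L01BC05",
    "capecitabine", "xelodarin", "L01BC06",
    "rituximab", "mabthera", "L01FA01",
    "trastuzumab", "herceptin", "L01FD01",
    "bevacizumab", "avastin", "L01FG01",
    "pemetrexed", "alimteron", "L01BA04",
    "doxorubicin", "adriblastin", "L01DB01",
    "cyclophosphamide", "endoxan", "L01AA01")
  tki$share <- tki_share / nrow(tki)
  comp$share <- (1 - tki_share) / nrow(comp)
  tki$is_tki <- TRUE
  comp$is_tki <- FALSE
  dplyr::bind_rows(tki, comp)
}

# non-anticancer drugs that appear as concomitant medication lines
default_concomitant_menu <- function() {
  tibble::tribble(
    ~inn, ~brand, ~atc,
    "metformin", "glucophage", "A10BA02",
    "lisinopril", "zestril", "C09AA03",
    "omeprazole", "prilosec", "A02BC01",
    "atorvastatin", "lipitor", "C10AA05",
    "furosemide", "lasilix", "C03CA01",
    "levothyroxine", "synthroid", "H03AA01",
    "warfarin", "coumadin", "B01AA03",
    "allopurinol", "zyloric", "M04AA01")
}

#' Default fictional SMQ term menu
#'
#' Five fictional MedDRA-like preferred terms (three narrow, two broad) per
#' cardiovascular query. No real MedDRA content is distributed; results are
#' term-list-parametric, so real narrow-scope SMQ lists can be substituted
#' at run time.
#'
#' @return tibble with columns `smq_name`, `preferred_term`, `scope`.
#' @export
default_smq_menu <- function() {
  stems <- c(
    "cardiac failure" = "myocordial insufficiency",
    "cardiomyopathy" = "myocordial dystrophia",
    "hypertension" = "pressoric elevation",
    "pulmonary hypertension" = "pulmonic pressoric elevation",
    "ischaemic heart disease" = "coronaric ischemia",
    "torsade de pointes/QT prolongation" = "ventricular torsion rhythm",
    "cardiac arrhythmias" = "rhythmic disturbance",
    "embolic and thrombotic events" = "vascular occlusion event")
  narrow <- c("type i", "type ii", "type iii")
  broad <- c("suspected", "aggravated")
  purrr::map_dfr(names(stems), function(s) {
    tibble::tibble(
      smq_name = s,
      preferred_term = paste(stems[[s]], c(narrow, broad)),
      scope = c(rep("narrow", 3), rep("broad", 2)))
  })
}

# baseline per-report probability of being a case of each query, for a
# comparator-drug report with reference covariates
default_smq_baseline <- function() {
  c("cardiac failure" = 0.012,
    "cardiomyopathy" = 0.005,
    "hypertension" = 0.012,
    "pulmonary hypertension" = 0.0015,
    "ischaemic heart disease" = 0.013,
    "torsade de pointes/QT prolongation" = 0.0015,
    "cardiac arrhythmias" = 0.003,
    "embolic and thrombotic events" = 0.04)
}

default_filler_terms <- function() {
  c("nausea simplex", "dermal eruption macular", "cephalic pain recurrent",
    "pyrexia intermittent", "fatigue state chronic", "hepatic enzyme shift",
    "renal clearance reduction", "gastric upset nonspecific",
    "neuropathic tingling distal", "ocular dryness bilateral",
    "arthral stiffness matutinal", "somnolence diurnal")
}

#' Scenario configuration for the synthetic report generator
#'
#' Bundles every knob of the generative model: cohort size, drug and SMQ
#' menus, true conditional odds ratios, confounding coefficients, data-dirt
#' rates (duplicates, follow-ups, aberrant dates, nonserious reports,
#' missing/partial dates, misspellings) and the time-to-onset law. The
#' structural model is: reported age class and sex are drawn from their
#' marginals; exposure (TKI vs comparator suspect drug) follows a logistic
#' model in those covariates; each query's case status follows a logistic
#' model in the same covariates plus `log(true_or)` for the assigned drug.
#' The planted `true_or` is therefore exactly the conditional odds ratio
#' the age/sex-adjusted analysis estimates.
#'
#' @param n_reports number of base reports (clones come on top).
#' @param drug_menu see [default_drug_menu()].
#' @param smq_menu term list, see [default_smq_menu()].
#' @param smq_baseline named baseline case probabilities per query.
#' @param true_or named numeric vector of conditional odds ratios keyed
#'   `"inn|smq_name"`; missing pairs default to 1.
#' @param confounding list of log-odds shifts: `age_exposure`,
#'   `age_outcome` (length 5, ordered as [age_class_of()] levels),
#'   `sex_exposure`, `sex_outcome` (length 3: female, male, unknown).
#' @param nonserious_rate,dup_rate,followup_rate,aberrant_rate probabilities
#'   that a base report is nonserious / spawns a duplicate clone / spawns a
#'   follow-up version / has its therapy start displaced after the event.
#' @param missing_date_rate probability that a date field is degraded (half
#'   of the degraded fields become missing, half month-precision).
#' @param misspell_rate probability a drug name is misspelled by one
#'   character (single deletion or substitution, i.e. edit distance 1).
#' @param brand_rate,dose_suffix_rate,concomitant_rate style knobs for drug
#'   lines.
#' @param age_probs,sex_probs,reporter_probs,country_probs,year_probs,years
#'   demographic marginals.
#' @param tto_law time-to-onset law: `list(dist = "exponential", mean = )`
#'   or `list(dist = "weibull", shape = , scale = )`; may be a named list of
#'   such laws keyed `"inn|smq_name"` with a `default` element.
#' @param window therapy-start window (character dates).
#' @param seed integer seed; identical seed and config give identical
#'   output.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(n_reports = 20000,
                            drug_menu = default_drug_menu(),
                            smq_menu = default_smq_menu(),
                            smq_baseline = default_smq_baseline(),
                            true_or = numeric(0),
                            confounding = list(),
                            nonserious_rate = 0.1,
                            dup_rate = 0.05,
                            followup_rate = 0.05,
                            aberrant_rate = 0.02,
                            missing_date_rate = 0.15,
                            misspell_rate = 0.05,
                            brand_rate = 0.5,
                            dose_suffix_rate = 0.3,
                            concomitant_rate = 0.4,
                            age_probs = c(0.05, 0.12, 0.45, 0.11, 0.27),
                            sex_probs = c(0.44, 0.43, 0.13),
                            reporter_probs = c(0.73, 0.22, 0.05),
                            country_probs = c(US = 0.35, JP = 0.1, DE = 0.07,
                                              FR = 0.07, GB = 0.05,
                                              other = 0.33, unknown = 0.03),
                            years = 2008:2018,
                            year_probs = NULL,
                            tto_law = list(dist = "exponential", mean = 100),
                            window = c("2008-04-01", "2017-06-30"),
                            seed = 1L) {
  cfd <- list(age_exposure = numeric(5), age_outcome = numeric(5),
              sex_exposure = numeric(3), sex_outcome = numeric(3))
  cfd[names(confounding)] <- confounding
  stopifnot(length(cfd$age_exposure) == 5, length(cfd$age_outcome) == 5,
            length(cfd$sex_exposure) == 3, length(cfd$sex_outcome) == 3)
  rates <- c(nonserious_rate, dup_rate, followup_rate, aberrant_rate,
             missing_date_rate, misspell_rate, brand_rate, dose_suffix_rate,
             concomitant_rate)
  assert_that(all(rates >= 0 & rates <= 1), "all rates must lie in [0, 1]")
  assert_that(all(true_or > 0), "true odds ratios must be positive")
  smqs <- unique(smq_menu$smq_name)
  assert_that(all(smqs %in% names(smq_baseline)),
              "every SMQ in the menu needs a baseline probability")
  assert_that(all(smq_baseline > 0 & smq_baseline < 1),
              "baseline probabilities must lie strictly in (0, 1)")
  drug_menu$share <- drug_menu$share / sum(drug_menu$share)
  for (p in list(age_probs, sex_probs, reporter_probs, country_probs)) {
    assert_that(all(p >= 0) && abs(sum(p) - 1) < 1e-6,
                "marginal probability vectors must be nonnegative and sum to 1")
  }
  if (is.null(year_probs)) year_probs <- rep(1 / length(years), length(years))
  structure(list(
    n_reports = as.integer(n_reports), drug_menu = drug_menu,
    concomitant_menu = default_concomitant_menu(),
    smq_menu = smq_menu, smq_baseline = smq_baseline,
    filler_terms = default_filler_terms(),
    true_or = true_or, confounding = cfd,
    nonserious_rate = nonserious_rate, dup_rate = dup_rate,
    followup_rate = followup_rate, aberrant_rate = aberrant_rate,
    missing_date_rate = missing_date_rate, misspell_rate = misspell_rate,
    brand_rate = brand_rate, dose_suffix_rate = dose_suffix_rate,
    concomitant_rate = concomitant_rate,
    age_probs = age_probs, sex_probs = sex_probs,
    reporter_probs = reporter_probs, country_probs = country_probs,
    years = years, year_probs = year_probs / sum(year_probs),
    tto_law = tto_law, window = window, seed = as.integer(seed)),
    class = "scenario_config")
}

#' Drug-name archive implied by a scenario
#'
#' Builds the [drug_archive()] covering every brand and generic name the
#' generator can emit (index and concomitant menus).
#'
#' @param config a [scenario_config()].
#' @return a `drug_archive`.
#' @export
archive_from_config <- function(config) {
  menus <- dplyr::bind_rows(
    config$drug_menu[, c("inn", "brand", "atc")],
    config$concomitant_menu)
  drug_archive(
    names = tibble::tibble(name = c(menus$brand, menus$inn),
                           inn = c(menus$inn, menus$inn)),
    atc = tibble::tibble(inn = menus$inn, atc = menus$atc))
}

or_lookup <- function(config, drug, smq) {
  v <- unname(config$true_or[paste(drug, smq, sep = "|")])
  v[is.na(v)] <- 1
  v
}

draw_tto_law <- function(law, m) {
  if (m == 0) return(numeric(0))
  switch(law$dist,
         exponential = stats::rexp(m, rate = 1 / law$mean),
         weibull = stats::rweibull(m, shape = law$shape, scale = law$scale),
         stop("unknown tto law: ", law$dist))
}

draw_tto <- function(config, drug, smq) {
  law <- config$tto_law
  m <- length(drug)
  if (!is.null(law$dist)) return(draw_tto_law(law, m))
  out <- numeric(m)
  key <- paste(drug, smq, sep = "|")
  for (k in unique(key)) {
    idx <- which(key == k)
    lk <- law[[k]] %||% law$default
    out[idx] <- draw_tto_law(lk, length(idx))
  }
  out
}

# misspell by one-character deletion or substitution: Levenshtein distance
# exactly 1 from the source token
misspell_one <- function(x) {
  ch <- strsplit(x, "")[[1]]
  letters_only <- which(grepl("[a-z]", ch))
  if (length(letters_only) < 2) return(x)
  pos <- sample(letters_only, 1)
  if (stats::runif(1) < 0.5) {
    paste(ch[-pos], collapse = "")
  } else {
    repl <- sample(setdiff(letters, ch[pos]), 1)
    ch[pos] <- repl
    paste(ch, collapse = "")
  }
}

style_drug_names <- function(inn, menu, config) {
  n <- length(inn)
  brand <- menu$brand[match(inn, menu$inn)]
  name <- ifelse(stats::runif(n) < config$brand_rate, brand, inn)
  mis <- stats::runif(n) < config$misspell_rate
  name[mis] <- vapply(name[mis], misspell_one, character(1))
  dose <- stats::runif(n) < config$dose_suffix_rate
  name[dose] <- paste(name[dose],
                      sample(c("100MG", "200MG", "400 MG", "50MG TABLET"),
                             sum(dose), replace = TRUE))
  up <- stats::runif(n) < 0.5
  name[up] <- toupper(name[up])
  name
}

# degrade a vector of full dates: returns precision labels
degrade_precision <- function(m, rate) {
  u <- stats::runif(m)
  ifelse(u < rate / 2, "missing", ifelse(u < rate, "month", "day"))
}

anchor_date <- function(date, precision) {
  out <- date
  out[precision == "missing"] <- NA
  mth <- precision == "month" & !is.na(date)
  out[mth] <- as.Date(format(date[mth], "%Y-%m-01"))
  out
}

#' Generate a FAERS-like table set with known ground truth
#'
#' Draws a cohort of base reports from the scenario's structural model,
#' then injects the data dirt the preprocessing funnel must remove:
#' nonserious reports (no outcome lines), follow-up versions (clones with a
#' higher case version), duplicates (clones under a fresh case identifier),
#' and aberrant reports (therapy start displaced after the event onset).
#' Drug names are emitted as a mix of brand, generic, misspelled and
#' dose-suffixed variants. Base reports are perturbed minimally (onset-day
#' shifts, age jitter within class, filler-term redraws) until their
#' five-field duplicate keys are unique, so that deduplication removes
#' exactly the injected clones.
#'
#' @param config a [scenario_config()].
#' @return list with `tables` (a `raw_table_set`) and `truth` (list:
#'   `report_flags`, `cases`, `exposure`, `counts` per drug/class x query,
#'   `funnel` expected removal counts, `tto` true onset latencies,
#'   `retained_ids`).
#' @export
generate_faers <- function(config) {
  stopifnot(inherits(config, "scenario_config"))
  set.seed(config$seed)
  cf <- config
  n <- cf$n_reports
  smqs <- unique(cf$smq_menu$smq_name)
  narrow_terms <- lapply(setNames(smqs, smqs), function(s)
    cf$smq_menu$preferred_term[cf$smq_menu$smq_name == s &
                                 cf$smq_menu$scope == "narrow"])

  # --- demographics -------------------------------------------------------
  age_class <- sample(age_levels(), n, TRUE, prob = cf$age_probs)
  age_lo <- c("<=25" = 1, "26-50" = 26, "51-75" = 51, ">=76" = 76)
  age_hi <- c("<=25" = 25, "26-50" = 50, "51-75" = 75, ">=76" = 94)
  age_years <- rep(NA_real_, n)
  known_age <- age_class != "unknown"
  age_years[known_age] <- floor(stats::runif(sum(known_age),
                                             age_lo[age_class[known_age]],
                                             age_hi[age_class[known_age]] + 1))
  age_str <- ifelse(is.na(age_years), "", as.character(as.integer(age_years)))
  sexn <- sample(c("female", "male", "unknown"), n, TRUE, prob = cf$sex_probs)
  sex_code <- c(female = "F", male = "M", unknown = "")[sexn]
  reporter <- sample(c("health professional", "nonhealth professional",
                       "unknown"), n, TRUE, prob = cf$reporter_probs)
  occp <- c(`health professional` = "MD",
            `nonhealth professional` = "CN", unknown = "")[reporter]
  country <- sample(names(cf$country_probs), n, TRUE, prob = cf$country_probs)
  country_code <- ifelse(country == "unknown", "", country)
  year <- sample(cf$years, n, TRUE, prob = cf$year_probs)

  age_ix <- match(age_class, age_levels())
  sex_ix <- match(sexn, c("female", "male", "unknown"))

  # --- exposure and case status ------------------------------------------
  menu <- cf$drug_menu
  p_tki <- sum(menu$share[menu$is_tki])
  eta_e <- stats::qlogis(p_tki) + cf$confounding$age_exposure[age_ix] +
    cf$confounding$sex_exposure[sex_ix]
  is_tki <- stats::rbinom(n, 1, stats::plogis(eta_e)) == 1
  tkim <- menu[menu$is_tki, ]; compm <- menu[!menu$is_tki, ]
  drug_inn <- character(n)
  if (any(is_tki))
    drug_inn[is_tki] <- sample(tkim$inn, sum(is_tki), TRUE, prob = tkim$share)
  if (any(!is_tki))
    drug_inn[!is_tki] <- sample(compm$inn, sum(!is_tki), TRUE,
                                prob = compm$share)

  case <- matrix(FALSE, n, length(smqs), dimnames = list(NULL, smqs))
  eta_o0 <- cf$confounding$age_outcome[age_ix] + cf$confounding$sex_outcome[sex_ix]
  for (s in smqs) {
    p <- stats::plogis(stats::qlogis(cf$smq_baseline[[s]]) + eta_o0 +
                         log(or_lookup(cf, drug_inn, s)))
    case[, s] <- stats::rbinom(n, 1, p) == 1
  }
  serious <- stats::rbinom(n, 1, 1 - cf$nonserious_rate) == 1

  # --- dates and events ---------------------------------------------------
  d0 <- as.Date(cf$window[1]); d1 <- as.Date(cf$window[2])
  start_date <- d0 + sample.int(as.integer(d1 - d0) + 1L, n, TRUE) - 1L
  start_prec <- degrade_precision(n, cf$missing_date_rate)

  n_filler <- 1L + stats::rbinom(n, 1, 0.4)
  f_i <- rep(seq_len(n), n_filler)
  filler_ev <- tibble::tibble(
    i = f_i,
    term = sample(cf$filler_terms, length(f_i), TRUE),
    dt = round(stats::rexp(length(f_i), 1 / 120)))
  case_ix <- which(case, arr.ind = TRUE)
  case_ev <- tibble::tibble(i = case_ix[, 1], smq = smqs[case_ix[, 2]])
  case_ev$term <- NA_character_
  for (s in smqs) {
    rows <- which(case_ev$smq == s)
    if (length(rows))
      case_ev$term[rows] <- sample(narrow_terms[[s]], length(rows), TRUE)
  }
  case_ev$dt <- round(draw_tto(cf, drug_inn[case_ev$i], case_ev$smq))
  events <- dplyr::bind_rows(
    filler_ev[, c("i", "term", "dt")],
    case_ev[, c("i", "term", "dt")])
  events$smq <- c(rep(NA_character_, nrow(filler_ev)), case_ev$smq)
  events$onset <- start_date[events$i] + events$dt
  events$prec <- degrade_precision(nrow(events), cf$missing_date_rate)
  events <- events[order(events$i), , drop = FALSE]
  ev_cnt <- tabulate(events$i, nbins = n)
  ev_off <- c(0L, cumsum(ev_cnt))
  rows_of <- function(i) (ev_off[i] + 1L):ev_off[i + 1L]

  # --- enforce uniqueness of the five-field duplicate key -----------------
  # so that deduplication removes exactly the injected clones; colliding
  # base reports are perturbed minimally (onset-day shift, age jitter
  # within class, or a fresh full-precision onset when the report carries
  # no other entropy)
  sentinel <- .Machine$integer.max
  a0 <- anchor_date(events$onset, events$prec)
  ge <- data.table::data.table(
    i = events$i, term = norm_term(events$term),
    anch_num = data.table::fifelse(is.na(a0), sentinel, as.integer(a0)))
  gt <- unique(ge[, c("i", "term")])
  data.table::setorder(gt, i, term)
  gterms <- gt[, list(terms = paste(term, collapse = "|")), by = "i"]
  gons <- ge[, list(m = min(anch_num)), by = "i"]
  terms_key <- onset_key <- rep("", n)
  terms_key[gterms$i] <- gterms$terms
  onset_key[gons$i] <- ifelse(gons$m == sentinel, "NA", as.character(gons$m))
  age_key <- ifelse(age_str == "", "NA", age_str)
  for (iter in 1:200) {
    key <- paste(terms_key, onset_key, age_key, sexn, country, sep = "\r")
    clash <- which(duplicated(key))
    if (length(clash) == 0) break
    if (iter == 200) stop("could not make duplicate keys unique", call. = FALSE)
    for (i in clash) {
      r <- rows_of(i)
      if (any(events$prec[r] != "missing")) {
        events$onset[r] <- events$onset[r] + sample(1:45, 1)
      } else if (!is.na(age_years[i])) {
        cls <- age_class[i]
        v <- stats::runif(1, age_lo[cls], age_hi[cls])
        age_years[i] <- v
        age_str[i] <- sprintf("%.4f", v)
        age_key[i] <- age_str[i]
      } else {
        events$prec[r[1]] <- "day"
        events$onset[r[1]] <- start_date[i] + round(stats::rexp(1, 1 / 120))
      }
      a <- anchor_date(events$onset[r], events$prec[r])
      an <- min(ifelse(is.na(a), sentinel, as.integer(a)))
      onset_key[i] <- if (an == sentinel) "NA" else as.character(an)
    }
  }
  events$dt <- as.integer(events$onset - start_date[events$i])

  # --- injections ---------------------------------------------------------
  elig <- which(serious)
  fu_sel <- elig[stats::runif(length(elig)) < cf$followup_rate]
  rest <- setdiff(elig, fu_sel)
  dup_sel <- rest[stats::runif(length(rest)) < cf$dup_rate]
  rest <- setdiff(rest, dup_sel)
  onset_full <- tapply(
    ifelse(events$prec == "day", as.integer(events$onset), NA_integer_),
    events$i, function(v) if (all(is.na(v))) NA_integer_ else min(v, na.rm = TRUE))
  onset_full_min <- rep(NA_integer_, n)
  onset_full_min[as.integer(names(onset_full))] <- as.integer(onset_full)
  ab_elig <- intersect(rest, which(start_prec == "day" & !is.na(onset_full_min)))
  ab_sel <- ab_elig[stats::runif(length(ab_elig)) < cf$aberrant_rate]
  aberrant <- rep(FALSE, n); aberrant[ab_sel] <- TRUE
  if (length(ab_sel))
    start_date[ab_sel] <- as.Date(onset_full_min[ab_sel],
                                  origin = "1970-01-01") +
      sample(1:30, length(ab_sel), TRUE)

  # --- base tables (strings) ---------------------------------------------
  base_id <- sprintf("R%08d", seq_len(n))
  case_id <- sprintf("C%08d", seq_len(n))
  demo <- tibble::tibble(
    primaryid = base_id, caseid = case_id, caseversion = "1",
    age = age_str, age_cod = ifelse(age_str == "", "", "YR"),
    sex = unname(sex_code), occp_cod = unname(occp),
    reporter_country = country_code, rept_yr = as.character(year))

  index_names <- style_drug_names(drug_inn, menu, cf)
  drug_rows <- tibble::tibble(primaryid = base_id, drug_seq = "1",
                              role_cod = "PS", drugname = index_names)
  conc_sel <- which(stats::runif(n) < cf$concomitant_rate)
  if (length(conc_sel)) {
    cm <- cf$concomitant_menu
    conc_inn <- sample(cm$inn, length(conc_sel), TRUE)
    conc_names <- style_drug_names(conc_inn,
                                   dplyr::mutate(cm, is_tki = FALSE), cf)
    drug_rows <- dplyr::bind_rows(drug_rows, tibble::tibble(
      primaryid = base_id[conc_sel], drug_seq = "2", role_cod = "C",
      drugname = conc_names))
  }

  reac <- tibble::tibble(
    primaryid = base_id[events$i],
    pt = events$term,
    onset_dt = format_partial_date(anchor_date(events$onset, events$prec),
                                   events$prec))

  outc_codes <- c("DE", "LT", "HO", "DS", "OT")
  outc_w <- c(0.12, 0.05, 0.35, 0.02, 0.46)
  ser_i <- which(serious)
  outc <- tibble::tibble(primaryid = base_id[ser_i],
                         outc_cod = sample(outc_codes, length(ser_i), TRUE,
                                           prob = outc_w))
  extra <- ser_i[stats::runif(length(ser_i)) < 0.25]
  if (length(extra))
    outc <- dplyr::bind_rows(outc, tibble::tibble(
      primaryid = base_id[extra],
      outc_cod = sample(outc_codes, length(extra), TRUE, prob = outc_w)))

  indi_pool_tki <- c("chronic myeloid leukemia", "acute lymphocytic leukemia",
                     "myeloid leukemia nos")
  indi_pool_other <- c("breast neoplasm", "pulmonic neoplasm",
                       "colorectal neoplasm", "lymphoma nonspecific")
  indi_pt <- ifelse(is_tki,
                    sample(indi_pool_tki, n, TRUE, prob = c(0.75, 0.15, 0.10)),
                    sample(indi_pool_other, n, TRUE))
  indi <- tibble::tibble(primaryid = base_id, indi_drug_seq = "1",
                         indi_pt = indi_pt)

  ther <- tibble::tibble(
    primaryid = base_id, dsg_drug_seq = "1",
    start_dt = format_partial_date(anchor_date(start_date, start_prec),
                                   start_prec),
    end_dt = "")

  # --- clones -------------------------------------------------------------
  clone_tables <- function(sel, new_pid, new_cid = NULL, new_version = NULL) {
    pid <- base_id[sel]
    map <- setNames(new_pid, pid)
    cl_demo <- demo[match(pid, demo$primaryid), , drop = FALSE]
    cl_demo$primaryid <- new_pid
    if (!is.null(new_cid)) cl_demo$caseid <- new_cid
    if (!is.null(new_version)) cl_demo$caseversion <- new_version
    reclone <- function(tab) {
      cl <- tab[tab$primaryid %in% pid, , drop = FALSE]
      cl$primaryid <- unname(map[cl$primaryid])
      cl
    }
    list(demo = cl_demo, drug = reclone(drug_rows), reac = reclone(reac),
         outc = reclone(outc), indi = reclone(indi), ther = reclone(ther))
  }
  fu_ids <- sprintf("F%08d", fu_sel)
  dup_ids <- sprintf("RZ%07d", dup_sel)
  fu_cl <- if (length(fu_sel)) clone_tables(fu_sel, fu_ids, new_version = "2")
  dup_cl <- if (length(dup_sel)) clone_tables(dup_sel, dup_ids,
                                              new_cid = sprintf("CZ%07d", dup_sel))
  bind_part <- function(nm) {
    dplyr::bind_rows(
      switch(nm, demo = demo, drug = drug_rows, reac = reac, outc = outc,
             indi = indi, ther = ther),
      if (length(fu_sel)) fu_cl[[nm]], if (length(dup_sel)) dup_cl[[nm]])
  }
  tabs <- lapply(setNames(c("demo", "drug", "reac", "outc", "indi", "ther"),
                          c("demo", "drug", "reac", "outc", "indi", "ther")),
                 bind_part)
  load_report <- tibble::tibble(table = names(tabs),
                                n_read = vapply(tabs, nrow, integer(1)),
                                n_dropped_no_key = 0L, n_dropped_orphan = 0L)
  tables <- new_raw_table_set(tabs, load_report,
                              source_quarter = "synthetic")

  # --- ground truth -------------------------------------------------------
  retained <- serious & !aberrant
  rep_id_final <- base_id
  rep_id_final[fu_sel] <- fu_ids  # the follow-up version survives step 1
  retained_ids <- rep_id_final[retained]

  report_flags <- tibble::tibble(
    report_id = base_id, case_id = case_id, serious = serious,
    aberrant = aberrant,
    has_followup_clone = seq_len(n) %in% fu_sel,
    has_duplicate_clone = seq_len(n) %in% dup_sel,
    drug_inn = drug_inn, is_tki = is_tki,
    retained_as = ifelse(retained, rep_id_final, NA_character_))

  cases_long <- tibble::tibble(
    report_id = rep(rep_id_final, length(smqs)),
    i = rep(seq_len(n), length(smqs)),
    smq_name = rep(smqs, each = n),
    is_case = as.vector(case))
  cases_long <- cases_long[retained[cases_long$i], , drop = FALSE]

  exposure <- tibble::tibble(report_id = retained_ids,
                             drug_inn = drug_inn[retained],
                             is_tki = is_tki[retained])

  count_one <- function(expo_vec, s) {
    cs <- case[retained, s]
    tibble::tibble(a = sum(expo_vec & cs), b = sum(expo_vec & !cs),
                   c = sum(!expo_vec & cs), d = sum(!expo_vec & !cs))
  }
  counts <- purrr::map_dfr(c(tkim$inn, "tki_class"), function(dg) {
    expo <- if (dg == "tki_class") is_tki[retained] else
      drug_inn[retained] == dg
    purrr::map_dfr(smqs, function(s)
      dplyr::mutate(count_one(expo, s), drug = dg, smq_name = s,
                    true_or = if (dg == "tki_class") NA_real_ else
                      or_lookup(cf, dg, s)))
  })

  cr <- which(!is.na(events$smq))
  truth_tto <- tibble::tibble(
    report_id = rep_id_final[events$i[cr]],
    drug = drug_inn[events$i[cr]],
    smq_name = events$smq[cr],
    tto_true = as.integer(events$onset[cr] - start_date[events$i[cr]]))
  truth_tto <- truth_tto[retained[events$i[cr]], , drop = FALSE]

  funnel <- list(
    n_input = nrow(tabs$demo),
    n_nonserious_removed = sum(!serious),
    n_duplicates_removed = length(fu_sel) + length(dup_sel),
    n_aberrant_removed = length(ab_sel),
    n_retained = sum(retained))

  list(tables = tables,
       truth = list(report_flags = report_flags, cases = cases_long,
                    exposure = exposure, counts = counts,
                    funnel = funnel, tto = truth_tto,
                    retained_ids = retained_ids, config = cf))
}
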