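#' Scenario calibrated to the published margins
#'
#' Builds a [scenario_config()] whose expected marginals approximate the
#' published screen at reduced scale: TKI share of anticancer reports,
#' within-TKI drug shares, per-drug cardiovascular case probabilities,
#' query mix, and the age/sex/reporter/country/year marginals of TKI
#' cases ([tki_cv_reference_counts()]). Per-pair odds ratios are derived so
#' that each TKI's expected per-query case probability matches its
#' published margin against the comparator baseline; no extra confounding
#' is planted. Under this preset the expected nilotinib share of TKI
#' cardiovascular cases is about 59% and the expected male share about
#' 52.9%.
#'
#' @param n_reports number of base reports (the published corpus is ~717k
#'   retained reports; the default emulates its structure at 1/7 scale
#'   while keeping every expected share).
#' @param seed integer seed.
#' @return a `scenario_config`.
#' @export
paper_margin_preset <- function(n_reports = 100000, seed = 1L) {
  ref <- tki_cv_reference_counts()
  drug_tot <- c(bosutinib = 258, dasatinib = 7217, imatinib = 2464,
                nilotinib = 11333, ponatinib = 3101)
  n_tki_reports <- sum(drug_tot)                      # 24,373
  tki_share <- n_tki_reports / ref$n_anticancer_retained
  menu <- default_drug_menu(tki_share = tki_share)
  w <- drug_tot[menu$inn[menu$is_tki]] / n_tki_reports
  menu$share[menu$is_tki] <- tki_share * unname(w)

  # per-drug probability of being a CV case of each query, and the
  # comparator baseline per query, both taken from the published margins
  any_cv <- ref$drug_of_tki_cases[names(drug_tot)] / drug_tot
  smq_split <- ref$smq_of_tki_cases / ref$n_tki_cases
  n_comp <- ref$n_anticancer_retained - n_tki_reports
  baseline <- ref$smq_of_other_anticancer_cases / n_comp
  odds <- function(p) p / (1 - p)
  true_or <- numeric(0)
  for (d in names(drug_tot)) {
    p_ds <- any_cv[[d]] * smq_split
    true_or[paste(d, names(smq_split), sep = "|")] <-
      unname(odds(p_ds) / odds(baseline[names(smq_split)]))
  }

  scenario_config(
    n_reports = n_reports,
    drug_menu = menu,
    smq_baseline = baseline,
    true_or = true_or,
    nonserious_rate = 0.125,
    dup_rate = 0.16,
    followup_rate = 0.16,
    aberrant_rate = 0.09,
    missing_date_rate = 0.45,
    age_probs = c(0.010, 0.111, 0.440, 0.125, 0.314),
    sex_probs = c(0.362, 0.529, 0.109),
    reporter_probs = c(0.732, 0.242, 0.026),
    country_probs = c(US = 0.321, JP = 0.106, DE = 0.075, FR = 0.070,
                      other = 0.383, unknown = 0.045),
    years = 2008:2018,
    year_probs = c(3.1, 2.7, 4.1, 5.3, 7.2, 10.8, 13.9, 10.6, 12.2, 12.8,
                   17.3),
    tto_law = list(dist = "exponential", mean = 150),
    seed = seed)
}
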