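#!/usr/bin/env Rscript
# Case/non-case disproportionality screen: crude and age/sex-adjusted RORs
# for every TKI x cardiovascular query pair plus the TKI class, with the
# >=3-case eligibility rule and SDR flagging; also writes the descriptive
# case-characteristics tables.
source("analysis/_common.R")

pl <- load_pipeline()
scr <- screen_all(pl$store, pl$exposures, pl$catalogue, labels = pl$labels)
print(scr)

ensure_dir(results_dir)
readr::write_csv(scr$results, file.path(results_dir, "screen_results.csv"))
readr::write_csv(format_screen(scr),
                 file.path(results_dir, "screen_results_display.csv"))
readr::write_csv(scr$ineligible, file.path(results_dir, "screen_ineligible.csv"))

sig <- format_screen(scr)[scr$results$sdr,
                          c("drug", "smq_name", "a",
                            "adj_ror", "adj_ci_low", "adj_ci_high")]
message("signals of disproportionate reporting:")
print(sig, n = Inf)

# descriptive table over the cases of any cardiovascular query
case_ids <- unique(pl$labels$report_id[pl$labels$is_case])
tki_ids <- pl$exposures$report_id[pl$exposures$n_tki > 0]
cases <- pl$store$reports[pl$store$reports$report_id %in%
                            intersect(case_ids, tki_ids), ]
ds <- descriptive_summary(cases)
for (v in c("age_class", "sex", "reporter_type", "country", "reporting_year")) {
  readr::write_csv(ds[[v]],
                   file.path(results_dir, paste0("tki_cases_", v, ".csv")))
}
message(sprintf("TKI cases: n=%d, median age %.0f (Q1 %.0f, Q3 %.0f)",
                nrow(cases), ds$age$median, ds$age$q1, ds$age$q3))
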