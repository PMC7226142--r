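#!/usr/bin/env Rscript
# Ingest the simulated tables, normalize drug names, and run the
# report-inclusion funnel (serious -> deduplicate -> aberrant).
source("analysis/_common.R")

cfg <- analysis_config()
paths <- setNames(file.path(tables_dir, paste0(names(faers_dialect()), ".txt")),
                  names(faers_dialect()))
ts <- read_table_set(paths, source_quarter = "synthetic")
st <- assemble_reports(ts)
arch <- archive_from_config(cfg)
st <- resolve_drugs(st, arch, fuzzy = TRUE)

cov <- mapping_coverage(st)
message(sprintf("name-mapping coverage: %.1f%%", 100 * cov$coverage))

pp <- preprocess_reports(st)
print(pp$funnel)

ensure_dir(results_dir)
readr::write_csv(tibble::as_tibble(unclass(pp$funnel)),
                 file.path(results_dir, "funnel.csv"))
keep <- pp$store
readr::write_csv(dplyr::select(keep$reports, -"outcomes"),
                 file.path(results_dir, "retained_reports.csv"))
readr::write_csv(dplyr::mutate(keep$drugs,
                               inn = vapply(inn, paste, "", collapse = ";")),
                 file.path(results_dir, "retained_drugs.csv"))
readr::write_csv(keep$events, file.path(results_dir, "retained_events.csv"))
message(pp$funnel$n_retained, " reports retained")
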