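# shared settings for the numbered analysis drivers
library(faersdispro)

analysis_seed <- 20260921L
analysis_n <- 40000L            # base reports in the simulated corpus
results_dir <- "results"
tables_dir <- file.path(results_dir, "synthetic_faers")

analysis_config <- function() {
  paper_margin_preset(n_reports = analysis_n, seed = analysis_seed)
}

ensure_dir <- function(d) if (!dir.exists(d)) dir.create(d, recursive = TRUE)

# rebuild the analysis state from the simulated tables on disk; each driver
# stays independently runnable after 01_simulate.R
load_pipeline <- function(cfg = analysis_config()) {
  paths <- setNames(file.path(tables_dir,
                              paste0(names(faers_dialect()), ".txt")),
                    names(faers_dialect()))
  st <- assemble_reports(read_table_set(paths, source_quarter = "synthetic"))
  arch <- archive_from_config(cfg)
  st <- resolve_drugs(st, arch, fuzzy = TRUE)
  pp <- preprocess_reports(st)
  catalogue <- smq_catalogue(cfg$smq_menu, required = cv_smq_names())
  list(config = cfg, archive = arch, store = pp$store, funnel = pp$funnel,
       exposures = flag_exposures(pp$store, arch),
       catalogue = catalogue,
       labels = classify_cases(pp$store, catalogue))
}
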