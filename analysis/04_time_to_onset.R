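#!/usr/bin/env Rscript
# Time-to-onset medians/IQRs and cumulative distribution tables for the
# drug-query pairs flagged by the screen.
source("analysis/_common.R")

pl <- load_pipeline()
scr <- screen_all(pl$store, pl$exposures, pl$catalogue, labels = pl$labels)
sdr_pairs <- scr$results[scr$results$sdr & scr$results$drug != "tki_class",
                         c("drug", "smq_name")]
if (nrow(sdr_pairs) == 0) {
  message("no single-drug SDR pairs; summarizing the largest eligible pair")
  top <- scr$results[scr$results$drug != "tki_class", ]
  sdr_pairs <- top[order(-top$a), c("drug", "smq_name")][1, ]
}

ensure_dir(results_dir)
summ <- list(); cdfs <- list()
for (k in seq_len(nrow(sdr_pairs))) {
  d <- sdr_pairs$drug[k]; s <- sdr_pairs$smq_name[k]
  rec <- compute_tto(pl$store, pl$labels, pl$exposures, pl$catalogue, d, s)
  st <- summarize_tto(rec, cap_days = 365)
  summ[[k]] <- tibble::tibble(drug = d, smq_name = s,
                              n_cases = nrow(rec),
                              n_informative = st$n_informative,
                              median = st$median, q1 = st$q1, q3 = st$q3)
  if (st$available)
    cdfs[[k]] <- dplyr::mutate(st$cdf, drug = d, smq_name = s)
}
summ <- dplyr::bind_rows(summ)
readr::write_csv(summ, file.path(results_dir, "tto_summary.csv"))
readr::write_csv(dplyr::bind_rows(cdfs), file.path(results_dir, "tto_cdf.csv"))
print(summ, n = Inf)
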