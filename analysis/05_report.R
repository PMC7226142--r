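#!/usr/bin/env Rscript
# Render the forest plot of adjusted RORs (one panel per query) and the
# time-to-onset step curves from the tables written by 03/04.
source("analysis/_common.R")

pl <- load_pipeline()
scr <- screen_all(pl$store, pl$exposures, pl$catalogue, labels = pl$labels)

ensure_dir(file.path(results_dir, "figures"))
p <- render_forest(scr)
ggplot2::ggsave(file.path(results_dir, "figures", "forest_aror.png"),
                p, width = 10, height = 7, dpi = 150)

cdf_path <- file.path(results_dir, "tto_cdf.csv")
if (file.exists(cdf_path)) {
  cdf <- readr::read_csv(cdf_path, show_col_types = FALSE)
  q <- ggplot2::ggplot(cdf, ggplot2::aes(x = t, y = p,
                                         colour = paste(drug, smq_name))) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "time to onset (days)", y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme(legend.position = "bottom")
  ggplot2::ggsave(file.path(results_dir, "figures", "tto_cdf.png"),
                  q, width = 8, height = 5, dpi = 150)
}
message("figures written to ", file.path(results_dir, "figures"))
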