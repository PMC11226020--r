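#!/usr/bin/env Rscript
# Species accumulation figures from the curves written by 03_richness.R.
# Figures are scratch output (PDF); the underlying tables live in results/.

suppressPackageStartupMessages({
  library(dplyr)
  library(ggplot2)
})

curves <- readr::read_csv("results/accumulation_curves.csv",
                          show_col_types = FALSE) |>
  mutate(series = ifelse(method == "point_count", "point count",
                         paste0("ARU @ ", threshold_label)))

dir.create("scratch", showWarnings = FALSE)
p <- ggplot(curves, aes(day_index, cumulative_richness, colour = series)) +
  geom_step(linewidth = 0.6) +
  labs(x = "Day of season", y = "Cumulative focal species richness",
       colour = NULL,
       title = "Focal species accumulation: ARU thresholds vs point counts") +
  theme_minimal()
ggsave("scratch/accumulation_curves.pdf", p, width = 7, height = 4.5)
message("Wrote scratch/accumulation_curves.pdf")
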