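#!/usr/bin/env Rscript
# Stage 4: trending (successive-change) analysis.
#
# Four-quadrant concordance for SBP, DBP and CO with the conventional
# exclusion zones (+/- 2 mmHg, +/- 0.5 l/min), plus the correlation of
# reference vs device changes among surviving pairs.

suppressPackageStartupMessages(library(hemovalid))

clean <- read_dataset("results/cohort_screened.csv")
tab <- trending_table(clean)
utils::write.csv(as.data.frame(tab), "results/trending.csv",
                 row.names = FALSE)

dir.create("results/figures", showWarnings = FALSE)
for (v in c("SBP", "DBP", "CO")) {
  ggplot2::ggsave(file.path("results/figures",
                            paste0("four_quadrant_", v, ".png")),
                  plot_four_quadrant(dataset_changes(clean, v)),
                  width = 5, height = 5, dpi = 150)
}

cat("Four-quadrant trending:\n")
print(as.data.frame(tab), digits = 3)
cat("\nWrote results/trending.csv and results/figures/\n")
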