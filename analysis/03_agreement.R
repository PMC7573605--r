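#!/usr/bin/env Rscript
# Stage 3: static agreement statistics per variable and phase stratum.
#
# Pearson correlation and device-on-reference regression, ICC(A,1) with
# the standard error of measurement, Bland-Altman bias with 95% limits
# of agreement, percentage error for CO, and mmHg error bins for BP.

suppressPackageStartupMessages(library(hemovalid))

clean <- read_dataset("results/cohort_screened.csv")
tab <- agreement_table(clean)
utils::write.csv(as.data.frame(tab), "results/agreement.csv",
                 row.names = FALSE)

dir.create("results/figures", showWarnings = FALSE)
for (v in hv_variables) {
  ggplot2::ggsave(file.path("results/figures",
                            paste0("bland_altman_", v, ".png")),
                  plot_bland_altman(clean, v), width = 6, height = 4,
                  dpi = 150)
  ggplot2::ggsave(file.path("results/figures", paste0("scatter_", v, ".png")),
                  plot_scatter_regression(clean, v), width = 6, height = 4,
                  dpi = 150)
}

pooled <- tab[tab$stratum == "all", ]
cat("Pooled agreement (all phases):\n")
print(as.data.frame(pooled[, c("variable", "n", "pearson_r", "icc",
                               "sem_measurement", "bias", "loa_lower",
                               "loa_upper")]), digits = 3)
cat("\nWrote results/agreement.csv and results/figures/\n")
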