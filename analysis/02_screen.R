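#!/usr/bin/env Rscript
# Stage 2: outlier screening on the invasive reference channel.
#
# Successive percentage differences are computed per series, pooled per
# variable, and a point is eliminated when it differs from both of its
# neighbours by more than 2 SD of the pooled absolute differences.

suppressPackageStartupMessages(library(hemovalid))

cohort <- read_dataset("results/cohort.csv")
screened <- screen_outliers(cohort, k = 2)
write_dataset(screened$clean, "results/cohort_screened.csv")

rep <- screened$report
jsonlite::write_json(
  list(removed = as.data.frame(rep$removed),
       per_variable_counts = as.list(rep$per_variable_counts),
       thresholds = as.list(rep$thresholds),
       total_screened = rep$total_screened),
  "results/outlier_report.json", auto_unbox = TRUE, digits = NA,
  pretty = TRUE)

cat(sprintf("Screened %d interior points; removed %d (%.2f%% of %d rows)\n",
            rep$total_screened, nrow(rep$removed),
            100 * nrow(rep$removed) / nrow(cohort), nrow(cohort)))
print(rep$per_variable_counts)
cat("\nWrote results/cohort_screened.csv and results/outlier_report.json\n")
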