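#!/usr/bin/env Rscript
# Stage 5: assemble the full validation report (stages 2-4 in one pass,
# from the raw cohort) and evaluate the acceptability flags.

suppressPackageStartupMessages(library(hemovalid))

cohort <- read_dataset("results/cohort.csv")
report <- run_pipeline(cohort)
write_report(report, "results/validation_report.json")

print(report)
cat("\nWrote results/validation_report.json\n")
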