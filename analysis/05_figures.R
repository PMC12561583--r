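#!/usr/bin/env Rscript
# Report figures: MARP and DP bar charts by group and stage with SD error
# bars, and ensemble mean +/- SD relative-phase curves over the 0-100%
# movement cycle for every group/stage/coupling cell. Writes PNGs under
# results/figures/.

library(crpcoord)

cohort <- load_cohort("results/cohort")
bundle <- run_analysis(cohort$trials, analysis_config())
files <- save_report_figures(bundle, "results/figures")
cat("wrote", length(files), "figures:\n")
cat(paste(" -", files), sep = "\n")
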