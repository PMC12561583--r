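#!/usr/bin/env Rscript
# The gated inferential workflow on the per-subject metrics: assumption
# checks (Shapiro-Wilk, Levene), the baseline novice t-test and three-group
# ANOVA with pairwise post hoc tests, the pre/post paired t-tests within each
# novice group, and the post-training comparisons - all with effect sizes.
# Writes the full report bundle under results/report/.

library(crpcoord)

cohort <- load_cohort("results/cohort")
bundle <- run_analysis(cohort$trials, analysis_config())
write_report_bundle(bundle, "results/report")

tests <- bundle$tests
show <- function(label, comparison, index) {
  sub <- tests[tests$comparison == comparison & tests$index == index &
                 tests$coupling == "ankle-knee", ]
  if (nrow(sub) == 0) return(invisible(NULL))
  df_txt <- if (sub$method == "one_way_anova") {
    sprintf("F(%g,%g)", sub$df1, sub$df2)
  } else {
    sprintf("t(%g)", sub$df1)
  }
  cat(sprintf("%-38s %s = %6.2f, p = %.3f, %s = %.2f\n", label, df_txt,
              sub$statistic, sub$p_value, sub$effect_type, sub$effect))
}

cat("ankle-knee MARP, key comparisons:\n")
show("baseline novice t (control vs test):", "pre_novice_t", "marp")
show("baseline 3-group ANOVA:", "pre_anova", "marp")
show("  post hoc control vs target:", "pre_posthoc_control_vs_target", "marp")
show("  post hoc test vs target:", "pre_posthoc_test_vs_target", "marp")
show("paired pre/post, control:", "paired_control_pre_post", "marp")
show("paired pre/post, test:", "paired_test_pre_post", "marp")
show("post-training 3-group ANOVA:", "post_anova", "marp")
cat("\nfull tables -> results/report/ (tests.csv, assumptions.csv,",
    "group_summary.csv, ensembles.csv)\n")
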