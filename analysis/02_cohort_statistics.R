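#!/usr/bin/env Rscript
# End-to-end synthetic study: a 10 non-smoker + 9 usable-smoker cohort is
# generated, every subject's acquisition is processed through field
# mapping, B0/B1 correction and ROI summarization, and the cohort
# statistics are computed: per-region Wilcoxon rank-sum group comparisons,
# per-group age regressions with R^2, and volume-contrast correlations.
# Writes the results bundle under results/cohort/.

library(glucestr)

run <- run_pipeline(cohort_config(), seed = 20240216,
                    output_dir = "results/cohort", quiet = FALSE)

message("\nGroup comparison table (mean (SD) percent contrast, Wilcoxon p):")
print(run$results$table1, digits = 3)

message("\nAge regressions per region and group:")
print(run$results$age_regressions, digits = 3)

message("\nUnder the default configuration no group effect or age slope is ",
        "injected, so group p-values should scatter uniformly and R^2 ",
        "values stay small.")
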