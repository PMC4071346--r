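#!/usr/bin/env Rscript
# Confidence filtering of the simulated identifications: target-decoy
# q-values on the PSM table (acceptance at q <= 0.01) and artifact rejection
# (C-terminal methyl-K, methyl-K in acidic context, C-terminal deamidated R).
# Expects results/cohort/ from 01_simulate.R.

suppressPackageStartupMessages(library(histoneLFQ))

out <- "results/cohort"
res <- run_pipeline(out, mode = "identify", cohort = cohort_config(seed = 1))
q <- res$psms
cat("PSMs: ", sum(!q$is_decoy), " targets, ", sum(q$is_decoy), " decoys; ",
    sum(!q$is_decoy & q$q_value <= 0.01), " accepted at q <= 0.01.\n",
    sep = "")
cat("Retained modified peptides: ", length(res$panel_retained),
    " (rejection report: ", file.path(out, "peptides_rejected.tsv"), ")\n",
    sep = "")
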