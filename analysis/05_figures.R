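#!/usr/bin/env Rscript
# Concentration-time figures: mean +/- SEM per arm with the terminal-phase
# single-exponential fit overlaid, on a log concentration axis.

library(hemopk)

study <- run_study(reference_study_arms())
dir.create("results/figures", recursive = TRUE, showWarnings = FALSE)

plot_profiles(study, file = "results/figures/concentration_time.png")
cat("Wrote results/figures/concentration_time.png\n")

# A focused two-analyte panel for one glucocorticoid arm
single <- structure(list(arms = study$arms["prednisone_human_hb"]),
                    class = "hemopk_study")
plot_profiles(single,
              file = "results/figures/prednisone_human_hb.png")
cat("Wrote results/figures/prednisone_human_hb.png\n")
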