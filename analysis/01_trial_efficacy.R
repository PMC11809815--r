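#!/usr/bin/env Rscript
# Stage 1: vaccine efficacy on the cattle tick-infestation trial.
#
# Reads the packaged per-animal trial table (control, SUB, SUB+BM86 and
# BM86 groups; n = 3 per arm), computes the four effect statistics per
# group with one-sided Welch gating, and writes the per-group summary.
# Finding: SUB significantly reduces tick number (43%, p ~ 0.008) and egg
# fertility (33%, p ~ 0.049) for a gated efficacy of 62%, while the
# antigen combination shows no gated effect (E = 0 under the stated
# rule) - the observation motivating the interaction modelling stages.

suppressPackageStartupMessages(library(quantavax))
dir.create("results", showWarnings = FALSE)

trial <- read_trial_csv(system.file("extdata", "trial_table1.csv",
                                    package = "quantavax"))
rows <- list()
for (group in names(trial$groups)) {
  s <- vaccine_efficacy(trial, group)
  print(s)
  eff <- s$effects
  rows[[group]] <- data.frame(
    group = group,
    metric = eff$metric,
    mean_v = round_half_away(eff$mean_v, 2),
    sd_v = round_half_away(eff$sd_v, 2),
    mean_c = round_half_away(eff$mean_c, 2),
    sd_c = round_half_away(eff$sd_c, 2),
    reduction_pct = eff$reduction_pct,
    p_value = signif(eff$p_value, 3),
    significant = eff$significant,
    efficacy_pct = s$efficacy_display
  )
}
summary <- do.call(rbind, rows)
write.csv(summary, "results/trial_efficacy.csv", row.names = FALSE)
cat("wrote results/trial_efficacy.csv\n")

# The later proof-of-concept chimera trial is summarised by its component
# ratios; all three entered the product.
e <- efficacy_from_ratios(22 / 25, 240 / 300, 1.1 / 4.4)
cat(sprintf("Chimera proof-of-concept trial: E = %d%%\n", as.integer(e$efficacy_display)))
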