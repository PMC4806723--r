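#!/usr/bin/env Rscript
# Stage 2: integrated diurnal water loss. Pads the porometer readings with
# zeros at dawn and dusk, integrates each individual's curve, and tests
# the species difference against a 1000-fold label-permutation null.

suppressPackageStartupMessages(library(invasiontraits))

obs <- read.csv("results/data/conductance.csv", comment.char = "#",
                stringsAsFactors = FALSE)
curves <- pad_dawn_dusk(obs)
daily <- integrate_daily(curves)

perm <- permutation_test(curves, n_perm = 1000, seed = 42,
                         species_order = c("ERTE", "ERCI"))
print(perm)
pct <- percent_reduction(daily)
cat(sprintf("\nThe lower species lost %.1f%% less water over the day.\n",
            pct))

dir.create("results/water_loss", recursive = TRUE, showWarnings = FALSE)
write.csv(daily, "results/water_loss/daily_water_loss.csv",
          row.names = FALSE)
write.csv(data.frame(perm_difference = perm$permutation_differences),
          "results/water_loss/permutation_distribution.csv",
          row.names = FALSE)
write.csv(data.frame(observed_difference = perm$observed,
                     lower_95 = perm$lower_95, upper_95 = perm$upper_95,
                     p_two_sided = perm$p_two_sided,
                     percent_reduction = pct),
          "results/water_loss/summary.csv", row.names = FALSE)
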