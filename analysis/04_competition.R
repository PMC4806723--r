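#!/usr/bin/env Rscript
# Stage 4: competition. Computes relative interaction intensity per focal
# plant for seed set, total, above-ground and root mass, and the two-way
# ANOVAs (focal species x competitor identity).

suppressPackageStartupMessages(library(invasiontraits))

comp <- read.csv("results/data/competition.csv", comment.char = "#",
                 stringsAsFactors = FALSE)
dir.create("results/competition", recursive = TRUE, showWarnings = FALSE)

riis <- rii_table(comp)
write.csv(riis, "results/competition/rii_values.csv", row.names = FALSE)

summ <- rii_summary(riis)
cat("Mean RII by focal species and competitor identity:\n")
print(summ[summ$response == "total_mass", ], digits = 3)
write.csv(summ, "results/competition/rii_summary.csv", row.names = FALSE)

for (resp in unique(riis$response)) {
  tab <- rii_anova(riis, resp)
  write.csv(as.data.frame(tab),
            file.path("results/competition",
                      paste0("rii_anova_", resp, ".csv")),
            row.names = FALSE)
}
tm <- rii_anova(riis, "total_mass")
cat("\nTotal-biomass RII ANOVA:\n")
print(tm)
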