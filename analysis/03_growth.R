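#!/usr/bin/env Rscript
# Stage 3: growth analysis. Fits RGR/NAR/leaf-area slopes per species and
# year, runs the mixed ANCOVAs (plot random), the mid-season allocation
# ANOVAs, the relative change in LAR, and the leaf-chemistry ANOVAs.

suppressPackageStartupMessages(library(invasiontraits))

harv <- read.csv("results/data/harvests.csv", comment.char = "#",
                 stringsAsFactors = FALSE)
iso <- read.csv("results/data/isotopes.csv", comment.char = "#",
                stringsAsFactors = FALSE)
dir.create("results/growth", recursive = TRUE, showWarnings = FALSE)
save_tab <- function(tab, name)
  write.csv(as.data.frame(tab), file.path("results/growth", name),
            row.names = FALSE)

rates <- fit_growth_rates(harv)
cat("Growth rates (slope of ln mass / ln mass-per-area vs. age):\n")
print(rates, digits = 3)
save_tab(rates, "growth_rates.csv")

cat("\nRGR ANCOVA (species x year, age covariate, plot random):\n")
rgr_tab <- rgr_ancova(harv)
print(rgr_tab)
save_tab(rgr_tab, "rgr_ancova.csv")
save_tab(nar_ancova(harv), "nar_ancova.csv")

for (comp in c("SLA", "LAR", "root_shoot", "LMR")) {
  tab <- midseason_anova(harv, comp, age = 95)
  save_tab(tab, paste0("midseason_", comp, ".csv"))
  cat(sprintf("\nMid-season %s: species-by-year p = %.4f\n", comp,
              tab$p[tab$term == "species:year"]))
}

lar <- lar_change_table(harv, early_age = 53, late_age = 95)
cat("\nRelative change in LAR (53 -> 95 days):\n")
print(lar, digits = 3)
save_tab(lar, "lar_change.csv")

for (resp in c("leaf_n", "delta")) {
  tab <- leafchem_anova(iso, resp)
  save_tab(tab, paste0("leafchem_", resp, ".csv"))
}
cat(sprintf("\nMean carbon isotope discrimination: %.2f per mil\n",
            mean(iso$delta)))
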