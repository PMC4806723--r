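---
title: "Comparing an invasive and a native desert annual: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparing an invasive and a native desert annual: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(invasiontraits)
```

## The scientific problem

Why does a non-native winter annual spread through a desert community
whose native flora sits on a well-documented trade-off between water-use
efficiency (WUE) and relative growth rate (RGR)? Two broad explanations
compete. Under the enemy release hypothesis (ERH) the invader escapes its
natural herbivores and converts the saved cost of defence into growth.
Under the trait-combination explanation the invader simply grows fast
*and* uses water efficiently, a combination the natives do not express.

This package implements the comparative pipeline needed to distinguish
those explanations for a pair of congeneric annuals — an invasive species
(coded `ERCI`) and a native (`ERTE`) — across four experimental designs:

1. **Diurnal water loss.** Instantaneous stomatal conductance
   ($g_s$, mmol m⁻² s⁻¹) measured on a handful of individuals a few times
   through the day, integrated into a daily total and compared between
   species with a permutation test.
2. **Sequential harvests.** Destructive harvests of field-grown plants at
   known ages in two growing seasons, yielding RGR, NAR and the
   allocation components SLA, LAR, LMR, RMR and root:shoot.
3. **Competition.** A greenhouse neighbour-manipulation design (each
   species alone, with four conspecifics, or with four heterospecifics),
   summarised by the relative interaction intensity (RII).
4. **Herbivore exclusion.** A blocked field factorial (control vs.
   exclusion plots × species) whose species-by-treatment interaction is
   the operational ERH test.

No raw data ship with the package; a seed-reproducible synthetic-data
generator (`sim_config()`, `gen_*()`) emulates all four designs, so every
statistical procedure has a parameter-recovery surface and every analysis
script runs end to end from nothing but a seed.

## Daily water loss and the permutation null

Porometer readings are taken at a few clock times (default 08:30, 10:30,
13:30, 16:30). Stomata are closed in the dark, so `pad_dawn_dusk()`
anchors each individual's curve with zeros at dawn and dusk; with the
default four readings each curve has six points. The dawn and dusk
defaults (06:30 and 18:30) are the minimal 12-hour window bracketing the
sampling times, and both are arguments. `integrate_daily()` evaluates the
trapezoid-rule area under each curve (via `pracma::trapz`). Because time
is in hours, the integral's unit is (mmol m⁻² s⁻¹) h; we label it
explicitly rather than dropping the time factor.

The test statistic is the difference of species means of per-individual
daily integrals. `permutation_test()` builds the null by reassigning
species labels uniformly at random over whole individuals, preserving
group sizes; individuals, not single readings, are the exchangeable
units. The decision rule is the percentile-limit rule (observed outside
the central 95% of the permutation distribution) and an add-one-corrected
two-sided p-value is reported alongside, so p is never exactly zero. A
`"timepoint"` variant that integrates the per-time-point species mean
curve is provided; on a common measurement grid it equals the
per-individual statistic exactly (the trapezoid rule is linear), so it
matters only for ragged designs, which it rejects.

```{r water, eval = FALSE}
cfg <- sim_config(seed = 1)
curves <- pad_dawn_dusk(gen_conductance(cfg))
permutation_test(curves, n_perm = 1000, seed = 1,
                 species_order = c("ERTE", "ERCI"))
```

## Growth analysis

RGR is the slope of ln(total dry mass) against plant age across
destructively harvested individuals (a cross-sectional fit, matching the
sequential-harvest design — no plant is measured twice). NAR is defined
operationally as the slope of ln(mass per leaf area) against age, and the
leaf-area growth rate as the slope of ln(leaf area). Since
$\ln W = \ln(W/A) + \ln A$ and least squares is linear,

$$\mathrm{RGR} = \mathrm{NAR}_{\text{slope}} + \mathrm{RGR}_{\text{leaf area}}$$

holds to machine precision whenever the three fits share the same plants;
the tests assert this identity on every synthetic dataset. A classical
instantaneous NAR, $(1/A)\,dW/dt$, is deliberately not offered — the
log-slope definition is the one used throughout this pipeline.

Allocation components follow their standard definitions: SLA = leaf area
/ leaf mass, LAR = leaf area / total mass, LMR = leaf mass / total mass,
RMR = root mass / total mass, root:shoot = root/shoot mass, so that
LAR = SLA × LMR exactly. (LAR is *leaf area* over total mass; defining it
as leaf mass over total mass would duplicate LMR and break the identity.)
Records with a zero denominator are flagged rather than silently becoming
NaN. The mid-season relative change in LAR,
$(\mathrm{LAR}_{95} - \mathrm{LAR}_{53}) / \mathrm{LAR}_{53}$, uses
anchor ages 53 and 95 days after germination by default; both are
arguments.

Carbon isotope discrimination is
$\Delta = (\delta_{\text{air}} - \delta_{\text{plant}}) /
(1 + \delta_{\text{plant}}/1000)$
with both deltas per mil; $\delta_{\text{air}}$ defaults to −8‰, the
standard modern atmospheric value, and is configurable. The inverse
transform `d13c_from_delta()` is provided and round-trips to machine
precision.

## The ANOVA engine

All factorial tests go through one engine. `model_spec()` describes the
response, covariates, fixed factors, an optional single random blocking
factor, and an optional natural-log transform; `fit_anova()` /
`fit_ancova()` return one uniform table (term, df, denominator df, SS,
MS, F, p).

* **Fixed-effects models** use Type-II sums of squares by default
  (`car::Anova`), with Type I/III as options. Type II is marginal to
  interactions and coincides with sequential SS on the balanced
  orthogonal designs the generator produces.
* **A random blocking factor** is handled classically by error strata
  rather than REML: fixed terms that are constant within blocks (year,
  when plots are nested in years) are tested against the block-stratum
  mean square; within-block terms are tested against the residual. This
  keeps the engine deterministic and dependency-light. Multistratum
  tables use sequential SS within strata, which again equals Type II on
  balanced designs. An REML backend (`method = "reml"`, via lmerTest,
  Satterthwaite df) is available for unbalanced data; on balanced designs
  its within-block F ratios coincide with the strata engine, and the
  tests assert that agreement.
* Denominator df therefore follow the containment scheme. For the
  default exclusion design (16 blocks × 2 plots × 2 species = 64 rows)
  every fixed term is tested on 45 df. Published analyses of comparable
  designs, fitted with REML software, can print slightly different
  denominator df (44, or fractional values); exact denominator df are
  estimation-method specific and are not a target of this engine.
* Degenerate inputs — constant response, aliased terms, zero residual
  df, a covariate constant within a cell — raise errors rather than
  returning half-meaningful tables.

The specific models are: RGR/NAR ANCOVAs with ln response, age as
covariate, species × year fixed and plot random; mid-season component
ANOVAs on ln values with plot random; leaf-chemistry ANOVAs with no
random factor (error df $N-4$); the RII two-way ANOVA with an overall
model row; and the exclusion ANOVAs with block random.

## Competition: RII

$$\mathrm{RII} = \frac{B_w - \bar{B}_o}{B_w + \bar{B}_o}$$

where $B_w$ is a focal plant's performance with neighbours and
$\bar{B}_o$ the mean of its species grown alone, computed per response
(seed count, total, above-ground and root mass). RII is bounded in
[−1, 1]; negative values indicate competition. Seed-count RII is computed
on raw counts (no transformation). Zero-performing plants keep RII = −1
by default (`drop_zero` removes them). Because all individuals of a
species share one baseline, their RII values are not strictly
independent; the ANOVA treats them as independent, which is the
conventional use of this index.

Two coding details matter. First, the ANOVA factor is the *competitor's
species identity*, not conspecific/heterospecific status: "neighbours of
the invader suppress everyone harder" is a main effect only in identity
coding. Second, RII is concave in $B_w$, so multiplicative noise leaves a
small negative Jensen bias in mean RII even without competition (about
−0.08 for overdispersed seed counts at the default noise); the tests
bound rather than ignore this.

## Herbivore exclusion and the ERH verdict

Responses are plot-level summaries (individuals per plot, mean fruits,
mean mass), analysed untransformed by default, with block random.
`erh_test()` extracts the species-by-treatment interaction rows and
declares enemy release supported when the interaction is significant at
α (default 0.05) for at least one response. Both α and the
any-vs-all-responses rule are arguments, because the any-response rule
has familywise false-positive rate ≈ $1-(1-\alpha)^3$ across three
responses — the demonstration run in `analysis/` happens to show exactly
such a null false positive on the count response, and prints the
conservative all-responses verdict alongside.

## The synthetic-data generator

The generator is first-class, tested code: its defaults *are* the study
conditions, chosen once.

* **Design sizes** follow the field designs: 5 individuals per species ×
  4 clock times; harvests in 2 years × 5 plots × 4 ages (33, 53, 95, 116
  days — the two anchor ages plus flanks) × 5 plants; 20 pots alone and
  20 per focal × neighbour combination; 16 blocks of paired
  control/exclusion plots; 5 leaf samples per species × year.
* **Conductance** follows a smooth unimodal template (two quarter-sine
  arcs joined at a configurable peak time) sampled with truncated
  Gaussian noise; only the sampled points matter downstream, so the
  template's exact shape is immaterial. Peak heights (ERCI 300, ERTE 475
  mmol m⁻² s⁻¹) were set so the integrated contrast reproduces the
  magnitude of difference reported for this species pair in the field
  (roughly a third less water lost by the invader).
* **Masses** are multiplicative lognormal (positive, variance growing
  with the mean, standard for allometric data; CV 0.2), with a
  plot-level random effect on the log scale (SD 0.1) shared by both
  species within a plot. Intrinsic RGR values (0.055–0.09 day⁻¹) give
  realistic final masses from a 1 mg establishment mass and encode the
  warm-year invader advantage that motivates the species-by-year terms.
* **Allocation noise** (`allocation_noise_cv`, default 0.1) perturbs the
  leaf/root fractions and SLA per plant. Without it leaf area would track
  mass exactly, NAR would be identically zero and the mid-season ANOVAs
  would have zero within-cell variance; setting it (and the other noise
  knobs) to 0 recovers every stated expectation exactly, which the tests
  exploit.
* **Seed counts** are negative-binomial (dispersion a config knob);
  **suppression factors** in (0, 1] multiply expected outcomes, so a
  noiseless factor $s$ yields RII $=(s-1)/(s+1)$ exactly.
* **Exclusion responses** are additive: species mean + treatment effect
  (default 0) + interaction (default 0) + block effect + residual, with
  counts rounded to non-negative integers. The power simulation in the
  tests injects an interaction of 2 residual SD on mean mass (0.4 g),
  fixed a priori from the analytic power (~0.97 with 16 plots per cell).
* None of the field variances were published, so all noise defaults are
  plausibility choices, not estimates — a deliberate limitation.

What passing tests therefore show is that the *procedures* are correct
and calibrated (exact integrals, exact enumeration agreement, null
rejection rates at α, unbiased slope recovery), not that the synthetic
data reproduce the real community: the generator does not simulate
germination phenology, weather, spatial structure, missing plants or
measurement drift.

## Numerical choices and problem sizes

Permutation p-values use an add-one correction and count ties with a
relative floating-point tolerance, so a permuted split that reproduces
the observed difference is never lost to summation order. Percentile
limits use the default quantile definition. The test suite sizes its
simulations for tight feedback: 10⁴ random curves against an independent
shoelace-polygon oracle, exhaustive enumeration at 4+4 individuals
(70 splits) against 50 000 Monte-Carlo permutations, 1000 replicate null
datasets for permutation calibration, 500 for exclusion-ANOVA
calibration, 200 for growth-rate bias and ERH power, and 100 random
balanced factorials against a closed-form cell-means oracle.

## Known limitations

* The strata engine supports a single random blocking factor; crossed or
  nested random structures need the REML backend or a dedicated mixed
  model.
* Published denominator df from REML software are not reproduced exactly
  (see above); conclusions in all shipped analyses are insensitive to
  this.
* RII inference ignores the shared-baseline dependence noted above.
* Counts are analysed by Gaussian ANOVA on plot summaries to match
  standard practice for this design; a log transform is available, a
  Poisson GLMM is out of scope.
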